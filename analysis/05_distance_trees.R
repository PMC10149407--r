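#!/usr/bin/env Rscript
# Genetic and expression distance trees: TN93 distances on the
# concatenated promoter alignment, Euclidean distances on replicate-mean
# TPM/1000 per condition, BIONJ trees, and the rank correlation between
# the genetic and expression distance matrices. Writes newick files and
# distance matrices under results/.

suppressMessages(library(hsp90regulon))

genes <- read_gene_table("results/data/genes.tsv")
fa_files <- Sys.glob("results/data/genome_strain*.fa")
strains <- sub("^genome_(.*)\\.fa$", "\\1", basename(fa_files))

concat <- vapply(seq_along(fa_files), function(i) {
  genome <- read_fasta(fa_files[i])
  paste(vapply(seq_len(nrow(genes)), function(j) {
    as.character(extract_promoter(genome, genes[j, ], 500L))
  }, character(1)), collapse = "")
}, character(1))
names(concat) <- strains

genetic_d <- tn93_distance(concat)
cat("TN93 genetic distances (x1000):\n")
print(round(genetic_d * 1000, 2))

expt <- read_counts("results/data/counts.tsv", "results/data/samples.tsv")
filt <- filter_genes(expt)
lens <- stats::setNames(genes$end - genes$start + 1L, genes$gene_id)
tpm_mat <- tpm(filt, lens[rownames(filt$counts)])

for (cond in c("untreated", "treated")) {
  d <- expression_distance(tpm_mat, filt$samples, cond)
  tr <- bionj(d)
  writeLines(write_newick(tr), sprintf("results/tree_expression_%s.nwk", cond))
  rho <- compare_matrices(genetic_d, d)
  cat(sprintf("%s expression tree vs genetic distances: Spearman rho = %.2f\n",
              cond, rho))
  utils::write.table(data.frame(strain = rownames(d), round(d, 4)),
                     sprintf("results/dist_expression_%s.tsv", cond),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
writeLines(write_newick(bionj(genetic_d)), "results/tree_genetic.nwk")
utils::write.table(data.frame(strain = rownames(genetic_d), genetic_d),
                   "results/dist_genetic.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
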