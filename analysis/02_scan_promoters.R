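#!/usr/bin/env Rscript
# Extract 500-bp promoters from each strain's genome, scan them with the
# PWM library on both strands, align each gene's promoters across
# strains and classify every motif group as conserved / conserved with
# variation / non-conserved. Reads the files written by
# 01_simulate_data.R; writes results/tfbs_hits.tsv and
# results/tfbs_conservation.tsv.

suppressMessages(library(hsp90regulon))

genes <- read_gene_table("results/data/genes.tsv")
pwms <- read_pwm_library("results/data/pwms.txt")
fa_files <- Sys.glob("results/data/genome_strain*.fa")
strains <- sub("^genome_(.*)\\.fa$", "\\1", basename(fa_files))

promoters <- lapply(seq_along(fa_files), function(i) {
  genome <- read_fasta(fa_files[i])
  p <- vapply(seq_len(nrow(genes)), function(j) {
    as.character(extract_promoter(genome, genes[j, ], 500L))
  }, character(1))
  stats::setNames(p, genes$gene_id)
})
names(promoters) <- strains

hits <- do.call(rbind, lapply(strains, function(st) {
  scan_promoters(promoters[[st]], pwms, st)
}))
cat("Predicted TFBS hits:", nrow(hits), "across", length(strains), "strains\n")

conservation <- do.call(rbind, lapply(genes$gene_id, function(g) {
  h <- hits[hits$gene_id == g, , drop = FALSE]
  if (nrow(h) == 0) return(NULL)
  aln <- align_promoters(vapply(promoters, `[[`, character(1), g))
  classify_conservation(h, aln, window_bp = 20L)
}))

cls <- table(conservation$class)
cat("Conservation classes:\n"); print(cls)
cat(sprintf("Conserved (incl. variation): %.1f%%\n",
            100 * mean(conservation$class != "non_conserved")))

utils::write.table(hits, "results/tfbs_hits.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(conservation, "results/tfbs_conservation.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
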