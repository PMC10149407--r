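#!/usr/bin/env Rscript
# Per-strain treated/untreated differential expression (NB Wald test,
# BH-adjusted, DE = adj p < 0.05 and fold change > 2 or < 0.5) and
# strain-pair-specific gene classification into buffered / potentiated.
# Reads results/data; writes results/de_<strain>.tsv and
# results/pairs_<A>_<B>.tsv.

suppressMessages(library(hsp90regulon))

expt <- read_counts("results/data/counts.tsv", "results/data/samples.tsv")
filt <- filter_genes(expt, min_count = 5L)
cat("Genes analyzed after filtering:", nrow(filt$counts), "of",
    nrow(expt$counts), "\n")

sf <- size_factors(filt)
strains <- unique(filt$samples$strain)
de <- lapply(strains, function(st) de_test(filt, st, sf = sf))
names(de) <- strains
for (st in strains) {
  cat(sprintf("  %s: %d DE genes\n", st, sum(de[[st]]$is_de)))
  utils::write.table(de[[st]], sprintf("results/de_%s.tsv", st), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

pairs <- utils::combn(strains, 2, simplify = FALSE)
for (pr in pairs) {
  tab <- pair_specific(de[[pr[1]]], de[[pr[2]]])
  cls <- table(factor(tab$bp_class, c("buffered", "potentiated", "tie", "none")))
  cat(sprintf("  %s vs %s: %d pair-specific (%d buffered, %d potentiated)\n",
              pr[1], pr[2], sum(tab$is_pair_specific),
              cls[["buffered"]], cls[["potentiated"]]))
  utils::write.table(tab, sprintf("results/pairs_%s_%s.tsv", pr[1], pr[2]),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
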