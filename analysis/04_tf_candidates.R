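#!/usr/bin/env Rscript
# The TF-candidate cascade: conserved-motif target sets -> regulon-size
# exclusion -> Kruskal-Wallis screen across strains (Bonferroni) ->
# pairwise Wilcoxon tests -> strain-pair-specific-gene enrichment ->
# 0/1/2 labels and complete-linkage clustering. Also GO enrichment of
# each candidate's targets and a chaperone-client enrichment check at
# the published overlap counts. Reads outputs of scripts 01-03; writes
# results/tf_*.tsv.

suppressMessages(library(hsp90regulon))

conservation <- utils::read.delim("results/tfbs_conservation.tsv")
de_files <- Sys.glob("results/de_strain*.tsv")
strains <- sub("^de_(.*)\\.tsv$", "\\1", basename(de_files))
de <- lapply(de_files, utils::read.delim)
names(de) <- strains

pair_files <- Sys.glob("results/pairs_*.tsv")
pair_records <- lapply(pair_files, utils::read.delim)
names(pair_records) <- vapply(pair_files, function(f) {
  paste(strsplit(sub("^pairs_(.*)\\.tsv$", "\\1", basename(f)), "_")[[1]],
        collapse = "|")
}, character(1))

analyzed <- de[[1]]$gene_id
expressed <- stats::setNames(rep(list(analyzed), length(strains)), strains)
target_sets <- build_target_sets(conservation, expressed)
cascade <- run_tf_cascade(target_sets, de, pair_records)

cat("TFs excluded (<3 targets in some strain):",
    paste(cascade$excluded, collapse = ", "), "\n")
cat("Candidates (KW Bonferroni p < 0.05):",
    paste(cascade$candidates, collapse = ", "), "\n")
cat("High-confidence (pair-specific enrichment in >= 1 pair):",
    paste(cascade$high_confidence, collapse = ", "), "\n")

utils::write.table(cascade$kw, "results/tf_kw.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(cascade$wilcoxon, "results/tf_wilcoxon.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(cascade$enrichment, "results/tf_enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(tf_name = rownames(cascade$labels),
                              cascade$labels, check.names = FALSE),
                   "results/tf_labels.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

if (nrow(cascade$labels) >= 2) {
  cl <- cluster_tfs(cascade$labels)
  cat("Label-clustering leaf order:", paste(cl$leaf_order, collapse = " "), "\n")
}

# GO enrichment of each high-confidence TF's targets (the generator
# plants one regulon-specific term per TF, so its targets should
# recover it)
go_map <- read_go_map("results/data/go_map.tsv")
for (tf in cascade$high_confidence) {
  res <- go_enrichment(target_sets[[tf]][[1]], go_map, analyzed)
  top <- res[1, ]
  cat(sprintf("  %s: top GO term %s (k=%d/K=%d, adj p = %.3g)\n",
              tf, top$term_id, top$k, top$K, top$adj_p))
}

# chaperone-client enrichment at the published overlap counts
universe <- sprintf("TF%03d", 1:187)
ce <- client_enrichment(c(universe[1:7], universe[101:114]),
                        universe[1:23], universe)
cat(sprintf("Client-TF enrichment at 7/21 vs 23/187: P(X>k) = %.4g, P(X>=k) = %.4g\n",
            ce$p_gt, ce$p_ge))
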