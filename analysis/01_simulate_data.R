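#!/usr/bin/env Rscript
# Simulate the study-design data set: 5 strains x (treated, untreated) x
# 3 replicates, 2000 genes, 20 TFs with 30-gene regulons, 5 responsive
# (TF, strain) pairs planted at log2 effect 1.5. Writes per-strain
# genome FASTA, gene table, PWM library, counts + sample sheet, GO map
# and the ground truth under results/data/.

suppressMessages(library(hsp90regulon))

cfg <- sim_config(seed = 1, planted_tfs = data.frame(
  tf = c("TF03", "TF07", "TF11", "TF15", "TF19"),
  strain = c("strain02", "strain03", "strain04", "strain05", "strain05"),
  log2_effect = 1.5))

out <- simulate_experiment(cfg, "results/data")

cat("Simulated", cfg$n_genes, "genes x", nrow(out$expt$samples), "samples for",
    cfg$n_strains, "strains\n")
cat("Planted responsive TF-strain pairs:\n")
print(out$expt$planted)
cat("Motif instances planted:", nrow(out$fixture$truth$motifs),
    "| variant:", sum(out$fixture$truth$motifs$event == "variant"),
    "| lost:", sum(out$fixture$truth$motifs$event == "lost"), "\n")
cat("Files written under results/data/\n")
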