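# Orchestration: simulate -> scan -> DE -> pairs -> TF cascade ->
# trees -> GO, with a machine-readable run report.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] describing the synthetic data (its seed
#'   is the pipeline seed).
#' @param alpha Adjusted-p threshold used by every stage (default 0.05).
#' @param fc_cutoff DE fold-change cutoff (default 2).
#' @param ratio_cutoff Pair-specific fold-change-ratio cutoff (default 2).
#' @param min_count Gene count filter threshold (default 5).
#' @param min_targets TF regulon-size exclusion threshold (default 3).
#' @param conservation_window Motif grouping window in alignment columns
#'   (default 20).
#' @param include_variant_motifs Count conserved-with-variation motifs
#'   as targets (default TRUE).
#' @param require_de_for_pairs Restrict pair-specific genes to genes DE
#'   in >= 1 strain of the pair (default TRUE).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), alpha = 0.05,
                            fc_cutoff = 2.0, ratio_cutoff = 2.0,
                            min_count = 5L, min_targets = 3L,
                            conservation_window = 20L,
                            include_variant_motifs = TRUE,
                            require_de_for_pairs = TRUE) {
  stopifnot(alpha > 0, alpha < 1, fc_cutoff > 1, ratio_cutoff > 1)
  structure(list(sim = sim, alpha = alpha, fc_cutoff = fc_cutoff,
                 ratio_cutoff = ratio_cutoff, min_count = min_count,
                 min_targets = min_targets,
                 conservation_window = conservation_window,
                 include_variant_motifs = include_variant_motifs,
                 require_de_for_pairs = require_de_for_pairs,
                 seed = sim$seed),
            class = "pipeline_config")
}

#' Build the count-independent motif fixture
#'
#' Simulates the per-strain genomes, extracts promoters through the gene
#' table, scans them with the PWM library on both strands, aligns each
#' gene's promoters across strains and classifies motif conservation.
#'
#' @param config A [pipeline_config()].
#' @return List: sim fixture plus `promoters`, `hits`, `conservation`.
#' @export
build_motif_fixture <- function(config) {
  fx <- simulate_promoters(config$sim)
  strains <- names(fx$genomes)
  promoters <- lapply(strains, function(st) {
    vapply(seq_len(nrow(fx$gene_table)), function(i) {
      as.character(extract_promoter(fx$genomes[[st]], fx$gene_table[i, ],
                                    config$sim$promoter_len))
    }, character(1L)) |> stats::setNames(fx$gene_table$gene_id)
  })
  names(promoters) <- strains
  hits <- do.call(rbind, lapply(strains, function(st) {
    scan_promoters(promoters[[st]], fx$pwms, st)
  }))
  cons <- do.call(rbind, lapply(fx$gene_table$gene_id, function(g) {
    h <- hits[hits$gene_id == g, , drop = FALSE]
    if (nrow(h) == 0L) return(NULL)
    aln <- align_promoters(vapply(promoters, `[[`, character(1L), g))
    classify_conservation(h, aln, config$conservation_window)
  }))
  fx$promoters <- promoters
  fx$hits <- hits
  fx$conservation <- cons
  fx
}

#' Run the expression stages on a motif fixture
#'
#' Simulates counts at `seed`, filters genes, tests per-strain
#' differential expression, classifies strain-pair-specific genes and
#' runs the TF cascade against the fixture's conserved-motif target
#' sets.
#'
#' @param fixture Output of [build_motif_fixture()].
#' @param config A [pipeline_config()].
#' @param seed Count-stream seed (default `config$seed + 1`).
#' @return List: expt, de (per strain), pairs (per strain pair),
#'   target_sets, cascade, analyzed_genes, planted.
#' @export
run_expression_stage <- function(fixture, config, seed = NULL) {
  expt <- simulate_counts(config$sim, fixture$truth, seed)
  filt <- filter_genes(expt, config$min_count)
  sf <- size_factors(filt)
  strains <- unique(filt$samples$strain)
  de <- lapply(strains, function(st) {
    de_test(filt, st, config$alpha, config$fc_cutoff, sf)
  })
  names(de) <- strains
  pairs <- strain_pairs(strains)
  pair_records <- lapply(pairs, function(pr) {
    st <- split_pair(pr)
    pair_specific(de[[st[1L]]], de[[st[2L]]], config$ratio_cutoff,
                  config$require_de_for_pairs)
  })
  names(pair_records) <- pairs
  expressed <- stats::setNames(rep(list(rownames(filt$counts)), length(strains)),
                               strains)
  target_sets <- build_target_sets(fixture$conservation, expressed,
                                   config$include_variant_motifs)
  cascade <- run_tf_cascade(target_sets, de, pair_records,
                            config$min_targets, config$alpha)
  list(expt = expt, filtered = filt, de = de, pairs = pair_records,
       target_sets = target_sets, cascade = cascade,
       analyzed_genes = rownames(filt$counts), planted = expt$planted)
}

#' Run the whole pipeline on one configuration
#'
#' Executes simulate -> promoter scan -> conservation -> DE ->
#' pair-specific classification -> TF cascade -> distance trees -> GO
#' enrichment, and assembles a run report of per-stage record counts.
#' Reruns with the same configuration are identical.
#'
#' @param config A [pipeline_config()].
#' @return List with `report` (named counts, config echo) and `results`
#'   (all stage outputs).
#' @export
run_all <- function(config) {
  fixture <- build_motif_fixture(config)
  expr <- run_expression_stage(fixture, config)

  # genetic distance: concatenated promoter alignment across strains
  concat <- vapply(fixture$promoters, paste, character(1L), collapse = "")
  genetic_d <- tn93_distance(concat)
  lens <- stats::setNames(fixture$gene_table$end - fixture$gene_table$start + 1L,
                          fixture$gene_table$gene_id)
  tpm_mat <- tpm(expr$filtered, lens)
  expr_d_untreated <- expression_distance(tpm_mat, expr$filtered$samples, "untreated")
  expr_d_treated <- expression_distance(tpm_mat, expr$filtered$samples, "treated")
  trees <- list(
    genetic = bionj(genetic_d),
    expression_untreated = bionj(expr_d_untreated),
    expression_treated = bionj(expr_d_treated))
  rho_untreated <- compare_matrices(genetic_d, expr_d_untreated)
  rho_treated <- compare_matrices(genetic_d, expr_d_treated)

  go_map <- simulate_go_map(config$sim, fixture$truth)
  go <- lapply(expr$de, function(d) {
    de_genes <- d$gene_id[d$is_de]
    if (!length(de_genes)) {
      return(data.frame(term_id = character(0), k = integer(0), K = integer(0),
                        n = integer(0), N = integer(0), p = numeric(0),
                        adj_p = numeric(0), significant = logical(0)))
    }
    go_enrichment(de_genes, go_map, expr$analyzed_genes, config$alpha)
  })

  cons_counts <- table(factor(fixture$conservation$class,
                              c("conserved", "conserved_with_variation",
                                "non_conserved")))
  pair_counts <- lapply(expr$pairs, function(pr) {
    cls <- table(factor(pr$bp_class, c("buffered", "potentiated", "tie", "none")))
    list(pair_specific = sum(pr$is_pair_specific),
         buffered = unname(cls[["buffered"]]),
         potentiated = unname(cls[["potentiated"]]),
         tie = unname(cls[["tie"]]))
  })
  report <- list(
    seed = config$seed,
    n_genes_simulated = config$sim$n_genes,
    n_genes_analyzed = length(expr$analyzed_genes),
    n_de_per_strain = vapply(expr$de, function(d) sum(d$is_de), integer(1L)),
    pair_counts = pair_counts,
    n_tfbs_hits = nrow(fixture$hits),
    conservation_classes = as.list(cons_counts),
    n_tfs_excluded = length(expr$cascade$excluded),
    n_tfs_tested = nrow(expr$cascade$kw),
    n_candidates = length(expr$cascade$candidates),
    n_high_confidence = length(expr$cascade$high_confidence),
    n_go_significant = vapply(go, function(g) sum(g$significant), integer(1L)),
    rho_genetic_vs_expression_untreated = rho_untreated,
    rho_genetic_vs_expression_treated = rho_treated,
    config = config[setdiff(names(config), "sim")])
  list(report = report,
       results = list(fixture = fixture, expression = expr,
                      distances = list(genetic = genetic_d,
                                       expression_untreated = expr_d_untreated,
                                       expression_treated = expr_d_treated),
                      trees = trees, go = go, go_map = go_map))
}

#' Rerun the DE-to-TF stages over a grid of fold-change cutoffs
#'
#' Counts are simulated once; the DE test, pair classification and TF
#' cascade are repeated per cutoff. Reports the per-cutoff DE sets
#' (nested by construction for fixed p-values) and the overlap of
#' high-confidence TF lists.
#'
#' @param config A [pipeline_config()].
#' @param cutoffs Fold-change cutoffs (default 1.5, 2, 2.5).
#' @return List: per-cutoff stage results, `high_confidence` per cutoff,
#'   and `stable_tfs` (TFs high-confidence at every cutoff).
#' @export
sweep_fc_cutoffs <- function(config, cutoffs = c(1.5, 2.0, 2.5)) {
  stopifnot(all(cutoffs > 1))
  fixture <- build_motif_fixture(config)
  runs <- lapply(cutoffs, function(fc) {
    cfg <- config
    cfg$fc_cutoff <- fc
    run_expression_stage(fixture, cfg)
  })
  names(runs) <- as.character(cutoffs)
  hc <- lapply(runs, function(r) r$cascade$high_confidence)
  list(runs = runs, high_confidence = hc,
       stable_tfs = Reduce(intersect, hc))
}
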