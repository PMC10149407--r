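# Synthetic genome + transcriptome generator emulating the study design:
# five diverged strains, two conditions (Hsp90 inhibitor treated /
# untreated), three biological replicates, promoters carrying planted TF
# binding motifs whose regulons respond to treatment in a strain-specific
# way. All ground truth is recorded so recovery is testable end to end.

#' Simulation configuration
#'
#' Defaults mirror the emulated study design: 5 strains x 2 conditions x
#' 3 replicates, 2000 genes, 20 TFs with 30 targets each, 5 responsive
#' (TF, strain) pairs planted at log2 effect 1.5 on treated means, NB
#' counts with variance `mu + alpha mu^2` at a shared dispersion
#' alpha = 0.05. `planted_tfs` is either a data frame (tf, strain,
#' log2_effect) or an integer: that many (TF, strain) pairs are drawn at
#' count-simulation time at effect `planted_effect`.
#'
#' @param n_strains,n_genes,n_replicates,n_tfs,targets_per_tf Design sizes.
#' @param promoter_len,motif_len Promoter and motif lengths (bp).
#' @param snp_rate Per-bp substitution rate per strain (background SNPs
#'   never fall inside planted motif footprints; motif fate is governed
#'   by the two rates below).
#' @param motif_variant_rate Probability a planted instance carries, in
#'   one random strain, a substitution that keeps its score above cutoff.
#' @param motif_loss_rate Probability a planted instance is scrambled
#'   below cutoff in one random strain.
#' @param base_mean_log_mu,base_mean_log_sd Log-normal law of baseline
#'   count means (natural-log scale).
#' @param dispersion Shared NB dispersion alpha.
#' @param libsize_log_sd Log-normal spread of library-size factors.
#' @param planted_tfs Responsive (TF, strain) pairs; see above.
#' @param planted_effect log2 treated-mean effect used when `planted_tfs`
#'   is an integer.
#' @param gene_len Coding-body length in bp (used for gene coordinates
#'   and TPM lengths).
#' @param seed Global seed; promoter draws use `seed`, count draws
#'   `seed + 1` (documented stream order).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_strains = 5L, n_genes = 2000L, n_replicates = 3L,
                       n_tfs = 20L, targets_per_tf = 30L,
                       promoter_len = 500L, motif_len = 12L,
                       snp_rate = 0.005, motif_variant_rate = 0.02,
                       motif_loss_rate = 0.02,
                       base_mean_log_mu = log(200), base_mean_log_sd = 1,
                       dispersion = 0.05, libsize_log_sd = 0.1,
                       planted_tfs = 5L, planted_effect = 1.5,
                       gene_len = 600L, seed = 1L) {
  stopifnot(n_strains >= 2L, n_genes >= 1L, n_replicates >= 1L,
            n_tfs >= 1L, targets_per_tf >= 1L,
            promoter_len >= 1L, motif_len >= 1L,
            snp_rate >= 0, snp_rate <= 1,
            motif_variant_rate >= 0, motif_loss_rate >= 0,
            motif_variant_rate + motif_loss_rate <= 1,
            dispersion > 0, gene_len >= 1L)
  if (motif_len >= promoter_len) stop("motif_len must be < promoter_len")
  if (!is.data.frame(planted_tfs) && planted_tfs > n_tfs * n_strains) {
    stop("planted_tfs cannot exceed n_tfs * n_strains")
  }
  structure(list(
    n_strains = n_strains, n_genes = n_genes, n_replicates = n_replicates,
    n_tfs = n_tfs, targets_per_tf = targets_per_tf,
    promoter_len = promoter_len, motif_len = motif_len,
    snp_rate = snp_rate, motif_variant_rate = motif_variant_rate,
    motif_loss_rate = motif_loss_rate,
    base_mean_log_mu = base_mean_log_mu, base_mean_log_sd = base_mean_log_sd,
    dispersion = dispersion, libsize_log_sd = libsize_log_sd,
    planted_tfs = planted_tfs, planted_effect = planted_effect,
    gene_len = gene_len, seed = seed,
    strains = sprintf("strain%02d", seq_len(n_strains)),
    genes = sprintf("g%04d", seq_len(n_genes)),
    tfs = sprintf("TF%02d", seq_len(n_tfs))), class = "sim_config")
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# a well-separated PWM: consensus base scores 1.2 (others -1.6) at every
# position except one degenerate position where an alternative base
# scores only 0.2 below the consensus base; cutoff = consensus - 1, so
# the designed variant stays a hit and any other substitution does not
make_pwm <- function(tf, L) {
  consensus <- sample(BASES, L, replace = TRUE)
  dpos <- sample.int(L, 1L)
  alt <- sample(setdiff(BASES, consensus[dpos]), 1L)
  ll <- matrix(-1.6, 4L, L, dimnames = list(BASES, NULL))
  ll[cbind(match(consensus, BASES), seq_len(L))] <- 1.2
  ll[consensus[dpos], dpos] <- 1.0
  ll[alt, dpos] <- 0.8
  cutoff <- sum(ll[cbind(match(consensus, BASES), seq_len(L))]) - 1.0
  p <- pwm(tf, ll, cutoff)
  p$consensus <- paste(consensus, collapse = "")
  p$degenerate_pos <- dpos
  p$alt_base <- alt
  p
}

#' Simulate per-strain promoters with planted, variant and lost motifs
#'
#' An ancestral promoter per gene receives background substitutions per
#' strain at `snp_rate` (outside motif footprints); each TF's consensus
#' is planted at a recorded position in each of its target genes; with
#' probability `motif_variant_rate` one random strain's instance receives
#' the tolerated degenerate-position substitution (still above cutoff),
#' otherwise with probability `motif_loss_rate` one random strain's
#' instance is scrambled below cutoff.
#'
#' @param cfg A [sim_config()].
#' @return List: `genomes` (strain -> named contig vector), `gene_table`,
#'   `pwms`, `truth` (tf_targets, motif events, responsive spec),
#'   `promoters` (strain -> gene-named promoter vector, for convenience).
#' @export
simulate_promoters <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$motif_len; P <- cfg$promoter_len
  pwms <- lapply(cfg$tfs, make_pwm, L = L)
  names(pwms) <- cfg$tfs
  tf_targets <- lapply(cfg$tfs, function(tf) sort(sample(cfg$genes, cfg$targets_per_tf)))
  names(tf_targets) <- cfg$tfs

  anc <- vapply(cfg$genes, function(g) random_dna(P), character(1L))
  # plant consensus motifs in the ancestral promoters, non-overlapping
  footprints <- stats::setNames(vector("list", cfg$n_genes), cfg$genes)
  plant <- list()
  for (tf in cfg$tfs) {
    cons <- pwms[[tf]]$consensus
    for (g in tf_targets[[tf]]) {
      occ <- footprints[[g]]
      for (try in 1:200) {
        s <- sample.int(P - L + 1L, 1L)
        if (!length(occ) || all(s + L - 1L < occ[, 1L] | s > occ[, 2L])) break
        s <- NA_integer_
      }
      if (is.na(s)) stop("could not place motif for ", tf, " in ", g,
                         "; promoter too crowded")
      substr(anc[[g]], s, s + L - 1L) <- cons
      footprints[[g]] <- rbind(occ, c(s, s + L - 1L))
      plant[[length(plant) + 1L]] <- data.frame(gene_id = g, tf_name = tf, start = s)
    }
  }
  plant <- do.call(rbind, plant)

  # per-strain copies: background SNPs outside footprints
  promoters <- lapply(cfg$strains, function(st) anc)
  names(promoters) <- cfg$strains
  if (cfg$snp_rate > 0) {
    for (st in cfg$strains) {
      for (g in cfg$genes) {
        prot <- logical(P)
        fp <- footprints[[g]]
        if (!is.null(fp)) for (r in seq_len(nrow(fp))) prot[fp[r, 1L]:fp[r, 2L]] <- TRUE
        n_mut <- stats::rbinom(1L, sum(!prot), cfg$snp_rate)
        if (n_mut > 0L) {
          at <- sample(which(!prot), n_mut)
          s <- promoters[[st]][[g]]
          for (i in at) {
            old <- substr(s, i, i)
            substr(s, i, i) <- sample(setdiff(BASES, old), 1L)
          }
          promoters[[st]][[g]] <- s
        }
      }
    }
  }

  # per-instance motif fate: tolerated variant or scrambling loss in one
  # random strain
  events <- character(nrow(plant)); events[] <- "intact"
  event_strain <- rep(NA_character_, nrow(plant))
  for (r in seq_len(nrow(plant))) {
    u <- stats::runif(1L)
    tf <- plant$tf_name[r]; g <- plant$gene_id[r]; s0 <- plant$start[r]
    pw <- pwms[[tf]]
    if (u < cfg$motif_variant_rate) {
      st <- sample(cfg$strains, 1L)
      seq <- promoters[[st]][[g]]
      dp <- s0 + pw$degenerate_pos - 1L
      substr(seq, dp, dp) <- pw$alt_base
      promoters[[st]][[g]] <- seq
      events[r] <- "variant"; event_strain[r] <- st
    } else if (u < cfg$motif_variant_rate + cfg$motif_loss_rate) {
      st <- sample(cfg$strains, 1L)
      seq <- promoters[[st]][[g]]
      repeat {
        scr <- random_dna(ncol(pw$loglik))
        if (score_window(pw, scr) <= pw$cutoff) break
      }
      substr(seq, s0, s0 + ncol(pw$loglik) - 1L) <- scr
      promoters[[st]][[g]] <- seq
      events[r] <- "lost"; event_strain[r] <- st
    }
  }
  plant$event <- events
  plant$event_strain <- event_strain

  # genome assembly: one contig per gene, promoter 5' of a fixed-length
  # coding body; strand drawn at random
  strands <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  body <- vapply(cfg$genes, function(g) paste0("ATG", random_dna(cfg$gene_len - 3L)),
                 character(1L))
  gene_table <- data.frame(
    gene_id = cfg$genes, seq_id = paste0("ctg_", cfg$genes),
    start = ifelse(strands == "+", P + 1L, 1L),
    end = ifelse(strands == "+", P + cfg$gene_len, cfg$gene_len),
    strand = strands, stringsAsFactors = FALSE)
  body_rc <- revcomp(body)
  genomes <- lapply(cfg$strains, function(st) {
    prom <- promoters[[st]][cfg$genes]
    prom_rc <- revcomp(prom)
    ctg <- ifelse(strands == "+",
                  paste0(prom, body),
                  paste0(body_rc, prom_rc))
    stats::setNames(ctg, paste0("ctg_", cfg$genes))
  })
  names(genomes) <- cfg$strains

  truth <- list(tf_targets = tf_targets, motifs = plant,
                responsive = if (is.data.frame(cfg$planted_tfs)) cfg$planted_tfs else NULL)
  list(genomes = genomes, gene_table = gene_table, pwms = pwms,
       truth = truth, promoters = promoters)
}

#' Simulate the count experiment from a ground truth
#'
#' Counts for gene g, strain s, condition c, replicate r are drawn
#' NB(mean mu_gsc * libsize, size 1/alpha) with
#' `log2 mu_treated - log2 mu_untreated` equal to the summed log2
#' effects of responsive TFs targeting g in s. When `cfg$planted_tfs` is
#' an integer, that many (TF, strain) pairs are drawn here (so each
#' count-level seed realizes its own responsive set).
#'
#' @param cfg A [sim_config()].
#' @param truth Ground truth from [simulate_promoters()].
#' @param seed Count-stream seed; defaults to `cfg$seed + 1`.
#' @return A [count_experiment()] with extra fields `planted` (the
#'   realized responsive pairs), `true_effects` (gene x strain log2
#'   matrix) and `true_size_factors`.
#' @export
simulate_counts <- function(cfg, truth, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(seed)) seed <- cfg$seed + 1L
  set.seed(seed)
  planted <- if (is.data.frame(cfg$planted_tfs)) {
    cfg$planted_tfs
  } else if (cfg$planted_tfs > 0L) {
    combos <- expand.grid(tf = cfg$tfs, strain = cfg$strains,
                          stringsAsFactors = FALSE)
    sel <- combos[sample.int(nrow(combos), cfg$planted_tfs), ]
    data.frame(tf = sel$tf, strain = sel$strain,
               log2_effect = cfg$planted_effect, row.names = NULL)
  } else {
    data.frame(tf = character(0), strain = character(0), log2_effect = numeric(0))
  }
  eff <- matrix(0, cfg$n_genes, cfg$n_strains,
                dimnames = list(cfg$genes, cfg$strains))
  if (nrow(planted)) {
    for (r in seq_len(nrow(planted))) {
      tg <- truth$tf_targets[[planted$tf[r]]]
      eff[tg, planted$strain[r]] <- eff[tg, planted$strain[r]] + planted$log2_effect[r]
    }
  }
  base <- stats::rlnorm(cfg$n_genes, cfg$base_mean_log_mu, cfg$base_mean_log_sd)
  samples <- expand.grid(replicate = seq_len(cfg$n_replicates),
                         condition = c("untreated", "treated"),
                         strain = cfg$strains, stringsAsFactors = FALSE)
  samples <- samples[, c("strain", "condition", "replicate")]
  samples$sample_id <- sprintf("%s_%s_r%d", samples$strain,
                               samples$condition, samples$replicate)
  libsf <- stats::rlnorm(nrow(samples), 0, cfg$libsize_log_sd)
  names(libsf) <- samples$sample_id
  size <- 1 / cfg$dispersion
  counts <- matrix(0L, cfg$n_genes, nrow(samples),
                   dimnames = list(cfg$genes, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mu <- base * libsf[j]
    if (samples$condition[j] == "treated") mu <- mu * 2^eff[, samples$strain[j]]
    counts[, j] <- stats::rnbinom(cfg$n_genes, mu = mu, size = size)
  }
  expt <- count_experiment(counts, samples[, c("sample_id", "strain",
                                               "condition", "replicate")])
  expt$planted <- planted
  expt$true_effects <- eff
  expt$true_size_factors <- libsf
  expt
}

#' Simulate a random GO annotation with one enriched term per regulon
#'
#' Every gene receives one to three background terms at random; in
#' addition, each TF's target set is annotated with a regulon-specific
#' term, so regulon-driven gene sets have a planted enrichment signal.
#'
#' @param cfg A [sim_config()].
#' @param truth Ground truth from [simulate_promoters()].
#' @param n_background Number of background GO terms.
#' @param seed Seed; defaults to `cfg$seed + 2`.
#' @return Named list gene_id -> character vector of term ids.
#' @export
simulate_go_map <- function(cfg, truth, n_background = 15L, seed = NULL) {
  if (is.null(seed)) seed <- cfg$seed + 2L
  set.seed(seed)
  bg <- sprintf("GO:B%03d", seq_len(n_background))
  go <- lapply(cfg$genes, function(g) sample(bg, sample(1:3, 1L)))
  names(go) <- cfg$genes
  for (tf in names(truth$tf_targets)) {
    term <- paste0("GO:R_", tf)
    for (g in truth$tf_targets[[tf]]) go[[g]] <- c(go[[g]], term)
  }
  go
}

#' Simulate an additive distance fixture with its generating tree
#'
#' A random unrooted topology with uniform branch lengths yields an
#' exactly additive patristic distance matrix, plus sequences evolved on
#' the tree under a Jukes-Cantor process.
#'
#' @param n_taxa Number of leaves (>= 3).
#' @param seed Seed.
#' @param seq_len Alignment length for the evolved sequences.
#' @return List: `tree` (ape phylo), `D` (additive matrix),
#'   `alignment` (named character vector).
#' @export
simulate_distance_fixture <- function(n_taxa, seed = 1L, seq_len = 2000L) {
  if (n_taxa < 3L) stop("n_taxa must be >= 3")
  set.seed(seed)
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(n) stats::runif(n, 0.02, 0.3))
  tree$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  D <- ape::cophenetic.phylo(tree)
  D <- D[tree$tip.label, tree$tip.label]
  aln <- evolve_jc(tree, seq_len)
  list(tree = tree, D = D, alignment = aln)
}

# evolve sequences down a tree under Jukes-Cantor; branch length d gives
# substitution probability 3/4 (1 - exp(-4d/3)) per site
evolve_jc <- function(tree, L) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", max(tree$edge))
  seqs[[root]] <- sample(BASES, L, replace = TRUE)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    p <- 0.75 * (1 - exp(-4 * ord$edge.length[e] / 3))
    s <- seqs[[par]]
    hit <- stats::runif(L) < p
    if (any(hit)) {
      s[hit] <- vapply(s[hit], function(b) sample(setdiff(BASES, b), 1L), character(1L))
    }
    seqs[[child]] <- s
  }
  out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""), character(1L))
  stats::setNames(out, tree$tip.label)
}

#' Write a complete simulated data set to disk
#'
#' Emits per-strain promoter/genome FASTA, the gene table, the PWM
#' library, counts and sample sheet TSVs, the GO map, and the ground
#' truth as JSON.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_experiment <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- simulate_promoters(cfg)
  expt <- simulate_counts(cfg, fx$truth)
  go <- simulate_go_map(cfg, fx$truth)
  for (st in names(fx$genomes)) {
    write_fasta(fx$genomes[[st]], file.path(dir, paste0("genome_", st, ".fa")))
  }
  write_gene_table(fx$gene_table, file.path(dir, "genes.tsv"))
  write_pwm_library(fx$pwms, file.path(dir, "pwms.txt"))
  write_counts(expt, file.path(dir, "counts.tsv"), file.path(dir, "samples.tsv"))
  write_go_map(go, file.path(dir, "go_map.tsv"))
  truth_out <- list(tf_targets = fx$truth$tf_targets,
                    motifs = fx$truth$motifs,
                    planted = expt$planted)
  jsonlite::write_json(truth_out, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(fixture = fx, expt = expt, go_map = go))
}
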