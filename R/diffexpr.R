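# Count filtering, normalization, simplified negative-binomial Wald
# test for treated/untreated fold changes, TPM, and classification of
# strain-pair-specific genes into buffered / potentiated classes.

#' Remove genes that are low everywhere (or carry missing values)
#'
#' A gene is dropped when its count is below `min_count` in every sample
#' (`mode = "max"`, the default: max over samples < min_count), or when
#' any sample is below `min_count` (`mode = "min"`). Genes with missing
#' values are always dropped.
#'
#' @param expt A [count_experiment()].
#' @param min_count Threshold (default 5).
#' @param mode `"max"` (drop genes low in all samples) or `"min"` (drop
#'   genes low in any sample).
#' @return Filtered [count_experiment()].
#' @export
filter_genes <- function(expt, min_count = 5L, mode = c("max", "min")) {
  mode <- match.arg(mode)
  stopifnot(inherits(expt, "count_experiment"), nrow(expt$counts) > 0L)
  m <- expt$counts
  ok <- !apply(is.na(m), 1L, any)
  keep <- if (mode == "max") apply(m, 1L, max) >= min_count
          else apply(m, 1L, min) >= min_count
  keep <- keep & ok
  if (!any(keep)) {
    stop("all genes removed by the count filter; review min_count = ", min_count)
  }
  expt$counts <- m[keep, , drop = FALSE]
  expt
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (expressed in every sample) of
#' the ratio of its count to the gene's geometric mean across samples.
#'
#' @param expt A [count_experiment()].
#' @return Named numeric vector, one factor per sample.
#' @export
size_factors <- function(expt) {
  m <- expt$counts
  pos <- apply(m > 0, 1L, all)
  if (!any(pos)) stop("no gene with nonzero counts in every sample")
  lg <- log(m[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2L, function(col) exp(stats::median(col - geo)))
  stats::setNames(sf, colnames(m))
}

# per-gene method-of-moments NB dispersion from normalized counts of
# one condition: alpha = (var - mean) / mean^2
mom_dispersion <- function(norm) {
  mu <- rowMeans(norm)
  v <- apply(norm, 1L, stats::var)
  a <- (v - mu) / mu^2
  a[!is.finite(a)] <- NA_real_
  a
}

# common dispersion: the mean of per-gene MoM values over well-measured
# genes (condition mean > 5). The mean, unlike the median, is an
# (asymptotically) unbiased moment estimator here: per-gene MoM values
# are right-skewed at small replicate numbers, so their median sits
# well below the true dispersion and would make the Wald test
# anti-conservative.
common_dispersion <- function(a_by_cond, m_by_cond, floor = 0.01) {
  keep <- is.finite(a_by_cond) & m_by_cond > 5
  est <- if (any(keep)) mean(a_by_cond[keep]) else NA_real_
  if (!is.finite(est)) est <- floor
  max(floor, est)
}

#' Per-gene treated/untreated fold change and NB Wald test for one strain
#'
#' Counts are normalized by median-of-ratios size factors computed on the
#' full experiment. Per gene, `log2fc = log2((m_t + 0.5)/(m_u + 0.5))`
#' with condition means of normalized counts; the Wald standard error
#' uses an NB variance (`mu + alpha mu^2`) with a method-of-moments
#' dispersion floored at 0.01 — by default the common dispersion pooled
#' across genes (`dispersion = "common"`; gene-wise estimates at 2-3
#' replicates are far too noisy to calibrate a Wald test), or gene-wise
#' estimates with `dispersion = "gene"`. P-values are Benjamini-Hochberg
#' adjusted across tested genes. A gene is differentially expressed when
#' `adj_p < alpha` and its fold change exceeds `fc_cut` or falls below
#' `1/fc_cut`.
#'
#' @param expt A (filtered) [count_experiment()].
#' @param strain Strain to test; needs >= 2 replicates per condition.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param fc_cut Fold-change threshold (default 2).
#' @param sf Optional precomputed size factors for all samples.
#' @param dispersion `"common"` (pooled across genes, default) or
#'   `"gene"` (per-gene).
#' @return Data frame: gene_id, strain, base_mean_untreated,
#'   base_mean_treated, log2fc, p, adj_p, is_de.
#' @export
de_test <- function(expt, strain, alpha = 0.05, fc_cut = 2.0, sf = NULL,
                    dispersion = c("common", "gene")) {
  dispersion <- match.arg(dispersion)
  stopifnot(inherits(expt, "count_experiment"))
  if (is.null(sf)) sf <- size_factors(expt)
  ss <- expt$samples
  sel_t <- ss$strain == strain & ss$condition == "treated"
  sel_u <- ss$strain == strain & ss$condition == "untreated"
  if (sum(sel_t) < 2L || sum(sel_u) < 2L) {
    stop("strain ", strain, " needs >= 2 replicates per condition")
  }
  nt <- expt$counts[, sel_t, drop = FALSE] /
    rep(sf[ss$sample_id[sel_t]], each = nrow(expt$counts))
  nu <- expt$counts[, sel_u, drop = FALSE] /
    rep(sf[ss$sample_id[sel_u]], each = nrow(expt$counts))
  mt <- rowMeans(nt); mu <- rowMeans(nu)
  log2fc <- log2((mt + 0.5) / (mu + 0.5))
  a_t <- mom_dispersion(nt); a_u <- mom_dispersion(nu)
  a_common <- common_dispersion(c(a_t, a_u), c(mt, mu))
  a <- if (dispersion == "common") {
    rep(a_common, length(mt))
  } else {
    ag <- rowMeans(cbind(a_t, a_u), na.rm = TRUE)
    ag[!is.finite(ag)] <- a_common
    pmax(ag, 0.01)
  }
  k_t <- ncol(nt); k_u <- ncol(nu)
  # delta-method variance of log2 of a pseudocounted NB mean
  var_l2 <- function(m, k) ((m + 0.5) + a * (m + 0.5)^2) / (k * (m + 0.5)^2) / log(2)^2
  se <- sqrt(var_l2(mt, k_t) + var_l2(mu, k_u))
  z <- log2fc / se
  p <- 2 * stats::pnorm(-abs(z))
  adj <- adjust_p(p, "bh")
  fc <- (mt + 0.5) / (mu + 0.5)
  data.frame(gene_id = rownames(expt$counts), strain = strain,
             base_mean_untreated = mu, base_mean_treated = mt,
             log2fc = log2fc, p = p, adj_p = adj,
             is_de = adj < alpha & (fc > fc_cut | fc < 1 / fc_cut),
             row.names = NULL)
}

#' Transcripts per million
#'
#' Per sample: length-normalized rates `count / (length/1000)` rescaled
#' to sum to 1e6.
#'
#' @param expt A [count_experiment()].
#' @param lengths Named vector of gene lengths in bp covering all genes.
#' @return Matrix of TPM values, same dimensions as the counts.
#' @export
tpm <- function(expt, lengths) {
  m <- expt$counts
  l <- lengths[rownames(m)]
  if (anyNA(l) || any(l <= 0)) stop("positive lengths required for all genes")
  rate <- m / (l / 1000)
  tot <- colSums(rate)
  if (any(tot == 0)) stop("zero total rate in a sample")
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Strain-pair-specific genes and buffered/potentiated classification
#'
#' For each gene shared by the two DE tables, the fold-change ratio
#' `FC_A / FC_B` (linear scale, pseudocounted means) flags the gene as
#' pair-specific when it exceeds `ratio_cut` or falls below
#' `1/ratio_cut`. With `require_de`, only genes differentially expressed
#' in at least one strain of the pair are eligible. Pair-specific genes
#' are classed `buffered` when the between-strain expression difference
#' is larger under treatment, `potentiated` when larger untreated, `tie`
#' when equal.
#'
#' @param deA,deB DE tables from [de_test()] for the two strains.
#' @param ratio_cut Fold-change-ratio threshold (default 2).
#' @param require_de Restrict to genes DE in >= 1 strain (default TRUE).
#' @return Data frame: gene_id, strain_a, strain_b, fc_ratio,
#'   is_pair_specific, bp_class.
#' @export
pair_specific <- function(deA, deB, ratio_cut = 2.0, require_de = TRUE) {
  common <- intersect(deA$gene_id, deB$gene_id)
  only <- union(setdiff(deA$gene_id, deB$gene_id), setdiff(deB$gene_id, deA$gene_id))
  if (length(only)) {
    warning(length(only), " gene(s) present in one strain only were skipped")
  }
  a <- deA[match(common, deA$gene_id), ]
  b <- deB[match(common, deB$gene_id), ]
  fc_a <- (a$base_mean_treated + 0.5) / (a$base_mean_untreated + 0.5)
  fc_b <- (b$base_mean_treated + 0.5) / (b$base_mean_untreated + 0.5)
  ratio <- fc_a / fc_b
  eligible <- if (require_de) a$is_de | b$is_de else rep(TRUE, length(common))
  is_ps <- eligible & (ratio > ratio_cut | ratio < 1 / ratio_cut)
  dplus <- abs(log2(a$base_mean_treated + 0.5) - log2(b$base_mean_treated + 0.5))
  dminus <- abs(log2(a$base_mean_untreated + 0.5) - log2(b$base_mean_untreated + 0.5))
  bp <- ifelse(!is_ps, "none",
        ifelse(dplus > dminus, "buffered",
        ifelse(dplus < dminus, "potentiated", "tie")))
  data.frame(gene_id = common,
             strain_a = a$strain[1L], strain_b = b$strain[1L],
             fc_ratio = ratio, is_pair_specific = is_ps, bp_class = bp,
             row.names = NULL)
}

#' Buffered / potentiated call for a single pair-specific gene
#'
#' `D+` is the absolute difference of log2 pseudocounted treated means
#' between the strains, `D-` the untreated analogue; buffered when
#' `D+ > D-`, potentiated when `D+ < D-`, tie when equal.
#'
#' @param meanA_treated,meanA_untreated Normalized condition means, strain A.
#' @param meanB_treated,meanB_untreated Normalized condition means, strain B.
#' @return `"buffered"`, `"potentiated"` or `"tie"`.
#' @export
classify_buffered_potentiated <- function(meanA_treated, meanA_untreated,
                                          meanB_treated, meanB_untreated) {
  dplus <- abs(log2(meanA_treated + 0.5) - log2(meanB_treated + 0.5))
  dminus <- abs(log2(meanA_untreated + 0.5) - log2(meanB_untreated + 0.5))
  if (dplus > dminus) "buffered" else if (dplus < dminus) "potentiated" else "tie"
}
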