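# Independent oracles used across test files.

# full Needleman-Wunsch DP (match +1, mismatch -1, linear gap -2),
# score only
nw_score_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  F <- matrix(0, n + 1L, m + 1L)
  F[, 1L] <- -2 * (0:n)
  F[1L, ] <- -2 * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) 1 else -1
      F[i + 1L, j + 1L] <- max(F[i, j] + s, F[i, j + 1L] - 2, F[i + 1L, j] - 2)
    }
  }
  F[n + 1L, m + 1L]
}

# exhaustive window-enumeration motif scan oracle using score_window
scan_oracle <- function(pw, promoter) {
  L <- ncol(pw$loglik)
  P <- nchar(promoter)
  if (P < L) {
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), site_seq = character(0)))
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(promoter)))
  rows <- list()
  for (i in seq_len(P - L + 1L)) {
    w <- substr(promoter, i, i + L - 1L)
    s <- score_window(pw, w)
    if (!is.na(s) && s > pw$cutoff) {
      rows[[length(rows) + 1L]] <- data.frame(
        offset = P - i - L + 2L, strand = "+", score = s, site_seq = w)
    }
    wr <- substr(rc, i, i + L - 1L)
    sr <- score_window(pw, wr)
    if (!is.na(sr) && sr > pw$cutoff) {
      cs <- P - i - L + 2L
      rows[[length(rows) + 1L]] <- data.frame(
        offset = i, strand = "-", score = sr,
        site_seq = substr(promoter, cs, cs + L - 1L))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(offset = integer(0), strand = character(0),
               score = numeric(0), site_seq = character(0))
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# P(X >= k) for a hypergeometric draw by exhaustive subset enumeration
hyper_ge_oracle <- function(k, K, n, N) {
  marked <- seq_len(K)
  subsets <- utils::combn(N, n)
  mean(apply(subsets, 2L, function(s) sum(s %in% marked) >= k))
}

random_promoter <- function(n, p_n = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

random_pwm <- function(name, L, cutoff = NULL) {
  ll <- matrix(stats::rnorm(4 * L), 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  if (is.null(cutoff)) cutoff <- stats::quantile(colSums(apply(ll, 2, sort)), 0.5)
  pwm(name, ll, sum(apply(ll, 2, max)) * 0.3)
}

# small pipeline configuration used by several files (fast to build)
small_pipeline_config <- function(seed = 42L, planted = 2L, ...) {
  pipeline_config(sim = sim_config(
    n_genes = 80L, n_tfs = 4L, targets_per_tf = 8L, n_strains = 3L,
    promoter_len = 120L, motif_len = 10L, snp_rate = 0.005,
    planted_tfs = planted, seed = seed, ...))
}

# builds an aligned sequence pair with exact substitution-type counts
# and equal base frequencies: n_match identical sites (ACGT balanced),
# n_ag A<->G transitions, n_ct C<->T transitions, n_tv transversions
# (balanced over A/T, C/G pairs), all direction-balanced
balanced_pair <- function(n_match, n_ag, n_ct, n_tv) {
  stopifnot(n_match %% 4 == 0, n_tv %% 4 == 0, n_ag == n_ct)
  a <- c(rep(c("A", "C", "G", "T"), n_match / 4),
         rep("A", n_ag / 2), rep("G", n_ag / 2),
         rep("C", n_ct / 2), rep("T", n_ct / 2),
         rep(c("A", "T", "C", "G"), n_tv / 4))
  b <- c(rep(c("A", "C", "G", "T"), n_match / 4),
         rep("G", n_ag / 2), rep("A", n_ag / 2),
         rep("T", n_ct / 2), rep("C", n_ct / 2),
         rep(c("T", "A", "G", "C"), n_tv / 4))
  c(x = paste(a, collapse = ""), y = paste(b, collapse = ""))
}

tn93_formula <- function(p1, p2, q, g = c(A = .25, C = .25, G = .25, T = .25)) {
  gR <- g["A"] + g["G"]; gY <- g["C"] + g["T"]
  k1 <- 2 * g["A"] * g["G"] / gR
  k2 <- 2 * g["T"] * g["C"] / gY
  k3 <- 2 * (gR * gY - g["A"] * g["G"] * gY / gR - g["T"] * g["C"] * gR / gY)
  unname(-k1 * log(1 - p1 / k1 - q / (2 * gR)) -
           k2 * log(1 - p2 / k2 - q / (2 * gY)) -
           k3 * log(1 - q / (2 * gR * gY)))
}

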