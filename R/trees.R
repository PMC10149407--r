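# Genetic (TN93) and expression (Euclidean on TPM/1000) distances and
# BIONJ tree construction.

#' Tamura-Nei (1993) pairwise distances with pairwise deletion
#'
#' For each pair of aligned sequences, sites where either sequence is
#' not A/C/G/T are dropped; base frequencies are averaged over the two
#' sequences at the retained sites; the two transition proportions
#' (A<->G and C<->T) and the transversion proportion enter the TN93
#' closed form.
#'
#' @param aln Named character vector of equal-length aligned sequences
#'   (>= 2 taxa). Gaps (`-`) and N are deleted pairwise.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
tn93_distance <- function(aln) {
  stopifnot(length(aln) >= 2L)
  if (length(unique(nchar(aln))) != 1L) stop("sequences must be aligned (equal lengths)")
  labs <- names(aln)
  chars <- lapply(aln, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  k <- length(aln)
  D <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      D[i, j] <- D[j, i] <- tn93_pair(chars[[i]], chars[[j]], labs[i], labs[j])
    }
  }
  D
}

tn93_pair <- function(a, b, la, lb) {
  use <- a %in% BASES & b %in% BASES
  a <- a[use]; b <- b[use]
  n <- length(a)
  if (n == 0L) stop("no comparable sites between ", la, " and ", lb)
  freq <- (table(factor(a, BASES)) + table(factor(b, BASES))) / (2 * n)
  gA <- freq[["A"]]; gC <- freq[["C"]]; gG <- freq[["G"]]; gT <- freq[["T"]]
  gR <- gA + gG; gY <- gC + gT
  diff <- a != b
  p1 <- sum(diff & ((a == "A" & b == "G") | (a == "G" & b == "A"))) / n
  p2 <- sum(diff & ((a == "C" & b == "T") | (a == "T" & b == "C"))) / n
  q <- sum(diff) / n - p1 - p2
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  w1 <- 1 - p1 / k1 - q / (2 * gR)
  w2 <- 1 - p2 / k2 - q / (2 * gY)
  w3 <- 1 - q / (2 * gR * gY)
  if (any(!is.finite(c(w1, w2, w3))) || w1 <= 0 || w2 <= 0 || w3 <= 0) {
    stop("TN93 saturation between ", la, " and ", lb)
  }
  -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
}

#' Euclidean expression distance between strains
#'
#' Per strain, replicate-mean TPM in the requested condition divided by
#' 1000; pairwise Euclidean distances between the resulting profiles.
#'
#' @param tpm_mat TPM matrix (genes x samples) from [tpm()].
#' @param samples Sample sheet covering the TPM columns.
#' @param condition `"treated"` or `"untreated"`.
#' @return Symmetric distance matrix over strains.
#' @export
expression_distance <- function(tpm_mat, samples, condition) {
  strains <- unique(samples$strain)
  prof <- vapply(strains, function(st) {
    sel <- samples$strain == st & samples$condition == condition
    if (!any(sel)) stop("strain ", st, " has no samples in condition ", condition)
    rowMeans(tpm_mat[, samples$sample_id[sel], drop = FALSE]) / 1000
  }, numeric(nrow(tpm_mat)))
  as.matrix(stats::dist(t(prof), method = "euclidean"))
}

#' BIONJ tree from a distance matrix
#'
#' Neighbor joining with Gascuel's variance-weighted reduction: at each
#' agglomeration the mixing weight lambda minimizes the variance of the
#' reduced matrix. Negative branch lengths are clamped to zero with the
#' deficit transferred to the sibling branch.
#'
#' @param D Symmetric distance matrix with labels (>= 3 taxa).
#' @return Unrooted `ape::phylo` tree with branch lengths.
#' @export
bionj <- function(D) {
  D <- as.matrix(D)
  labs <- rownames(D)
  n <- nrow(D)
  if (n < 3L) stop("need >= 3 taxa")
  stopifnot(isSymmetric(unname(D), tol = 1e-8))
  V <- D                                   # variance estimates
  node <- labs                             # newick fragment per active cluster
  repeat {
    m <- nrow(D)
    if (m == 3L) break
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- arrayInd(which.min(Q), dim(Q))
    i <- min(ij); j <- max(ij)
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    keep <- setdiff(seq_len(m), c(i, j))
    lambda <- if (V[i, j] > 0) {
      0.5 + sum(V[j, keep] - V[i, keep]) / (2 * (m - 2) * V[i, j])
    } else 0.5
    lambda <- min(1, max(0, lambda))
    du <- lambda * (D[i, keep] - bi) + (1 - lambda) * (D[j, keep] - bj)
    vu <- lambda * V[i, keep] + (1 - lambda) * V[j, keep] -
      lambda * (1 - lambda) * V[i, j]
    newnode <- sprintf("(%s:%.12g,%s:%.12g)", node[i], bi, node[j], bj)
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du), c(du, 0))
    V <- rbind(cbind(V[keep, keep, drop = FALSE], vu), c(vu, 0))
    node <- c(node[keep], newnode)
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  bs <- pmax(c(b1, b2, b3), 0)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 node[1], bs[1], node[2], bs[2], node[3], bs[3])
  ape::read.tree(text = nwk)
}

#' Spearman correlation of two distance matrices
#'
#' Strictly-lower-triangle entries paired by label.
#'
#' @param D1,D2 Labeled symmetric matrices over the same taxa.
#' @return Spearman rho.
#' @export
compare_matrices <- function(D1, D2) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  labs <- rownames(D1)
  if (is.null(labs) || !setequal(labs, rownames(D2))) {
    stop("matrices must share the same labels")
  }
  D2 <- D2[labs, labs]
  lt <- lower.tri(D1)
  spearman(D1[lt], D2[lt])
}
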