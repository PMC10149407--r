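# Promoter extraction, PWM scanning on both strands, cross-strain
# conservation classification of predicted TF binding sites.

BASES <- c("A", "C", "G", "T")

revcomp <- function(s) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
  names(out) <- names(s)
  out
}

# reverse-complemented PWM: scanning the forward strand with it is
# equivalent to scanning the reverse strand with the original
revcomp_pwm_matrix <- function(loglik) {
  rc <- loglik[4:1, ncol(loglik):1, drop = FALSE]
  dimnames(rc) <- dimnames(loglik)
  rc
}

seq_to_index <- function(s) {
  # A=1 C=2 G=3 T=4, N (or anything else) = NA
  m <- match(strsplit(s, "", fixed = TRUE)[[1L]], BASES)
  m
}

#' Extract the promoter of a gene from its genome
#'
#' Returns the `promoter_len` bases immediately 5' of the translation
#' start on the coding strand; for minus-strand genes this is the reverse
#' complement of the bases just 3' of `end` in genome coordinates. If the
#' contig offers fewer bases the available prefix is returned and the
#' result carries attribute `truncated = TRUE`.
#'
#' @param genome Named character vector of contig sequences.
#' @param gene One-row data frame (or list) with gene_id, seq_id, start,
#'   end, strand.
#' @param promoter_len Promoter length in bp (default 500).
#' @return Promoter string (coding-strand orientation) with attribute
#'   `truncated`.
#' @export
extract_promoter <- function(genome, gene, promoter_len = 500L) {
  idx <- match(as.character(gene$seq_id), names(genome))
  if (is.na(idx)) stop("seq_id not in genome: ", gene$seq_id)
  contig <- genome[[idx]]
  len <- nchar(contig)
  if (gene$strand == "+") {
    to <- gene$start - 1L
    from <- max(1L, gene$start - promoter_len)
    p <- if (to >= from) substr(contig, from, to) else ""
  } else {
    from <- gene$end + 1L
    to <- min(len, gene$end + promoter_len)
    p <- if (to >= from) revcomp(substr(contig, from, to)) else ""
  }
  attr(p, "truncated") <- nchar(p) < promoter_len
  p
}

#' Score one window under a PWM
#'
#' Sum of per-position log-likelihoods of the window's bases. A window
#' containing N has no defined score and returns NA.
#'
#' @param pwm A [pwm()] object.
#' @param window DNA string of exactly the motif length.
#' @return Numeric score, or NA for windows containing N.
#' @export
score_window <- function(pwm, window) {
  L <- ncol(pwm$loglik)
  stopifnot(nchar(window) == L)
  idx <- seq_to_index(window)
  if (anyNA(idx)) return(NA_real_)
  sum(pwm$loglik[cbind(idx, seq_len(L))])
}

# scores of all windows of one strand; returns numeric vector indexed by
# window start (NA where the window contains N)
scan_strand_scores <- function(loglik, idx) {
  L <- ncol(loglik)
  P <- length(idx)
  nw <- P - L + 1L
  if (nw < 1L) return(numeric(0))
  s <- numeric(nw)
  na <- logical(nw)
  for (j in seq_len(L)) {
    b <- idx[j:(j + nw - 1L)]
    na <- na | is.na(b)
    v <- loglik[cbind(b, j)]
    v[is.na(v)] <- 0
    s <- s + v
  }
  s[na] <- NA_real_
  s
}

#' Scan a promoter with a PWM on both strands
#'
#' Every window (stepping one base) on the forward and reverse strands is
#' scored; windows scoring strictly above the PWM cutoff are reported at
#' coding-strand coordinates. `upstream_offset` is the 1-based distance
#' from the translation start to the hit base nearest it (the promoter's
#' 3'-most base has offset 1). Windows containing N are skipped.
#'
#' @param pwm A [pwm()] object.
#' @param promoter Promoter string, 5' to 3' on the coding strand.
#' @return Data frame with columns offset, strand, score, site_seq,
#'   sorted by offset. Empty (with a warning) if the promoter is shorter
#'   than the motif.
#' @export
scan_promoter <- function(pwm, promoter) {
  L <- ncol(pwm$loglik)
  P <- nchar(promoter)
  empty <- data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), site_seq = character(0))
  if (P < L) {
    warning("promoter shorter than motif; no windows scanned")
    return(empty)
  }
  idx <- seq_to_index(promoter)
  fwd <- scan_strand_scores(pwm$loglik, idx)
  rev <- scan_strand_scores(pwm$loglik, rev(5L - idx))  # revcomp in index space
  hits <- list()
  starts_f <- which(!is.na(fwd) & fwd > pwm$cutoff)
  if (length(starts_f)) {
    hits[[1L]] <- data.frame(
      offset = P - starts_f - L + 2L, strand = "+", score = fwd[starts_f],
      site_seq = substring(promoter, starts_f, starts_f + L - 1L))
  }
  starts_r <- which(!is.na(rev) & rev > pwm$cutoff)
  if (length(starts_r)) {
    # window i on the reverse complement covers coding positions
    # (P - i - L + 2) .. (P - i + 1)
    cs <- P - starts_r - L + 2L
    hits[[2L]] <- data.frame(
      offset = P - cs - L + 2L, strand = "-", score = rev[starts_r],
      site_seq = substring(promoter, cs, cs + L - 1L))
  }
  out <- if (length(hits)) do.call(rbind, hits) else empty
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of promoters with a PWM library
#'
#' Equivalent to [scan_promoter()] over every promoter and PWM, but
#' scores all windows in bulk: the promoters are concatenated with N
#' spacers into one subject, scored once per PWM and strand (the
#' reverse strand via the reverse-complemented matrix), and windows
#' touching an N or a spacer are masked out.
#'
#' @param promoters Named character vector gene_id -> promoter string.
#' @param pwms List of [pwm()] objects.
#' @param strain Strain name recorded in the output.
#' @return Data frame gene_id, strain, tf_name, offset, strand, score,
#'   site_seq.
#' @export
scan_promoters <- function(promoters, pwms, strain = NA_character_) {
  empty <- data.frame(gene_id = character(0), strain = character(0),
                      tf_name = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      site_seq = character(0))
  promoters <- promoters[nchar(promoters) > 0L]
  if (!length(promoters) || !length(pwms)) return(empty)
  maxL <- max(vapply(pwms, function(p) ncol(p$loglik), integer(1L)))
  spacer <- strrep("N", maxL)
  big <- paste(promoters, collapse = spacer)
  plens <- nchar(promoters)
  gene_start <- cumsum(c(1L, utils::head(plens + maxL, -1L)))  # subject pos of each promoter
  gene_of <- rep(seq_along(promoters), plens + c(rep(maxL, length(promoters) - 1L), 0L))
  n_pos <- cumsum(strsplit(big, "", fixed = TRUE)[[1L]] == "N")
  subject <- Biostrings::DNAString(chartr("N", "A", big))
  bigN <- nchar(big)
  res <- list()
  for (pw in pwms) {
    L <- ncol(pw$loglik)
    if (bigN < L) next
    at <- seq_len(bigN - L + 1L)
    has_n <- (n_pos[at + L - 1L] - c(0L, n_pos)[at]) > 0L
    for (strand in c("+", "-")) {
      mat <- if (strand == "+") pw$loglik else revcomp_pwm_matrix(pw$loglik)
      sc <- Biostrings::PWMscoreStartingAt(mat, subject, starting.at = at)
      sel <- which(!has_n & sc > pw$cutoff)
      if (!length(sel)) next
      gi <- gene_of[sel]
      cs <- sel - gene_start[gi] + 1L               # window start within promoter
      ok <- cs >= 1L & cs + L - 1L <= plens[gi]     # inside one promoter
      sel <- sel[ok]; gi <- gi[ok]; cs <- cs[ok]
      if (!length(sel)) next
      res[[length(res) + 1L]] <- data.frame(
        gene_id = names(promoters)[gi], strain = strain, tf_name = pw$tf_name,
        offset = plens[gi] - cs - L + 2L, strand = strand, score = sc[sel],
        site_seq = substring(promoters[gi], cs, cs + L - 1L))
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$gene_id, out$tf_name, out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

nw_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      letters <- c(BASES, "N")
      mm <- matrix(-1, 5, 5, dimnames = list(letters, letters))
      diag(mm) <- 1
      mm["N", ] <- -1; mm[, "N"] <- -1
      m <<- mm
    }
    m
  }
})

# global Needleman-Wunsch via Biostrings: match +1, mismatch -1, linear
# gap -2. `a` may be a vector (aligned elementwise against the single
# subject `b` in one call); returns per-pair gapped strings or scores.
nw_pair <- function(a, b, score_only = FALSE) {
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(a), subject = b, type = "global",
    substitutionMatrix = nw_submat(), gapOpening = 0, gapExtension = 2,
    scoreOnly = score_only)
  if (score_only) return(al)
  list(a = as.character(Biostrings::alignedPattern(al)),
       b = as.character(Biostrings::alignedSubject(al)),
       score = Biostrings::score(al))
}

#' Center-star multiple alignment of one gene's promoters
#'
#' The strain minimizing the summed pairwise Needleman-Wunsch distance
#' (negated global score; match +1, mismatch -1, gap -2) is the center;
#' pairwise alignments to the center are merged into one set of gapped
#' strings of equal length. Strains with empty promoters are excluded and
#' reported in attribute `absent`.
#'
#' @param promoters Named character vector strain -> promoter string.
#' @return Named character vector of gapped strings (equal lengths), with
#'   attribute `absent` naming excluded strains.
#' @export
align_promoters <- function(promoters) {
  stopifnot(length(promoters) >= 2L)
  seqs <- vapply(promoters, as.character, character(1L))
  absent <- names(seqs)[!nzchar(seqs)]
  seqs <- seqs[nzchar(seqs)]
  if (length(seqs) < 2L) {
    out <- seqs
    attr(out, "absent") <- absent
    return(out)
  }
  if (length(unique(seqs)) == 1L) {            # identical: gap-free trivially
    attr(seqs, "absent") <- absent
    return(seqs)
  }
  k <- length(seqs)
  # center selection by summed pairwise NW distance (= -score); one
  # batched call per subject fills the upper triangle
  scores <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    sc <- nw_pair(seqs[(i + 1L):k], seqs[[i]], TRUE)
    scores[i, (i + 1L):k] <- sc
    scores[(i + 1L):k, i] <- sc
  }
  center <- which.max(rowSums(scores))          # max score = min distance
  aln <- merge_center_star(seqs, center, scores[center, ])
  attr(aln, "absent") <- absent
  aln
}

hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

merge_center_star <- function(seqs, center, center_scores = NULL) {
  k <- length(seqs)
  others <- setdiff(seq_len(k), center)
  # master: gap pattern of the center accumulated over pairwise alignments
  master <- strsplit(seqs[[center]], "", fixed = TRUE)[[1L]]
  cseq <- seqs[[center]]
  clen <- nchar(cseq)
  # exact shortcut: when the NW score of (center, other) equals the
  # gap-free score L - 2*hamming (equal lengths only), the ungapped
  # alignment already attains the optimum and is used as is
  gapfree <- vapply(others, function(j) {
    !is.null(center_scores) && nchar(seqs[[j]]) == clen &&
      abs(center_scores[j] - (clen - 2 * hamming(cseq, seqs[[j]]))) < 1e-9
  }, logical(1L))
  pair_alns <- vector("list", length(others))
  for (m in which(gapfree)) {
    pair_alns[[m]] <- list(a = cseq, b = seqs[[others[m]]])
  }
  if (any(!gapfree)) {
    batch <- nw_pair(seqs[others[!gapfree]], cseq)
    hard <- which(!gapfree)
    for (mi in seq_along(hard)) {
      pair_alns[[hard[mi]]] <- list(a = batch$b[mi], b = batch$a[mi])
    }
  }
  # build the union gap structure of the center across all pairwise
  # alignments: represent the center as its residues with per-gap counts
  ncenter <- length(master)
  # gaps_before[i]: max gap run inserted before center residue i (i in
  # 1..ncenter+1, last = after final residue)
  gaps_before <- integer(ncenter + 1L)
  parsed <- lapply(pair_alns, function(al) {
    ac <- strsplit(al$a, "", fixed = TRUE)[[1L]]
    bc <- strsplit(al$b, "", fixed = TRUE)[[1L]]
    gb <- integer(ncenter + 1L)
    pos <- 1L; run <- 0L
    for (t in seq_along(ac)) {
      if (ac[t] == "-") run <- run + 1L
      else { gb[pos] <- run; run <- 0L; pos <- pos + 1L }
    }
    gb[ncenter + 1L] <- run
    list(ac = ac, bc = bc, gb = gb)
  })
  for (p in parsed) gaps_before <- pmax(gaps_before, p$gb)
  # lay out the center row in the merged alignment
  total <- ncenter + sum(gaps_before)
  center_row <- character(total)
  col <- 1L
  col_of_residue <- integer(ncenter)
  for (i in seq_len(ncenter)) {
    if (gaps_before[i] > 0L) {
      center_row[col:(col + gaps_before[i] - 1L)] <- "-"
      col <- col + gaps_before[i]
    }
    center_row[col] <- master[i]
    col_of_residue[i] <- col
    col <- col + 1L
  }
  if (gaps_before[ncenter + 1L] > 0L) {
    center_row[col:total] <- "-"
  }
  out <- matrix("-", nrow = k, ncol = total)
  out[center, ] <- center_row
  for (m in seq_along(others)) {
    p <- parsed[[m]]
    row <- rep("-", total)
    pos <- 0L          # center residues consumed
    slot <- 0L         # columns used within the current pre-residue gap block
    for (t in seq_along(p$ac)) {
      if (p$ac[t] == "-") {
        slot <- slot + 1L
        anchor <- if (pos < ncenter) col_of_residue[pos + 1L] - gaps_before[pos + 1L]
                  else total - gaps_before[ncenter + 1L] + 1L
        row[anchor + slot - 1L] <- p$bc[t]
      } else {
        pos <- pos + 1L
        slot <- 0L
        row[col_of_residue[pos]] <- p$bc[t]
      }
    }
    out[others[m], ] <- row
  }
  aln <- apply(out, 1L, paste, collapse = "")
  names(aln) <- names(seqs)
  aln
}

# alignment column of each ungapped position, per strain
alignment_columns <- function(aln) {
  lapply(aln, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    which(ch != "-")
  })
}

#' Classify cross-strain conservation of motif hits
#'
#' Hits of one TF in one gene are grouped greedily by ascending alignment
#' column (ties broken by higher score): a group collects all ungrouped
#' hits whose columns lie within `window_bp` alignment columns of the
#' anchor hit. A group with a hit in every strain and identical site
#' sequence is `conserved`; with differing site sequences,
#' `conserved_with_variation`; if any strain lacks a hit,
#' `non_conserved`.
#'
#' @param hits Data frame of hits across strains for one gene (columns
#'   gene_id, strain, tf_name, offset, strand, score, site_seq); promoter
#'   positions are recovered from offsets via the alignment.
#' @param alignment Named character vector of gapped promoter strings
#'   (output of [align_promoters()]); names are the strains considered.
#' @param window_bp Grouping window in alignment columns (default 20).
#' @return Data frame with columns gene_id, tf_name, anchor_offset,
#'   class, n_strains_hit, plus one column per strain with the hit site
#'   (NA if absent).
#' @export
classify_conservation <- function(hits, alignment, window_bp = 20L) {
  strains <- names(alignment)
  cols <- alignment_columns(alignment)
  plens <- lengths(cols)
  empty <- data.frame(gene_id = character(0), tf_name = character(0),
                      anchor_offset = integer(0), class = character(0),
                      n_strains_hit = integer(0))
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[hits$strain %in% strains, , drop = FALSE]
  out <- list()
  for (tf in unique(hits$tf_name)) {
    h <- hits[hits$tf_name == tf, , drop = FALSE]
    # anchor column: alignment column of the hit base nearest the start
    # (promoter position plen - offset + 1)
    pos <- plens[h$strain] - h$offset + 1L
    h$column <- mapply(function(s, p) cols[[s]][p], h$strain, pos)
    h <- h[order(h$column, -h$score), , drop = FALSE]
    used <- rep(FALSE, nrow(h))
    while (!all(used)) {
      a <- which(!used)[1L]
      grp <- !used & abs(h$column - h$column[a]) <= window_bp
      used[grp] <- TRUE
      g <- h[grp, , drop = FALSE]
      # one hit per strain: the highest-scoring in the group
      g <- g[order(g$strain, -g$score), , drop = FALSE]
      g <- g[!duplicated(g$strain), , drop = FALSE]
      present <- strains %in% g$strain
      cls <- if (!all(present)) "non_conserved"
             else if (length(unique(g$site_seq)) == 1L) "conserved"
             else "conserved_with_variation"
      sites <- stats::setNames(rep(NA_character_, length(strains)), strains)
      sites[g$strain] <- g$site_seq
      out[[length(out) + 1L]] <- data.frame(
        gene_id = h$gene_id[a], tf_name = tf, anchor_offset = h$offset[a],
        class = cls, n_strains_hit = sum(present),
        as.list(sites), check.names = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of external target genes supported by a predicted motif
#'
#' For each TF, the fraction of its externally supplied target genes
#' whose promoter carries at least one predicted hit for that TF.
#'
#' @param target_sets Named list tf -> character vector of gene ids.
#' @param hits Data frame of predicted hits (columns tf_name, gene_id).
#' @return Named numeric vector in \[0, 1\], one entry per TF with a
#'   non-empty target set; TFs with no hits table entry score 0.
#' @export
motif_support_fraction <- function(target_sets, hits) {
  stopifnot(all(lengths(target_sets) > 0L))
  vapply(names(target_sets), function(tf) {
    tg <- unique(target_sets[[tf]])
    with_hit <- unique(hits$gene_id[hits$tf_name == tf])
    mean(tg %in% with_hit)
  }, numeric(1L))
}
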