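test_that("window scoring sums per-position log-likelihoods", {
  zero <- pwm("Z", matrix(0, 4, 5), 0)
  expect_equal(score_window(zero, "ACGTA"), 0)

  ll <- matrix(0, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  ll["A", ] <- c(1.0, 0.5)
  expect_equal(score_window(pwm("P", ll, 0), "AA"), 1.5)
  expect_true(is.na(score_window(pwm("P", ll, 0), "AN")))

  set.seed(10)
  for (i in 1:25) {
    L <- sample(3:10, 1)
    p <- random_pwm("R", L)
    w <- random_promoter(L)
    idx <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
    expected <- if (anyNA(idx)) NA_real_ else
      sum(vapply(seq_len(L), function(j) p$loglik[idx[j], j], numeric(1)))
    expect_equal(score_window(p, w), expected, tolerance = 1e-12)
  }
})

test_that("promoter scanning equals exhaustive window enumeration", {
  set.seed(20)
  for (i in 1:30) {
    p <- random_pwm(paste0("T", i), sample(4:8, 1))
    prom <- random_promoter(sample(20:100, 1), p_n = 0.03)
    expect_equal(scan_promoter(p, prom), scan_oracle(p, prom))
  }
})

test_that("a planted consensus above cutoff is recovered as a hit", {
  set.seed(21)
  ll <- matrix(-2, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- sample(c("A", "C", "G", "T"), 8, replace = TRUE)
  ll[cbind(match(cons, rownames(ll)), 1:8)] <- 1
  p <- pwm("X", ll, 8 - 0.5)      # only the exact consensus scores above
  prom <- random_promoter(120)
  substr(prom, 50, 57) <- paste(cons, collapse = "")
  h <- scan_promoter(p, prom)
  expect_true(any(h$site_seq == paste(cons, collapse = "") & h$strand == "+"))
  expect_true(all(h$score > p$cutoff))
})

test_that("scanning the reverse complement mirrors hits", {
  set.seed(22)
  for (i in 1:10) {
    p <- random_pwm("T", 6)
    prom <- random_promoter(60)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(prom)))
    h1 <- scan_promoter(p, prom)
    h2 <- scan_promoter(p, rc)
    # a +-strand hit with offset o maps to a --strand hit at the
    # mirrored offset P - o - L + 2 and vice versa
    P <- nchar(prom); L <- ncol(p$loglik)
    mirrored <- data.frame(offset = P - h1$offset - L + 2L,
                           strand = ifelse(h1$strand == "+", "-", "+"),
                           score = h1$score)
    mirrored <- mirrored[order(mirrored$offset, mirrored$strand), ]
    expect_equal(h2[, c("offset", "strand", "score")], mirrored,
                 ignore_attr = TRUE)
  }
})

test_that("bulk scanning agrees with the per-promoter reference scan", {
  set.seed(23)
  pwms <- lapply(1:4, function(i) random_pwm(paste0("T", i), sample(4:7, 1)))
  proms <- setNames(vapply(1:15, function(i) random_promoter(sample(10:90, 1), p_n = 0.02),
                           character(1)), paste0("g", 1:15))
  batch <- scan_promoters(proms, pwms, "s")
  ref <- do.call(rbind, lapply(names(proms), function(g) {
    do.call(rbind, lapply(pwms, function(pw) {
      h <- suppressWarnings(scan_promoter(pw, proms[[g]]))
      if (nrow(h)) cbind(gene_id = g, strain = "s", tf_name = pw$tf_name, h)
    }))
  }))
  ref <- ref[order(ref$gene_id, ref$tf_name, ref$offset, ref$strand), ]
  rownames(ref) <- NULL
  expect_equal(batch, ref)
})

test_that("promoter extraction honors strand, coordinates and truncation", {
  contig <- random_promoter(1000)
  genome <- c(c1 = contig)
  plus <- list(gene_id = "g1", seq_id = "c1", start = 501, end = 900, strand = "+")
  p <- extract_promoter(genome, plus, 500)
  expect_equal(as.character(p), substr(contig, 1, 500), ignore_attr = TRUE)
  expect_false(attr(p, "truncated"))

  minus <- list(gene_id = "g2", seq_id = "c1", start = 1, end = 500, strand = "-")
  m <- extract_promoter(genome, minus, 500)
  expect_equal(as.character(m),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(contig, 501, 1000)))),
               ignore_attr = TRUE)
  expect_false(attr(m, "truncated"))

  short <- list(gene_id = "g3", seq_id = "c1", start = 300, end = 500, strand = "+")
  s <- extract_promoter(genome, short, 500)
  expect_equal(nchar(s), 299)
  expect_true(attr(s, "truncated"))

  edge <- list(gene_id = "g4", seq_id = "c1", start = 1, end = 100, strand = "+")
  e <- extract_promoter(genome, edge, 500)
  expect_equal(nchar(e), 0)
  expect_true(attr(e, "truncated"))

  expect_error(extract_promoter(genome, list(seq_id = "nope", start = 1,
                                             end = 2, strand = "+")), "nope")
})

test_that("center-star alignment reproduces Needleman-Wunsch optima", {
  # identical promoters align without gaps
  idn <- align_promoters(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"))
  expect_false(any(grepl("-", idn)))

  # a single 3-bp deletion yields one 3-column gap block in that strain
  base <- "CCGTTTCTAGCATTAGTCCG"
  del <- paste0(substr(base, 1, 8), substr(base, 12, nchar(base)))
  al <- align_promoters(c(s1 = base, s2 = del, s3 = base))
  expect_equal(unique(nchar(al)), nchar(base))
  gaps <- gregexpr("-+", al[["s2"]])[[1]]
  expect_equal(length(gaps), 1L)
  expect_equal(attr(gaps, "match.length"), 3L)
  # the DP-optimal score: all retained bases match, 3 gap columns at -2
  expect_equal(nw_score_oracle(base, del), nchar(del) - 3 * 2)

  # degapping recovers the inputs on random instances
  set.seed(30)
  for (i in 1:10) {
    n <- sample(2:5, 1)
    seqs <- setNames(vapply(seq_len(n), function(j) {
      s <- random_promoter(sample(30:60, 1))
    }, character(1)), paste0("s", seq_len(n)))
    al <- align_promoters(seqs)
    expect_equal(unname(gsub("-", "", al)), unname(seqs[names(al)]),
                 ignore_attr = TRUE)
    expect_equal(length(unique(nchar(al))), 1L)
  }

  # empty promoters are excluded and reported
  al <- align_promoters(c(a = "ACGT", b = "", c = "ACGT"))
  expect_identical(attr(al, "absent"), "b")
  expect_false("b" %in% names(al))
})

test_that("gap-free shortcut matches the full DP on substitution-only pairs", {
  set.seed(31)
  for (i in 1:10) {
    a <- random_promoter(80)
    b <- a
    for (k in sample(80, 4)) substr(b, k, k) <- sample(c("A", "C", "G", "T"), 1)
    al <- align_promoters(c(x = a, y = b))
    expect_false(any(grepl("-", al)))
    mism <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(nw_score_oracle(a, b), 80 - 2 * mism)
  }
})

test_that("conservation classes reflect planted, variant and lost motifs", {
  mk_hits <- function(sites, offset = 20L) {
    do.call(rbind, lapply(names(sites), function(st) {
      if (is.na(sites[[st]])) return(NULL)
      data.frame(gene_id = "g1", strain = st, tf_name = "TF1",
                 offset = offset, strand = "+", score = 10,
                 site_seq = sites[[st]])
    }))
  }
  aln <- c(s1 = strrep("A", 60), s2 = strrep("A", 60), s3 = strrep("A", 60))

  same <- classify_conservation(mk_hits(c(s1 = "ACGT", s2 = "ACGT", s3 = "ACGT")), aln)
  expect_equal(same$class, "conserved")

  var <- classify_conservation(mk_hits(c(s1 = "ACGT", s2 = "ACGA", s3 = "ACGT")), aln)
  expect_equal(var$class, "conserved_with_variation")

  lost <- classify_conservation(mk_hits(c(s1 = "ACGT", s2 = NA, s3 = "ACGT")), aln)
  expect_equal(lost$class, "non_conserved")

  # grouping window: hits 25 columns apart fall into separate groups
  h <- rbind(mk_hits(c(s1 = "ACGT", s2 = "ACGT", s3 = "ACGT"), offset = 10L),
             mk_hits(c(s1 = "ACGT"), offset = 40L))
  two <- classify_conservation(h, aln, window_bp = 20L)
  expect_equal(nrow(two), 2L)
  expect_setequal(two$class, c("conserved", "non_conserved"))
  expect_equal(sum(table(two$class)), nrow(two))  # classes partition groups
})

test_that("motif support fraction counts externally supplied targets", {
  hits <- data.frame(tf_name = c("T1", "T1", "T2"),
                     gene_id = c("g1", "g2", "g9"))
  expect_equal(motif_support_fraction(list(T1 = c("g1", "g2")), hits)[["T1"]], 1)
  expect_equal(motif_support_fraction(list(T1 = c("g7", "g8")), hits)[["T1"]], 0)
  expect_equal(motif_support_fraction(list(T1 = c("g1", "g7"),
                                           T2 = c("g9", "g3", "g4", "g5")), hits),
               c(T1 = 0.5, T2 = 0.25))
})
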