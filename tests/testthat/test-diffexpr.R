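make_expt <- function(counts, strains = NULL) {
  n <- ncol(counts)
  if (is.null(strains)) strains <- rep("A", n)
  samples <- data.frame(sample_id = colnames(counts), strain = strains,
                        condition = attr(counts, "condition"),
                        replicate = ave(seq_len(n), strains,
                                        attr(counts, "condition"), FUN = seq_along))
  count_experiment(counts, samples)
}

two_cond_counts <- function(treated, untreated, strain = "A") {
  k <- ncol(treated)
  m <- cbind(treated, untreated)
  colnames(m) <- paste0(strain, "_", rep(c("t", "u"), each = k), 1:k)
  attr(m, "condition") <- rep(c("treated", "untreated"), each = k)
  m
}

test_that("the count filter drops genes low in every sample", {
  counts <- rbind(g1 = c(0, 0, 4, 3), g2 = c(0, 0, 5, 3), g3 = c(9, 9, 9, 9))
  attr(counts, "condition") <- c("treated", "treated", "untreated", "untreated")
  colnames(counts) <- paste0("s", 1:4)
  expt <- make_expt(counts)
  filt <- filter_genes(expt, 5)
  expect_setequal(rownames(filt$counts), c("g2", "g3"))

  # the strict per-sample mode removes any gene with one low sample
  strict <- filter_genes(expt, 5, mode = "min")
  expect_identical(rownames(strict$counts), "g3")

  low <- expt; low$counts <- expt$counts[1, , drop = FALSE]
  expect_error(filter_genes(low, 5), "min_count")
})

test_that("median-of-ratios size factors scale with library size", {
  counts <- matrix(rep(c(10L, 40L, 100L), 4), 3, 4,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  attr(counts, "condition") <- c("treated", "treated", "untreated", "untreated")
  expt <- make_expt(counts)
  expect_equal(unname(size_factors(expt)), rep(1, 4))

  doubled <- expt
  doubled$counts[, 2] <- doubled$counts[, 2] * 2L
  sf <- size_factors(doubled)
  expect_equal(unname(sf[2] / sf[1]), 2)

  # direct evaluation on a 3-gene toy matrix
  m <- matrix(c(2L, 4L, 8L,
                4L, 8L, 16L), 3, 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  attr(m, "condition") <- c("treated", "untreated")
  toy <- make_expt(m)
  geo <- exp(rowMeans(log(m)))
  expected <- apply(m / geo, 2, median)
  expect_equal(size_factors(toy), expected)
})

test_that("identical conditions give zero fold change and no DE calls", {
  set.seed(40)
  base <- matrix(rpois(60, 50), 20, 3)
  counts <- two_cond_counts(base, base)
  rownames(counts) <- paste0("g", 1:20)
  expt <- make_expt(counts)
  de <- de_test(expt, "A")
  expect_true(all(de$log2fc == 0))
  expect_false(any(de$is_de))
})

test_that("a planted four-fold effect is estimated without bias", {
  # the effect sits on a minority of genes so the median-of-ratios
  # normalization is anchored by the unchanged majority
  set.seed(41)
  n <- 300
  mu <- rlnorm(n, log(200), 0.8)
  fold <- rep(1, n); fold[1:60] <- 4
  treated <- sapply(1:3, function(i) rnbinom(n, mu = fold * mu, size = 20))
  untreated <- sapply(1:3, function(i) rnbinom(n, mu = mu, size = 20))
  counts <- two_cond_counts(treated, untreated)
  rownames(counts) <- paste0("g", 1:n)
  expt <- make_expt(counts)
  de <- de_test(expt, "A")
  expect_lt(abs(median(de$log2fc[1:60]) - 2), 0.3)
  expect_gt(mean(de$is_de[1:60]), 0.9)
  expect_lt(mean(de$is_de[61:n]), 0.05)
})

test_that("DE adjusted p-values use Benjamini-Hochberg across genes", {
  set.seed(42)
  base <- matrix(rpois(30, 100), 10, 3)
  counts <- two_cond_counts(base + matrix(rpois(30, 5), 10, 3), base)
  rownames(counts) <- paste0("g", 1:10)
  de <- de_test(make_expt(counts), "A")
  expect_equal(de$adj_p, adjust_p(de$p, "bh"))
})

test_that("rescaling one sample moves its size factor, not the fold changes", {
  set.seed(43)
  treated <- matrix(rnbinom(90, mu = 100, size = 10), 30, 3)
  untreated <- matrix(rnbinom(90, mu = 100, size = 10), 30, 3)
  counts <- two_cond_counts(treated, untreated)
  rownames(counts) <- paste0("g", 1:30)
  expt <- make_expt(counts)
  de1 <- de_test(expt, "A")
  scaled <- expt
  scaled$counts[, 1] <- scaled$counts[, 1] * 3L
  sf1 <- size_factors(expt); sf2 <- size_factors(scaled)
  # factors are defined up to a common constant (the geometric mean
  # moves with the rescaled column): compare ratios between samples
  expect_equal(unname((sf2[1] / sf2[2]) / (sf1[1] / sf1[2])), 3, tolerance = 1e-9)
  de2 <- de_test(scaled, "A")
  # fold changes are invariant up to the pseudocount at the slightly
  # rescaled normalized means
  expect_equal(de2$log2fc, de1$log2fc, tolerance = 5e-3)
})

test_that("TPM normalizes by length and sums to one million per sample", {
  counts <- matrix(c(10L, 10L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  attr(counts, "condition") <- "treated"
  expt <- make_expt(counts)
  tt <- tpm(expt, c(g1 = 1000, g2 = 2000))
  expect_equal(unname(tt[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  single <- counts[1, , drop = FALSE]
  attr(single, "condition") <- "treated"
  expect_equal(unname(tpm(make_expt(single), c(g1 = 500))[1, 1]), 1e6)

  set.seed(44)
  m <- matrix(rpois(40, 50) + 1L, 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  attr(m, "condition") <- rep(c("treated", "untreated"), 2)
  lens <- setNames(sample(200:2000, 10), paste0("g", 1:10))
  expect_equal(unname(colSums(tpm(make_expt(m), lens))), rep(1e6, 4))
})

fake_de <- function(genes, fc, strain, de = TRUE) {
  # builds a DE table whose pseudocounted fold change equals fc exactly
  mu <- rep(10, length(genes))
  mt <- (mu + 0.5) * fc - 0.5
  data.frame(gene_id = genes, strain = strain,
             base_mean_untreated = mu, base_mean_treated = mt,
             log2fc = log2(fc), p = 0.001, adj_p = 0.001, is_de = de)
}

test_that("pair-specific classification follows the fold-change-ratio rule", {
  a <- fake_de("g1", 4, "A"); b <- fake_de("g1", 1, "B")
  pr <- pair_specific(a, b)
  expect_true(pr$is_pair_specific)
  expect_equal(pr$fc_ratio, 4)

  pr_eq <- pair_specific(fake_de("g1", 2, "A"), fake_de("g1", 2, "B"))
  expect_false(pr_eq$is_pair_specific)

  pr_lo <- pair_specific(fake_de("g1", 1, "A"), fake_de("g1", 3, "B"))
  expect_true(pr_lo$is_pair_specific)
  expect_equal(pr_lo$fc_ratio, 1 / 3, tolerance = 1e-9)

  # non-DE genes are ineligible when require_de is on
  nd <- pair_specific(fake_de("g1", 4, "A", de = FALSE),
                      fake_de("g1", 1, "B", de = FALSE))
  expect_false(nd$is_pair_specific)
  nd2 <- pair_specific(fake_de("g1", 4, "A", de = FALSE),
                       fake_de("g1", 1, "B", de = FALSE), require_de = FALSE)
  expect_true(nd2$is_pair_specific)
})

test_that("swapping the strain pair inverts ratios but preserves the classes", {
  set.seed(45)
  genes <- paste0("g", 1:40)
  a <- fake_de(genes, exp(rnorm(40, 0, 1)), "A")
  b <- fake_de(genes, exp(rnorm(40, 0, 1)), "B")
  ab <- pair_specific(a, b)
  ba <- pair_specific(b, a)
  expect_equal(ba$fc_ratio, 1 / ab$fc_ratio, tolerance = 1e-9)
  expect_equal(ba$is_pair_specific, ab$is_pair_specific)
  swap <- c(buffered = "buffered", potentiated = "potentiated",
            tie = "tie", none = "none")
  expect_equal(unname(swap[ab$bp_class]), ba$bp_class)
})

test_that("buffered and potentiated calls compare the two conditions' gaps", {
  expect_equal(classify_buffered_potentiated(80, 10, 10, 10), "buffered")
  expect_equal(classify_buffered_potentiated(10, 80, 10, 10), "potentiated")
  expect_equal(classify_buffered_potentiated(40, 40, 10, 10), "tie")
})

test_that("DE sets are nested across fold-change cutoffs", {
  set.seed(46)
  mu <- rlnorm(120, log(100), 1)
  fc <- sample(c(1, 1.7, 2.2, 3), 120, replace = TRUE)
  treated <- sapply(1:3, function(i) rnbinom(120, mu = fc * mu, size = 20))
  untreated <- sapply(1:3, function(i) rnbinom(120, mu = mu, size = 20))
  counts <- two_cond_counts(treated, untreated)
  rownames(counts) <- paste0("g", 1:120)
  expt <- make_expt(counts)
  sets <- lapply(c(1.5, 2, 2.5), function(fcut) {
    d <- de_test(expt, "A", fc_cut = fcut)
    d$gene_id[d$is_de]
  })
  expect_true(all(sets[[3]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[1]]))
})
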