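cons_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_id = r[[1]], tf_name = r[[2]], anchor_offset = 10L,
               class = r[[3]], n_strains_hit = 3L)
  }))
}

test_that("target sets follow conservation classes and expression filters", {
  cons <- cons_df(list("g1", "T1", "conserved"),
                  list("g2", "T1", "conserved_with_variation"),
                  list("g3", "T1", "non_conserved"),
                  list("g1", "T2", "conserved"))
  expressed <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3"))
  ts <- build_target_sets(cons, expressed)
  expect_setequal(ts$T1$A, c("g1", "g2"))
  expect_setequal(ts$T1$B, "g2")          # g1 not expressed in B
  expect_setequal(ts$T2$A, "g1")
  ts2 <- build_target_sets(cons, expressed, include_variant = FALSE)
  expect_setequal(ts2$T1$A, "g1")
})

test_that("TFs with a small regulon in any strain are excluded", {
  ts <- list(
    T1 = list(A = paste0("g", 1:3), B = paste0("g", 1:3), C = paste0("g", 1:3)),
    T2 = list(A = paste0("g", 1:3), B = paste0("g", 1:2), C = paste0("g", 1:3)))
  ex <- exclude_small_tfs(ts, 3)
  expect_identical(names(ex$kept), "T1")
  expect_identical(names(ex$excluded), "T2")
  expect_equal(length(ex$kept) + length(ex$excluded), length(ts))
})

test_that("the KW screen flags only regulons with cross-strain differences", {
  set.seed(50)
  genes <- paste0("g", 1:60)
  de_list <- lapply(c(A = "A", B = "B", C = "C"), function(st) {
    data.frame(gene_id = genes, strain = st, log2fc = rnorm(60, 0, 0.2))
  })
  # T_shift's targets respond only in strain C
  shift_targets <- genes[1:12]
  de_list$C$log2fc[1:12] <- de_list$C$log2fc[1:12] + 2
  ts <- list(T_shift = list(A = shift_targets, B = shift_targets, C = shift_targets),
             T_null = list(A = genes[21:40], B = genes[21:40], C = genes[21:40]))
  kw <- kw_screen(ts, de_list)
  expect_true(kw$is_candidate[kw$tf_name == "T_shift"])
  expect_false(kw$is_candidate[kw$tf_name == "T_null"])
  # fully identical fold changes across strains give p = 1
  same <- lapply(de_list, function(d) { d$log2fc <- seq(0, 1, length.out = 60); d })
  expect_equal(kw_screen(ts, same)$kw_p, c(1, 1))
})

test_that("pairwise Wilcoxon separates shifted from unshifted strain pairs", {
  set.seed(51)
  genes <- paste0("g", 1:30)
  de_list <- lapply(c(A = "A", B = "B", C = "C"), function(st) {
    data.frame(gene_id = genes, strain = st, log2fc = rnorm(30, 0, 0.2))
  })
  de_list$C$log2fc <- de_list$C$log2fc + 1.5
  ts <- list(T1 = list(A = genes, B = genes, C = genes))
  w <- pairwise_wilcoxon(ts, de_list, "T1")
  expect_true(all(w$adj_p >= w$p))
  expect_lt(w$adj_p[w$pair == "A|C"], 0.05)
  expect_lt(w$adj_p[w$pair == "B|C"], 0.05)
  expect_gt(w$adj_p[w$pair == "A|B"], 0.05)
})

test_that("enrichment bookkeeping and the high-confidence rule are correct", {
  genes <- paste0("g", 1:100)
  ps <- rep(FALSE, 100); ps[1:10] <- TRUE   # pair-specific genes g1..g10
  pr <- data.frame(gene_id = genes, strain_a = "A", strain_b = "B",
                   fc_ratio = 1, is_pair_specific = ps, bp_class = "none")
  ts <- list(T_enr = list(A = genes[1:10], B = genes[1:10]),
             T_bg = list(A = genes[41:60], B = genes[41:60]))
  enr <- pair_enrichment(ts, list(`A|B` = pr), c("T_enr", "T_bg"))
  tab <- enr$table
  expect_equal(tab$x1[tab$tf_name == "T_enr"], 10L)
  expect_equal(tab$n1[tab$tf_name == "T_enr"], 10L)
  expect_equal(tab$x2[1], 10L)
  expect_equal(tab$n2[1], 100L)
  expect_identical(enr$high_confidence, "T_enr")
})

test_that("the 0/1/2 label rule reproduces the adjusted-p grid exactly", {
  kw <- data.frame(tf_name = c("T1", "T2", "T3"),
                   kw_p = c(0.2, 0.001, 0.001),
                   kw_adj_p = c(0.2, 0.01, 0.01),
                   is_candidate = c(FALSE, TRUE, TRUE))
  wil <- expand.grid(tf_name = c("T2", "T3"), pair = c("A|B", "A|C"),
                     stringsAsFactors = FALSE)
  wil$p <- c(0.001, 0.3, 0.3, 0.001)
  wil$adj_p <- c(0.01, 0.3, 0.3, 0.01)
  lab <- label_tfs(kw, wil, pairs = c("A|B", "A|C"))
  expect_equal(unname(lab["T1", ]), c(0L, 0L))
  expect_equal(unname(lab["T2", ]), c(2L, 1L))
  expect_equal(unname(lab["T3", ]), c(1L, 2L))
  expect_true(all(lab %in% 0:2))
  # label 2 implies the KW (label-1) condition held
  expect_true(all(kw$kw_adj_p[match(rownames(lab)[rowSums(lab == 2) > 0],
                                    kw$tf_name)] < 0.05))
})

test_that("TF clustering groups identical label rows first", {
  lab <- rbind(T1 = c(0L, 0L, 0L), T2 = c(0L, 0L, 0L), T3 = c(2L, 2L, 2L))
  cl <- cluster_tfs(lab)
  expect_equal(cl$hclust$height[1], 0)
  first <- rownames(lab)[-cl$hclust$merge[1, ]]
  expect_setequal(first, c("T1", "T2"))
  # distance between all-0 and all-2 rows over k pairs is 2*sqrt(k)
  D <- as.matrix(dist(lab))
  expect_equal(D["T1", "T3"], 2 * sqrt(3))
  expect_equal(max(cl$hclust$height), 2 * sqrt(3))
})

test_that("client enrichment reports both hypergeometric tail conventions", {
  universe <- paste0("T", 1:20)
  clients <- universe            # every TF a client
  cand <- universe[1:5]
  ce <- client_enrichment(cand, clients, universe)
  expect_equal(ce$p_ge, 1)       # overlap is certain
  ce2 <- client_enrichment(paste0("T", 1:4), paste0("T", 1:8), universe)
  expect_equal(ce2$k, 4L)
  expect_equal(ce2$p_ge, hypergeometric_ge(4, 8, 4, 20), tolerance = 1e-12)
  expect_equal(ce2$p_gt, 0)   # overlap cannot exceed the candidate count
  expect_error(client_enrichment("a", "b", character(0)), "universe")
})

test_that("GO enrichment counts match brute-force set intersections", {
  set.seed(52)
  universe <- paste0("g", 1:60)
  go_map <- lapply(setNames(universe, universe),
                   function(g) sample(paste0("GO:", 1:6), 2))
  term <- "GO:RARE"
  go_map[["g1"]] <- c(go_map[["g1"]], term)
  go_map[["g2"]] <- c(go_map[["g2"]], term)
  go_map[["g3"]] <- c(go_map[["g3"]], term)
  res <- go_enrichment(c("g1", "g2", "g3"), go_map, universe)
  row <- res[res$term_id == term, ]
  expect_equal(row$k, 3L)
  expect_equal(row$K, 3L)
  expect_equal(row$n, 3L)
  expect_equal(row$N, 60L)
  expect_true(row$significant)
  # bookkeeping oracle for every term
  for (i in seq_len(nrow(res))) {
    tg <- universe[vapply(universe, function(g) res$term_id[i] %in% go_map[[g]],
                          logical(1))]
    expect_equal(res$K[i], length(tg))
    expect_equal(res$k[i], length(intersect(c("g1", "g2", "g3"), tg)))
  }
  expect_warning(go_enrichment(character(0), go_map, universe), "empty")
})
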