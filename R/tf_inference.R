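# The TF-candidate cascade: conserved-motif target sets, a
# Kruskal-Wallis screen across strains, pairwise Wilcoxon tests,
# strain-pair-specific-gene enrichment, 0/1/2 labels and clustering,
# plus chaperone-client and GO enrichment.

strain_pairs <- function(strains) {
  utils::combn(strains, 2L, function(p) paste(p, collapse = "|"))
}

split_pair <- function(pair) strsplit(pair, "|", fixed = TRUE)[[1L]]

#' Build per-strain TF target sets from conserved motifs
#'
#' A gene is a target of a TF in a strain when its promoter carries a
#' conservation record of class `conserved` (or, with `include_variant`,
#' `conserved_with_variation`) for that TF and the gene has expression
#' data in that strain.
#'
#' @param conservation Data frame from [classify_conservation()].
#' @param expressed Named list strain -> character vector of genes with
#'   expression data.
#' @param include_variant Count `conserved_with_variation` records
#'   (default TRUE).
#' @return Named list tf -> named list strain -> character vector.
#' @export
build_target_sets <- function(conservation, expressed, include_variant = TRUE) {
  classes <- c("conserved", if (include_variant) "conserved_with_variation")
  keep <- conservation[conservation$class %in% classes, , drop = FALSE]
  tfs <- unique(keep$tf_name)
  out <- lapply(tfs, function(tf) {
    genes <- unique(keep$gene_id[keep$tf_name == tf])
    lapply(expressed, function(e) intersect(genes, e))
  })
  names(out) <- tfs
  out
}

#' Exclude TFs with too few targets in any strain
#'
#' @param target_sets Output of [build_target_sets()].
#' @param min_targets A TF is excluded when it has fewer targets than
#'   this in at least one strain (default 3).
#' @return List with elements `kept` and `excluded` (both target-set
#'   lists in the input layout).
#' @export
exclude_small_tfs <- function(target_sets, min_targets = 3L) {
  small <- vapply(target_sets, function(by_strain) {
    any(lengths(by_strain) < min_targets)
  }, logical(1L))
  list(kept = target_sets[!small], excluded = target_sets[small])
}

target_log2fc <- function(targets, de) {
  de$log2fc[match(intersect(targets, de$gene_id), de$gene_id)]
}

#' Kruskal-Wallis screen of TF regulons across strains
#'
#' Per TF, the per-strain lists of target log2 fold changes form the
#' groups of a Kruskal-Wallis test; p-values are Bonferroni adjusted
#' across tested TFs and candidates are called at `adj_p < alpha`.
#'
#' @param target_sets Kept target sets from [exclude_small_tfs()].
#' @param de_list Named list strain -> DE table from [de_test()].
#' @param alpha Candidate threshold (default 0.05).
#' @return Data frame: tf_name, kw_p, kw_adj_p, is_candidate.
#' @export
kw_screen <- function(target_sets, de_list, alpha = 0.05) {
  tfs <- names(target_sets)
  ps <- vapply(tfs, function(tf) {
    groups <- lapply(names(de_list), function(st) {
      target_log2fc(target_sets[[tf]][[st]], de_list[[st]])
    })
    kruskal_wallis(groups)$p
  }, numeric(1L))
  adj <- adjust_p(ps, "bonferroni")
  data.frame(tf_name = tfs, kw_p = ps, kw_adj_p = adj,
             is_candidate = adj < alpha, row.names = NULL)
}

#' Pairwise Wilcoxon tests of candidate TF regulons
#'
#' For every candidate TF and unordered strain pair, a two-sided
#' Wilcoxon rank-sum test compares the target log2 fold changes; the
#' Bonferroni family is all (TF, pair) tests performed.
#'
#' @param target_sets Kept target sets.
#' @param de_list Named list strain -> DE table.
#' @param candidates Character vector of candidate TF names.
#' @return Data frame: tf_name, pair, p, adj_p.
#' @export
pairwise_wilcoxon <- function(target_sets, de_list, candidates) {
  pairs <- strain_pairs(names(de_list))
  grid <- expand.grid(tf_name = candidates, pair = pairs,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0L) {
    return(data.frame(tf_name = character(0), pair = character(0),
                      p = numeric(0), adj_p = numeric(0)))
  }
  grid$p <- vapply(seq_len(nrow(grid)), function(i) {
    st <- split_pair(grid$pair[i])
    x <- target_log2fc(target_sets[[grid$tf_name[i]]][[st[1L]]], de_list[[st[1L]]])
    y <- target_log2fc(target_sets[[grid$tf_name[i]]][[st[2L]]], de_list[[st[2L]]])
    wilcoxon_ranksum(x, y)$p
  }, numeric(1L))
  grid$adj_p <- adjust_p(grid$p, "bonferroni")
  grid
}

#' Strain-pair-specific-gene enrichment among TF targets
#'
#' Per candidate TF and strain pair: are the pair's pair-specific genes
#' over-represented among the TF's targets relative to all analyzed
#' genes? One-sided two-proportion test (targets vs background),
#' Bonferroni adjusted over all (TF, pair) tests. A TF is
#' high-confidence when it is enriched (`adj_p < alpha`) in at least one
#' pair.
#'
#' @param target_sets Kept target sets.
#' @param pair_records Named list pair ("A|B") -> data frame from
#'   [pair_specific()].
#' @param candidates Character vector of candidate TF names.
#' @param alpha Enrichment threshold (default 0.05).
#' @return List: `table` (tf_name, pair, x1, n1, x2, n2, p, adj_p),
#'   `high_confidence` (character vector of TFs).
#' @export
pair_enrichment <- function(target_sets, pair_records, candidates, alpha = 0.05) {
  rows <- list()
  for (tf in candidates) {
    for (pair in names(pair_records)) {
      pr <- pair_records[[pair]]
      st <- split_pair(pair)
      targets <- intersect(target_sets[[tf]][[st[1L]]],
                           target_sets[[tf]][[st[2L]]])
      targets <- intersect(targets, pr$gene_id)
      n1 <- length(targets)
      if (n1 == 0L) next
      ps_genes <- pr$gene_id[pr$is_pair_specific]
      rows[[length(rows) + 1L]] <- data.frame(
        tf_name = tf, pair = pair,
        x1 = sum(targets %in% ps_genes), n1 = n1,
        x2 = length(ps_genes), n2 = nrow(pr))
    }
  }
  if (!length(rows)) {
    return(list(table = data.frame(tf_name = character(0), pair = character(0),
                                   x1 = integer(0), n1 = integer(0),
                                   x2 = integer(0), n2 = integer(0),
                                   p = numeric(0), adj_p = numeric(0)),
                high_confidence = character(0)))
  }
  tab <- do.call(rbind, rows)
  tab$p <- vapply(seq_len(nrow(tab)), function(i) {
    two_proportion_greater(tab$x1[i], tab$n1[i], tab$x2[i], tab$n2[i])$p
  }, numeric(1L))
  tab$adj_p <- adjust_p(tab$p, "bonferroni")
  hc <- unique(tab$tf_name[tab$adj_p < alpha])
  list(table = tab, high_confidence = hc)
}

#' Assign the 0/1/2 label matrix
#'
#' Per TF and strain pair: 0 when the TF's Kruskal-Wallis adjusted p is
#' >= alpha; 1 when the KW adjusted p < alpha but the pair's Wilcoxon
#' adjusted p is >= alpha; 2 when both are < alpha.
#'
#' @param kw Data frame from [kw_screen()].
#' @param wilcoxon Data frame from [pairwise_wilcoxon()].
#' @param pairs Character vector of pair names (default: those present
#'   in `wilcoxon`, or computed from strains).
#' @param alpha Threshold (default 0.05).
#' @return Integer matrix, TFs x pairs, entries in \{0, 1, 2\}.
#' @export
label_tfs <- function(kw, wilcoxon, pairs = NULL, alpha = 0.05) {
  if (is.null(pairs)) pairs <- unique(wilcoxon$pair)
  lab <- matrix(0L, nrow(kw), length(pairs),
                dimnames = list(kw$tf_name, pairs))
  for (i in seq_len(nrow(kw))) {
    if (kw$kw_adj_p[i] >= alpha) next
    for (pr in pairs) {
      wrow <- wilcoxon[wilcoxon$tf_name == kw$tf_name[i] & wilcoxon$pair == pr, ]
      lab[i, pr] <- if (nrow(wrow) && wrow$adj_p[1L] < alpha) 2L else 1L
    }
  }
  lab
}

#' Cluster TFs on their label rows
#'
#' Euclidean distances between 0/1/2 label rows, complete linkage.
#'
#' @param labels Label matrix from [label_tfs()] (>= 2 TFs).
#' @return List: `hclust` (see [hclust_complete()]), `leaf_order`
#'   (TF names in dendrogram order).
#' @export
cluster_tfs <- function(labels) {
  stopifnot(nrow(labels) >= 2L)
  D <- as.matrix(stats::dist(labels, method = "euclidean"))
  hc <- hclust_complete(D, labels = rownames(labels))
  list(hclust = hc, leaf_order = rownames(labels)[hc$order])
}

#' Chaperone-client enrichment among candidate TFs
#'
#' Upper-tail hypergeometric test of the overlap between the candidate
#' list and the client list within the tested TF universe. Both tail
#' conventions are reported: `p_ge` is the inclusive tail P(X >= k);
#' `p_gt` is the exclusive tail P(X > k), the value produced by
#' upper-tail CDF calls that exclude the boundary (the convention common
#' in published enrichment analyses). The two differ noticeably at small
#' counts.
#'
#' @param candidates,clients,universe Character vectors of TF names;
#'   candidates and clients must lie within the universe.
#' @return One-row data frame: k, K, n, N, p_ge, p_gt.
#' @export
client_enrichment <- function(candidates, clients, universe) {
  if (length(universe) == 0L) stop("empty universe")
  candidates <- intersect(candidates, universe)
  clients <- intersect(clients, universe)
  k <- length(intersect(candidates, clients))
  K <- length(clients); n <- length(candidates); N <- length(universe)
  data.frame(k = k, K = K, n = n, N = N,
             p_ge = hypergeometric_ge(k, K, n, N),
             p_gt = if (k + 1L > min(K, n)) 0 else
               hypergeometric_ge(k + 1L, K, n, N))
}

#' GO term over-representation of a gene set
#'
#' Per GO term annotated in the universe, an upper-tail hypergeometric
#' test of the overlap with the gene set, Bonferroni adjusted over terms.
#'
#' @param gene_set Character vector of genes (subset of universe).
#' @param go_map Named list gene_id -> GO term ids.
#' @param universe Character vector of background genes.
#' @param alpha Significance threshold on adjusted p (default 0.05).
#' @return Data frame: term_id, k, K, n, N, p, adj_p, significant;
#'   empty (with a warning) for an empty gene set.
#' @export
go_enrichment <- function(gene_set, go_map, universe, alpha = 0.05) {
  empty <- data.frame(term_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      adj_p = numeric(0), significant = logical(0))
  if (length(gene_set) == 0L) {
    warning("empty gene set: no enrichment computed")
    return(empty)
  }
  gene_set <- intersect(unique(gene_set), universe)
  gm <- go_map[intersect(names(go_map), universe)]
  term_genes <- split(rep(names(gm), lengths(gm)), unlist(gm, use.names = FALSE))
  term_genes <- lapply(term_genes, unique)
  if (!length(term_genes)) return(empty)
  N <- length(universe); n <- length(gene_set)
  rows <- lapply(names(term_genes), function(term) {
    K <- length(term_genes[[term]])
    k <- length(intersect(gene_set, term_genes[[term]]))
    data.frame(term_id = term, k = k, K = K, n = n, N = N,
               p = hypergeometric_ge(k, K, n, N))
  })
  tab <- do.call(rbind, rows)
  tab$adj_p <- adjust_p(tab$p, "bonferroni")
  tab$significant <- tab$adj_p < alpha
  tab[order(tab$p), ]
}

#' Run the full TF-candidate cascade
#'
#' Exclusion of small regulons, the Kruskal-Wallis screen, pairwise
#' Wilcoxon tests, pair-specific enrichment, and the 0/1/2 label matrix.
#'
#' @param target_sets Output of [build_target_sets()].
#' @param de_list Named list strain -> DE table.
#' @param pair_records Named list pair -> table from [pair_specific()].
#' @param min_targets Regulon-size exclusion threshold (default 3).
#' @param alpha Threshold used throughout (default 0.05).
#' @return List: excluded, kw, wilcoxon, enrichment, labels,
#'   candidates, high_confidence.
#' @export
run_tf_cascade <- function(target_sets, de_list, pair_records,
                           min_targets = 3L, alpha = 0.05) {
  ex <- exclude_small_tfs(target_sets, min_targets)
  if (!length(ex$kept)) stop("no TF passes the minimum-target filter")
  kw <- kw_screen(ex$kept, de_list, alpha)
  candidates <- kw$tf_name[kw$is_candidate]
  wil <- pairwise_wilcoxon(ex$kept, de_list, candidates)
  enr <- pair_enrichment(ex$kept, pair_records, candidates, alpha)
  labels <- label_tfs(kw, wil, pairs = strain_pairs(names(de_list)), alpha = alpha)
  list(excluded = names(ex$excluded), kw = kw, wilcoxon = wil,
       enrichment = enr$table, labels = labels,
       candidates = candidates, high_confidence = enr$high_confidence)
}
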