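stop_format <- function(...) {
  stop(structure(class = c("format_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased and must consist of A, C, G, T or N only.
#' Record order in the file is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop_format("not parseable as FASTA: %s", path))
  if (length(set) == 0L) stop_format("empty FASTA file: %s", path)
  seqs <- toupper(as.character(set))
  # first whitespace-delimited token of the header is the id
  names(seqs) <- sub("\\s.*$", "", names(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop_format("illegal character in FASTA record '%s'", names(seqs)[which(bad)[1L]])
  }
  seqs
}

#' Write sequences to FASTA (wrapped at 80 columns)
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read a PWM library
#'
#' One block per TF: a header line `>NAME cutoff=<float>` followed by exactly
#' four rows `A: v1 v2 ...`, `C: ...`, `G: ...`, `T: ...` of whitespace-
#' separated log-likelihood values, all of equal length.
#'
#' @param path Path to the library file.
#' @return List of `pwm` objects (see [pwm()]), in file order.
#' @export
read_pwm_library <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop_format("no PWM blocks in %s", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(b) {
    block <- lines[starts[b]:ends[b]]
    hdr <- block[1L]
    name <- sub("^>\\s*(\\S+).*$", "\\1", hdr)
    if (!grepl("cutoff=", hdr)) stop_format("PWM '%s': missing cutoff", name)
    cutoff <- suppressWarnings(as.numeric(sub("^.*cutoff=([-0-9.eE+]+).*$", "\\1", hdr)))
    if (is.na(cutoff)) stop_format("PWM '%s': unparseable cutoff", name)
    body <- block[-1L]
    if (length(body) != 4L) {
      stop_format("PWM '%s': expected 4 base rows, found %d", name, length(body))
    }
    tags <- sub("^\\s*([ACGT]):.*$", "\\1", body)
    if (!identical(tags, c("A", "C", "G", "T"))) {
      stop_format("PWM '%s': base rows must be A, C, G, T in order", name)
    }
    rows <- lapply(body, function(l) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(sub("^\\s*[ACGT]:", "", l)), "\\s+")[[1L]]))
      if (anyNA(vals)) stop_format("PWM '%s': non-numeric value in a base row", name)
      vals
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop_format("PWM '%s': base rows of unequal length", name)
    }
    pwm(name, do.call(rbind, rows), cutoff)
  })
}

#' Construct a position weight matrix object
#'
#' @param tf_name TF name.
#' @param loglik 4 x L numeric matrix of log-likelihoods, rows A, C, G, T.
#' @param cutoff Score cutoff; windows scoring strictly above it are hits.
#' @return Object of class `pwm`.
#' @export
pwm <- function(tf_name, loglik, cutoff) {
  loglik <- as.matrix(loglik)
  stopifnot(nrow(loglik) == 4L, ncol(loglik) >= 1L,
            all(is.finite(loglik)), is.finite(cutoff))
  rownames(loglik) <- c("A", "C", "G", "T")
  structure(list(tf_name = as.character(tf_name), loglik = loglik,
                 cutoff = as.numeric(cutoff)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s: length %d, cutoff %.4g\n", x$tf_name, ncol(x$loglik), x$cutoff))
  invisible(x)
}

#' Write a PWM library in the dialect read by [read_pwm_library()]
#'
#' @param pwms List of `pwm` objects.
#' @param path Output path.
#' @export
write_pwm_library <- function(pwms, path) {
  out <- unlist(lapply(pwms, function(p) {
    c(sprintf(">%s cutoff=%.10g", p$tf_name, p$cutoff),
      vapply(c("A", "C", "G", "T"), function(b) {
        paste0(b, ": ", paste(formatC(p$loglik[b, ], format = "g", digits = 10),
                              collapse = " "))
      }, character(1L)))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Construct a count experiment
#'
#' Bundles a gene x sample matrix of raw integer counts with its sample
#' sheet (sample_id, strain, condition, replicate).
#'
#' @param counts Integer matrix, rows = genes, columns = samples.
#' @param samples Data frame with columns sample_id, strain, condition,
#'   replicate; `condition` must be "treated" or "untreated".
#' @return Object of class `count_experiment`.
#' @export
count_experiment <- function(counts, samples) {
  counts <- as.matrix(counts)
  samples <- as.data.frame(samples)
  req <- c("sample_id", "strain", "condition", "replicate")
  if (!all(req %in% names(samples))) {
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in sample sheet")
  if (!all(samples$condition %in% c("treated", "untreated"))) {
    stop("condition must be 'treated' or 'untreated'")
  }
  if (is.null(colnames(counts)) || is.null(rownames(counts))) {
    stop("counts must have gene row names and sample column names")
  }
  missing <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing)) {
    stop("sample(s) in counts absent from sample sheet: ",
         paste(missing, collapse = ", "))
  }
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop_format("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "count_experiment")
}

#' @export
print.count_experiment <- function(x, ...) {
  cat(sprintf("count_experiment: %d genes x %d samples (%d strains)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$samples$strain))))
  invisible(x)
}

#' Read a counts TSV and its sample sheet
#'
#' The counts file has a `gene_id` first column and one column per sample;
#' the sample sheet is a TSV with columns sample_id, strain, condition,
#' replicate. Every sample column must appear in the sheet.
#'
#' @param counts_path,samples_path File paths.
#' @return A [count_experiment()].
#' @export
read_counts <- function(counts_path, samples_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_format("counts file needs gene_id plus >=1 sample column")
  genes <- as.character(tab[[1L]])
  dup <- duplicated(genes)
  if (any(dup)) {
    tab <- tab[!dup, , drop = FALSE]
    genes <- genes[!dup]
    warning("duplicate gene_id rows dropped in ", counts_path)
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop_format("non-numeric count in %s", counts_path)
  rownames(m) <- genes
  sheet <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  count_experiment(m, sheet)
}

#' Write a count experiment to a counts TSV and sample-sheet TSV
#'
#' @param expt A [count_experiment()].
#' @param counts_path,samples_path Output paths.
#' @export
write_counts <- function(expt, counts_path, samples_path) {
  df <- data.frame(gene_id = rownames(expt$counts), expt$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expt$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' Read a gene coordinate table
#'
#' TSV with header gene_id, seq_id, start, end, strand; coordinates are
#' 1-based inclusive and the translation start is `start` for +-strand
#' genes and `end` for minus-strand genes.
#'
#' @param path File path.
#' @return Data frame of validated gene records.
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "seq_id", "start", "end", "strand")
  if (!all(req %in% names(tab))) {
    stop_format("gene table must have columns %s", paste(req, collapse = ", "))
  }
  if (anyDuplicated(tab$gene_id)) stop_format("duplicate gene_id in gene table")
  if (!all(tab$strand %in% c("+", "-"))) stop_format("strand must be '+' or '-'")
  if (any(tab$start > tab$end)) stop_format("gene with start > end")
  tab[, req]
}

#' Write a gene coordinate table
#' @param genes Data frame as returned by [read_gene_table()].
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-GO mapping
#'
#' Tab-separated with at least two columns (gene_id, go_id); extra columns
#' are ignored and duplicate (gene, term) pairs collapse.
#'
#' @param path File path.
#' @return Named list: gene_id -> character vector of GO term ids.
#' @export
read_go_map <- function(path) {
  tab <- tryCatch(utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE),
                  error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0L || ncol(tab) < 2L) {
    stop_format("no parsable rows in GO map %s", path)
  }
  pairs <- unique(data.frame(gene = as.character(tab[[1L]]),
                             term = as.character(tab[[2L]]),
                             stringsAsFactors = FALSE))
  split(pairs$term, pairs$gene)
}

#' Write a gene-to-GO mapping TSV
#' @param go_map Named list gene_id -> GO ids.
#' @param path Output path.
#' @export
write_go_map <- function(go_map, path) {
  df <- data.frame(gene_id = rep(names(go_map), lengths(go_map)),
                   go_id = unlist(go_map, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a tree to a newick string
#'
#' @param tree An `ape::phylo` tree with named leaves and branch lengths.
#' @return Newick string terminated by ";".
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label))) {
    stop("all leaves must be named")
  }
  if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
  ape::write.tree(tree)
}

#' Parse a newick string
#' @param text Newick string.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(text) {
  ape::read.tree(text = text)
}
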