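#' Read a substitution matrix in NCBI plain-text layout
#'
#' @param path Path to the matrix file; defaults to the bundled BLOSUM62.
#' @return A symmetric integer matrix with residue row/column names.
#' @export
read_blosum <- function(path = NULL) {
  path <- path %||% system.file("extdata", "BLOSUM62.txt", package = "divrank")
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  syms <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  m <- do.call(rbind, lapply(rows, function(r) as.integer(r[-1])))
  rownames(m) <- vapply(rows, `[`, character(1), 1)
  colnames(m) <- syms
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE))) {
    abort("substitution matrix is not symmetric", class = "divrank_parse_error")
  }
  m
}

#' Convert a substitution matrix into a symbol dissimilarity matrix
#'
#' Each similarity entry is replaced by its deficit from the row's
#' self-similarity, \eqn{a'_{ij} = a_{ii} - a_{ij}}; because the deficit is
#' taken from the row diagonal these raw distances are not symmetric, so
#' the final distance is the average \eqn{(a'_{ij} + a'_{ji})/2}. The
#' result has an exactly zero diagonal and is symmetric.
#'
#' @param m A complete substitution matrix covering the 20 standard amino
#'   acids (extra rows such as B/Z/X are ignored); see [read_blosum()].
#' @return A `symbol_distance` matrix over the 20 amino acids.
#' @export
blosum_to_distance <- function(m = read_blosum()) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort("substitution matrix must be square", class = "divrank_contract_error")
  }
  missing_aa <- setdiff(AMINO_ACIDS, rownames(m))
  if (length(missing_aa) > 0) {
    abort(paste0("substitution matrix lacks amino acids: ",
                 paste(missing_aa, collapse = ", ")),
          class = "divrank_contract_error")
  }
  m <- m[AMINO_ACIDS, AMINO_ACIDS]
  raw <- diag(m) - m          # rows: a_ii - a_ij
  d <- (raw + t(raw)) / 2
  structure(d, class = c("symbol_distance", "matrix"))
}

#' Extend a dissimilarity matrix with gap and non-aligned symbols
#'
#' Adds the two special alignment symbols to an amino-acid dissimilarity
#' matrix: `-` (gap opened by the alignment) at `gap_distance` from every
#' amino acid, and `.` (non-aligned, outside the HSP) at twice that
#' distance, reflecting that a residue never aligned to the query is
#' farther from the amino acids than a gap the alignment itself created.
#' The gap/non-aligned pair is placed at `gap_distance`; both diagonal
#' entries are zero.
#'
#' @param d A `symbol_distance` from [blosum_to_distance()].
#' @param gap_distance Positive gap-to-amino-acid distance. The default
#'   9.5 puts the non-aligned symbol at 19, the stated upper bound of the
#'   BLOSUM62-derived distance matrix.
#' @return A `symbol_distance` over 22 symbols.
#' @export
extend_with_special_symbols <- function(d, gap_distance = 9.5) {
  if (!is.numeric(gap_distance) || length(gap_distance) != 1 || gap_distance <= 0) {
    abort("gap_distance must be a positive number", class = "divrank_contract_error")
  }
  syms <- c(rownames(d), GAP, NONALIGNED)
  n <- length(syms)
  out <- matrix(0, n, n, dimnames = list(syms, syms))
  out[rownames(d), colnames(d)] <- d
  out[GAP, rownames(d)] <- gap_distance
  out[rownames(d), GAP] <- gap_distance
  out[NONALIGNED, rownames(d)] <- 2 * gap_distance
  out[rownames(d), NONALIGNED] <- 2 * gap_distance
  out[GAP, NONALIGNED] <- gap_distance
  out[NONALIGNED, GAP] <- gap_distance
  structure(out, class = c("symbol_distance", "matrix"),
            gap_distance = gap_distance)
}

#' Empirical probability of a symbol within one alignment column
#'
#' @param column Character vector: the column's symbols across rows.
#' @param symbol The symbol whose within-column frequency is wanted.
#' @return A frequency in `[0, 1]`.
#' @export
column_probability <- function(column, symbol) {
  if (length(column) == 0) {
    abort("column must be non-empty", class = "divrank_contract_error")
  }
  mean(as.character(column) == as.character(symbol))
}

#' Rao quadratic entropy of one alignment column
#'
#' \eqn{\sum_i \sum_j p_i p_j d_{ij}} over the symbols present in the
#' column, with \eqn{p} the within-column frequencies and \eqn{d} the
#' symbol dissimilarities. Zero iff the column is uniform; bounded by the
#' largest pairwise distance among the symbols present.
#'
#' @param column Character vector of symbols.
#' @param d A `symbol_distance` covering every symbol in the column.
#' @return The column's quadratic entropy.
#' @export
rao_column_entropy <- function(column, d) {
  if (length(column) == 0) {
    abort("column must be non-empty", class = "divrank_contract_error")
  }
  tab <- table(column)
  syms <- names(tab)
  missing_syms <- setdiff(syms, rownames(d))
  if (length(missing_syms) > 0) {
    abort(paste0("symbols absent from distance matrix: ",
                 paste(missing_syms, collapse = ", ")),
          class = "divrank_contract_error")
  }
  p <- as.numeric(tab) / length(column)
  as.numeric(t(p) %*% d[syms, syms, drop = FALSE] %*% p)
}

#' Rao quadratic-entropy diversity of an aligned result set
#'
#' The mean over alignment columns of the per-column quadratic entropy
#' ([rao_column_entropy()]). Zero exactly when every column is uniform
#' (all rows identical); bounded above by the maximum entry of the
#' distance matrix.
#'
#' @param x A `star_alignment`, or a character matrix of aligned rows.
#' @param d A `symbol_distance`; defaults to the BLOSUM62-derived matrix
#'   extended with gap and non-aligned symbols.
#' @return A one-row tibble: `value`, `n_rows`, `n_columns`.
#' @export
rao_diversity <- function(x, d = extend_with_special_symbols(blosum_to_distance())) {
  rows <- if (inherits(x, "star_alignment")) x$symbols else x
  if (!is.matrix(rows)) rows <- matrix(rows, nrow = 1)
  if (nrow(rows) < 1 || ncol(rows) < 1) {
    abort("need at least one row and one column", class = "divrank_contract_error")
  }
  value <- mean(apply(rows, 2, rao_column_entropy, d = d))
  tibble::tibble(value = value, n_rows = nrow(rows), n_columns = ncol(rows))
}

#' Query coverage of a selection of fragments
#'
#' The fraction of true query positions (insertion columns excluded)
#' aligned by at least one fragment of the selection.
#'
#' @param x A `div_ranking` from [diversify()], or a `star_alignment`.
#' @param prefix Use only the first `prefix` fragments of the ranking
#'   (default: all). For a `star_alignment`, a vector of fragment row
#'   indices may be given instead (default: all rows).
#' @return A fraction in `[0, 1]`.
#' @export
coverage <- function(x, prefix = NULL) {
  if (inherits(x, "div_ranking")) {
    bits <- attr(x, "sel_bits")
    qcols <- attr(x, "query_cols")
    if (!is.null(prefix)) bits <- bits[seq_len(min(prefix, nrow(bits))), , drop = FALSE]
  } else if (inherits(x, "star_alignment")) {
    bits <- x$bits
    qcols <- x$columns$offset == 0L
    if (!is.null(prefix)) bits <- bits[prefix, , drop = FALSE]
  } else {
    abort("coverage() expects a div_ranking or star_alignment",
          class = "divrank_contract_error")
  }
  if (nrow(bits) == 0) return(0)
  mean(colSums(bits[, qcols, drop = FALSE]) > 0)
}

#' Coverage as a function of ranking prefix length
#'
#' For each prefix of the ranking, the query coverage of the fragments
#' selected so far. Monotone non-decreasing by construction. Set
#' `drop_first = TRUE` to exclude the first-ranked fragment before
#' computing the curve (useful when the top hit is the query itself).
#'
#' @param ranking A `div_ranking`.
#' @param drop_first Exclude the seed fragment from the curve.
#' @return A tibble: `prefix`, `fraction_used` (prefix over ranking size),
#'   `coverage`.
#' @export
coverage_curve <- function(ranking, drop_first = FALSE) {
  stopifnot(inherits(ranking, "div_ranking"))
  bits <- attr(ranking, "sel_bits")
  qcols <- attr(ranking, "query_cols")
  if (drop_first) bits <- bits[-1, , drop = FALSE]
  n <- nrow(bits)
  if (n == 0) {
    abort("ranking has no fragments after dropping the first",
          class = "divrank_contract_error")
  }
  bq <- bits[, qcols, drop = FALSE]
  cum <- apply(bq, 2, cummax)
  if (n == 1) cum <- matrix(cum, nrow = 1)
  cov <- rowMeans(cum)
  tibble::tibble(prefix = seq_len(n),
                 fraction_used = seq_len(n) / n,
                 coverage = cov)
}
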