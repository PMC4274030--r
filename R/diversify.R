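#' Hamming (XOR) difference between two bit vectors
#'
#' The elementary dissimilarity of the bit-mask selection rule: the number
#' of positions where exactly one of the two fragments has an aligned
#' residue.
#'
#' @param a,b Equal-length vectors of 0/1 (integer or logical).
#' @return A non-negative integer count.
#' @export
xor_difference <- function(a, b) {
  if (length(a) != length(b)) {
    abort("bit vectors differ in length", class = "divrank_contract_error")
  }
  sum(as.integer(a) != as.integer(b))
}

#' Bit-mask diversity of a candidate against a chosen set
#'
#' Linkage of the per-pair Hamming distances between the candidate's bit
#' mask and each chosen fragment's mask: the mean (average linkage,
#' default), minimum (single) or maximum (complete).
#'
#' @param candidate Bit vector of the candidate fragment.
#' @param chosen Matrix with one chosen fragment's bit vector per row
#'   (a single vector is accepted).
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @return The linkage-aggregated Hamming distance.
#' @export
bit_div <- function(candidate, chosen,
                    linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (is.vector(chosen)) chosen <- matrix(chosen, nrow = 1)
  if (nrow(chosen) == 0) {
    abort("chosen set must be non-empty (the greedy loop seeds with one fragment)",
          class = "divrank_contract_error")
  }
  d <- apply(chosen, 1, xor_difference, b = candidate)
  switch(linkage, average = mean(d), single = min(d), complete = max(d))
}

xlog2x <- function(x) ifelse(x > 0, x * log2(x), 0)

# Scores within a small absolute tolerance of the step maximum are treated
# as tied; the earliest candidate (lowest original rank) wins. The smallest
# genuine score gap at realistic sizes is orders of magnitude above 1e-9,
# so the tolerance only absorbs floating-point summation-order noise.
DIV_TIE_TOL <- 1e-9
argmax_tied <- function(div) which(div >= max(div) - DIV_TIE_TOL)[1]

#' Shannon entropy of one alignment column
#'
#' \eqn{-\sum_x p_x \log_2 p_x} over the symbols present in the column,
#' where \eqn{p_x} is the within-column frequency. Zero for a column
#' uniform in a single symbol; at most \eqn{\log_2 |alphabet|}.
#'
#' @param column Character (or 0/1) vector: the column's symbols, one per row.
#' @param alphabet Symbol set the column is allowed to draw from; entropy
#'   itself only involves symbols actually present.
#' @return Entropy in bits.
#' @export
column_entropy <- function(column, alphabet = RESIDUE_ALPHABET) {
  if (length(column) == 0) {
    abort("column must be non-empty", class = "divrank_contract_error")
  }
  bad <- setdiff(unique(as.character(column)), as.character(alphabet))
  if (length(bad) > 0) {
    abort(paste0("column symbols outside alphabet: ", paste(bad, collapse = ", ")),
          class = "divrank_contract_error")
  }
  p <- table(column) / length(column)
  -sum(xlog2x(as.numeric(p)))
}

# total entropy over all columns from a count matrix (columns x symbols),
# computed as sum_j [log2(m) - (sum_x c log2 c)/m] for m rows
total_entropy_from_counts <- function(counts, m) {
  if (m == 0) return(0)
  S <- rowSums(xlog2x(counts))
  sum(log2(m) - S / m)
}

#' Normalized entropy diversity of a candidate against a chosen set
#'
#' Scores the alignment formed by the chosen fragments plus the candidate
#' by its total column entropy at two levels: residue symbols (20 amino
#' acids, gap and non-aligned) and aligned-position bits. Each total is
#' normalized by its uniform-column upper bound
#' (columns times \eqn{\log_2} alphabet size) and the two ratios averaged.
#' Higher means the candidate makes the selection more heterogeneous.
#'
#' @param candidate_symbols,candidate_bits The candidate's row of the star
#'   alignment and its bit mask.
#' @param chosen_symbols,chosen_bits Matrices of the already-chosen rows
#'   (single vectors accepted).
#' @return The normalized average entropy, in `[0, 1]`.
#' @export
entropy_div <- function(candidate_symbols, candidate_bits,
                        chosen_symbols, chosen_bits) {
  if (is.vector(chosen_symbols)) chosen_symbols <- matrix(chosen_symbols, nrow = 1)
  if (is.vector(chosen_bits)) chosen_bits <- matrix(chosen_bits, nrow = 1)
  if (nrow(chosen_symbols) == 0) {
    abort("chosen set must be non-empty", class = "divrank_contract_error")
  }
  sym <- rbind(chosen_symbols, candidate_symbols)
  bit <- rbind(chosen_bits, candidate_bits)
  d <- ncol(sym)
  m <- nrow(sym)
  counts_sym <- t(apply(sym, 2, function(col)
    tabulate(match(col, RESIDUE_ALPHABET), length(RESIDUE_ALPHABET))))
  counts_bit <- t(apply(bit, 2, function(col) tabulate(col + 1L, 2L)))
  e_aa <- total_entropy_from_counts(counts_sym, m)
  e_bit <- total_entropy_from_counts(counts_bit, m)
  (e_aa / (d * log2(length(RESIDUE_ALPHABET))) + e_bit / d) / 2
}

#' Greedy diversity re-ranking of aligned fragments
#'
#' Re-orders the fragments of a star alignment by greedy selection: the
#' chosen list is seeded with the fragment ranked first by the search
#' tool; each iteration scores every unchosen fragment against the chosen
#' list with the selected rule and appends the highest scorer, until
#' `min(k, n)` fragments are selected. Ties are broken in favour of the
#' lower original rank, preserving the search tool's relevance order.
#'
#' The selection is incremental: the first `k` entries of the ranking do
#' not depend on `k`, so a larger `k` only extends the ranking.
#'
#' @param x A `star_alignment` from [build_star_alignment()].
#' @param k Number of fragments to select (`k > n` returns all `n` ranked).
#' @param method `"bit"` for the average-linkage Hamming rule, `"entropy"`
#'   for the normalized residue+bit entropy rule.
#' @param linkage Linkage for the bit rule; the entropy rule ignores it.
#' @return A `div_ranking`: a tibble with one row per selected fragment
#'   (`new_rank`, `original_rank`, `subject_id`, `method`,
#'   `selection_score`, `qstart`, `qend`, `evalue`, `score`), carrying the
#'   selected rows' bit masks for coverage analysis.
#' @seealso [coverage()], [coverage_curve()], [tidy.div_ranking()]
#' @export
diversify <- function(x, k, method = c("bit", "entropy"),
                      linkage = c("average", "single", "complete")) {
  stopifnot(inherits(x, "star_alignment"))
  method <- match.arg(method)
  linkage <- match.arg(linkage)
  n <- n_fragments(x)
  if (n == 0) {
    abort("no fragments to diversify", class = "divrank_contract_error")
  }
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    abort("k must be a positive integer", class = "divrank_contract_error")
  }
  k <- min(as.integer(k), n)

  ord <- order(x$fragments$original_rank)
  bits <- x$bits[ord, , drop = FALSE]
  sym <- x$symbols[ord, , drop = FALSE]
  d <- ncol(bits)

  chosen <- 1L  # fragment with original_rank 1 seeds the selection
  scores <- NA_real_
  remaining <- setdiff(seq_len(n), chosen)

  if (method == "bit") {
    # pairwise Hamming via inner products: |a| + |b| - 2 a.b
    ones <- rowSums(bits)
    cross <- tcrossprod(bits)
    H <- outer(ones, ones, "+") - 2 * cross
    while (length(chosen) < k) {
      sub <- H[remaining, chosen, drop = FALSE]
      div <- switch(linkage,
                    average = rowMeans(sub),
                    single = apply(sub, 1, min),
                    complete = apply(sub, 1, max))
      best <- remaining[argmax_tied(div)]
      scores <- c(scores, max(div))
      chosen <- c(chosen, best)
      remaining <- setdiff(remaining, best)
    }
  } else {
    # per-column running counts for the chosen set; adding a candidate
    # changes one symbol count per column, so each candidate is O(d)
    sym_idx <- matrix(match(sym, RESIDUE_ALPHABET), nrow = n)
    n_sym <- length(RESIDUE_ALPHABET)
    counts_sym <- matrix(0L, nrow = d, ncol = n_sym)
    counts_bit <- matrix(0L, nrow = d, ncol = 2L)
    add_row <- function(i) {
      js <- cbind(seq_len(d), sym_idx[i, ])
      counts_sym[js] <<- counts_sym[js] + 1L
      jb <- cbind(seq_len(d), bits[i, ] + 1L)
      counts_bit[jb] <<- counts_bit[jb] + 1L
    }
    add_row(1L)
    m <- 1L
    e_aa_max <- d * log2(n_sym)
    e_bit_max <- d
    while (length(chosen) < k) {
      S_sym <- rowSums(xlog2x(counts_sym))
      S_bit <- rowSums(xlog2x(counts_bit))
      div <- vapply(remaining, function(i) {
        c_s <- counts_sym[cbind(seq_len(d), sym_idx[i, ])]
        c_b <- counts_bit[cbind(seq_len(d), bits[i, ] + 1L)]
        s2_sym <- S_sym - xlog2x(c_s) + xlog2x(c_s + 1L)
        s2_bit <- S_bit - xlog2x(c_b) + xlog2x(c_b + 1L)
        e_aa <- sum(log2(m + 1L) - s2_sym / (m + 1L))
        e_bit <- sum(log2(m + 1L) - s2_bit / (m + 1L))
        (e_aa / e_aa_max + e_bit / e_bit_max) / 2
      }, numeric(1))
      best <- remaining[argmax_tied(div)]
      scores <- c(scores, max(div))
      chosen <- c(chosen, best)
      remaining <- setdiff(remaining, best)
      add_row(best)
      m <- m + 1L
    }
  }

  fr <- x$fragments[ord, ][chosen, ]
  out <- tibble::tibble(
    new_rank = seq_along(chosen),
    original_rank = fr$original_rank,
    subject_id = fr$subject_id,
    method = method,
    selection_score = scores,
    qstart = fr$qstart,
    qend = fr$qend,
    evalue = fr$evalue,
    score = fr$score
  )
  structure(out,
            class = c("div_ranking", class(out)),
            method = method, linkage = linkage, k = k,
            n_candidates = n,
            query_length = max(x$columns$pos),
            sel_bits = bits[chosen, , drop = FALSE],
            query_cols = x$columns$offset == 0L)
}

#' @export
print.div_ranking <- function(x, ...) {
  cat("<div_ranking> method=", attr(x, "method"),
      ", k=", attr(x, "k"), " of ", attr(x, "n_candidates"),
      " fragments\n", sep = "")
  NextMethod()
}

#' Tidy a diversity ranking
#'
#' @param x A `div_ranking` from [diversify()].
#' @param ... Unused.
#' @return The ranking as a plain tibble (attributes dropped).
#' @method tidy div_ranking
#' @export
tidy.div_ranking <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a diversity ranking
#'
#' @param x A `div_ranking`.
#' @param ... Unused.
#' @return A one-row tibble: method, linkage, selected/candidate counts,
#'   query coverage of the selection and the final selection score.
#' @method glance div_ranking
#' @export
glance.div_ranking <- function(x, ...) {
  tibble::tibble(
    method = attr(x, "method"),
    linkage = attr(x, "linkage"),
    k = attr(x, "k"),
    n_candidates = attr(x, "n_candidates"),
    coverage = coverage(x),
    final_selection_score = x$selection_score[nrow(x)]
  )
}
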