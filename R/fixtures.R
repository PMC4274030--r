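#' Specification for a synthetic search-result fixture
#'
#' Describes a toy query and fragment set with controlled redundancy and
#' overlap, emulating the typical shape of a protein similarity search
#' result: a cluster of near-identical top hits piled on one region of
#' the query, plus a handful of hits tiling the rest. Identical spec and
#' seed give byte-identical output.
#'
#' @param query_length Query length in residues.
#' @param n_redundant Near-identical fragments clustered on one region.
#' @param n_tilers Fragments tiling the remaining query.
#' @param tile_overlap Fraction of a tile's length shared with its
#'   neighbour, in `[0, 1]`.
#' @param mutation_rate Per-residue substitution probability applied to
#'   each fragment's subject string.
#' @param seed Integer seed; every random draw derives from it.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(query_length = 120, n_redundant = 8, n_tilers = 4,
                         tile_overlap = 0.1, mutation_rate = 0.05, seed = 1) {
  if (query_length < 1 || n_redundant < 0 || n_tilers < 0) {
    abort("counts must be non-negative and query_length positive",
          class = "divrank_spec_error")
  }
  if (tile_overlap < 0 || tile_overlap > 1 || mutation_rate < 0 || mutation_rate > 1) {
    abort("tile_overlap and mutation_rate must lie in [0, 1]",
          class = "divrank_spec_error")
  }
  structure(list(query_length = as.integer(query_length),
                 n_redundant = as.integer(n_redundant),
                 n_tilers = as.integer(n_tilers),
                 tile_overlap = tile_overlap,
                 mutation_rate = mutation_rate,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

mutate_seq <- function(chars, rate) {
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(ch)
      sample(setdiff(AMINO_ACIDS, ch), 1), character(1))
  }
  chars
}

tile_bounds <- function(start, end, n, overlap) {
  R <- end - start + 1L
  if (R < n) {
    abort("query too short for the requested tiling", class = "divrank_spec_error")
  }
  if (n == 1) return(tibble::tibble(qstart = start, qend = end))
  len <- ceiling(R / (1 + (n - 1) * (1 - overlap)))
  if (len < 1 || len > R) {
    abort("query too short for the requested tiling", class = "divrank_spec_error")
  }
  starts <- start + round(seq(0, R - len, length.out = n))
  ends <- pmin(starts + len - 1L, end)
  ends[n] <- end
  tibble::tibble(qstart = as.integer(starts), qend = as.integer(ends))
}

#' Generate a deterministic synthetic query and fragment set
#'
#' Emits a random query, `n_redundant` near-identical fragments covering
#' one region (the first half of the query when tilers are also present,
#' the whole query otherwise), and `n_tilers` fragments tiling the
#' remaining region with the requested overlap. Redundant fragments come
#' first in report order, mirroring how a search tool ranks a pile of
#' close homologs above partial matches. All alignments are gapless.
#'
#' @param spec A [fixture_spec()].
#' @return A list: `query` (a `query_record`) and `hits` (a hit tibble
#'   accepted by [build_star_alignment()]).
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  L <- spec$query_length
  qchars <- sample(AMINO_ACIDS, L, replace = TRUE)
  query <- query_record(sprintf("fixture_query_%d", spec$seed),
                        paste(qchars, collapse = ""))

  both <- spec$n_redundant > 0 && spec$n_tilers > 0
  red_end <- if (both) max(1L, L %/% 2L) else L
  tile_start <- if (both) red_end + 1L else 1L
  if (both && tile_start > L) {
    abort("query too short to host both a redundant region and tiles",
          class = "divrank_spec_error")
  }

  rows <- list()
  if (spec$n_redundant > 0) {
    for (i in seq_len(spec$n_redundant)) {
      seg <- qchars[1:red_end]
      subj <- mutate_seq(seg, spec$mutation_rate)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = sprintf("redundant_%02d", i),
        qstart = 1L, qend = red_end,
        aligned_query = paste(seg, collapse = ""),
        aligned_subject = paste(subj, collapse = ""),
        n_match = sum(subj == seg))
    }
  }
  if (spec$n_tilers > 0) {
    tiles <- tile_bounds(tile_start, L, spec$n_tilers, spec$tile_overlap)
    for (i in seq_len(nrow(tiles))) {
      seg <- qchars[tiles$qstart[i]:tiles$qend[i]]
      subj <- mutate_seq(seg, spec$mutation_rate)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = sprintf("tiler_%02d", i),
        qstart = tiles$qstart[i], qend = tiles$qend[i],
        aligned_query = paste(seg, collapse = ""),
        aligned_subject = paste(subj, collapse = ""),
        n_match = sum(subj == seg))
    }
  }
  if (length(rows) == 0) {
    hits <- new_hit_tbl(character(), integer(), integer(),
                        character(), character(), numeric(), numeric())
    return(list(query = query, hits = hits))
  }
  all_rows <- dplyr::bind_rows(rows)
  score <- 2 * all_rows$n_match  # half-bit-flavoured identity score
  hits <- new_hit_tbl(
    subject_id = all_rows$subject_id,
    qstart = all_rows$qstart, qend = all_rows$qend,
    aligned_query = all_rows$aligned_query,
    aligned_subject = all_rows$aligned_subject,
    score = score,
    evalue = 10^(-score / 10)
  )
  list(query = query, hits = hits)
}
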