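#' Build the query-anchored star alignment
#'
#' Projects every hit onto a shared column coordinate system: one column
#' per query position, plus one insertion column per (query position,
#' offset) needed by the longest insertion run observed at that position
#' across all hits. When two hits insert different numbers of residues
#' after the same position, the shorter insertion is left-aligned and
#' padded with gaps, giving a deterministic, order-independent master
#' coordinate system.
#'
#' Row symbols are the 20 amino acids, `-` for a gap opened inside the
#' fragment's HSP, and `.` for columns outside the HSP span (non-aligned).
#' The distinction matters downstream: the Rao sequence-diversity measure
#' places the non-aligned symbol twice as far from the amino acids as the
#' gap. Each fragment also carries a bit mask with 1 exactly where its
#' symbol is an amino acid.
#'
#' @param query A `query_record` (see [query_record()]).
#' @param hits A hit tibble from [parse_blast_xml()], [parse_blast_tabular()]
#'   or [generate_fixture()]. Coordinates are 1-based inclusive.
#' @return A `star_alignment`: list with `columns` (tibble of `pos`,
#'   `offset`; `offset == 0` marks true query positions), `query_row`
#'   (character vector over columns), `symbols` and `bits` (fragment-by-column
#'   matrices), and `fragments` (per-fragment metadata tibble).
#' @export
build_star_alignment <- function(query, hits) {
  stopifnot(inherits(query, "query_record"))
  validate_hits(hits, query)
  L <- nchar(query$residues)
  qres <- strsplit(query$residues, "")[[1]]
  n <- nrow(hits)

  # First pass: per hit, the column key (pos, offset) of every alignment
  # position; collect the maximal insertion run after each query position.
  walk_hit <- function(aq, as_, qstart) {
    chars_q <- strsplit(aq, "")[[1]]
    chars_s <- strsplit(as_, "")[[1]]
    pos <- integer(length(chars_q))
    off <- integer(length(chars_q))
    p <- qstart - 1L
    o <- 0L
    for (j in seq_along(chars_q)) {
      if (chars_q[j] == GAP) {
        o <- o + 1L
      } else {
        p <- p + 1L
        o <- 0L
      }
      pos[j] <- p
      off[j] <- o
    }
    list(pos = pos, off = off, sym = chars_s)
  }
  walks <- purrr::pmap(
    list(hits$aligned_query, hits$aligned_subject, hits$qstart), walk_hit)

  ins_run <- integer(L + 1L)  # index p+1 = insertions after position p
  for (w in walks) {
    ins <- w$off > 0L
    if (any(ins)) {
      runs <- tapply(w$off[ins], w$pos[ins], max)
      idx <- as.integer(names(runs)) + 1L
      ins_run[idx] <- pmax(ins_run[idx], as.integer(runs))
    }
  }

  col_pos <- integer(0)
  col_off <- integer(0)
  for (p in 0:L) {
    if (p > 0L) {
      col_pos <- c(col_pos, p)
      col_off <- c(col_off, 0L)
    }
    r <- ins_run[p + 1L]
    if (r > 0L) {
      col_pos <- c(col_pos, rep(p, r))
      col_off <- c(col_off, seq_len(r))
    }
  }
  d <- length(col_pos)
  col_index <- setNames(seq_len(d), paste(col_pos, col_off, sep = ":"))

  query_row <- ifelse(col_off == 0L, qres[col_pos], GAP)

  symbols <- matrix(NONALIGNED, nrow = n, ncol = d)
  for (i in seq_len(n)) {
    w <- walks[[i]]
    j <- unname(col_index[paste(w$pos, w$off, sep = ":")])
    symbols[i, j] <- w$sym
    # pad unused insertion columns inside the HSP span with GAP
    inside <- col_off > 0L & col_pos >= hits$qstart[i] & col_pos < hits$qend[i]
    untouched <- inside & !(seq_len(d) %in% j)
    symbols[i, untouched] <- GAP
  }
  bits <- matrix(0L, nrow = n, ncol = d)
  bits[symbols != GAP & symbols != NONALIGNED] <- 1L

  structure(list(
    columns = tibble::tibble(pos = col_pos, offset = col_off),
    query_row = query_row,
    query_id = query$id,
    symbols = symbols,
    bits = bits,
    fragments = dplyr::select(hits, -"aligned_query", -"aligned_subject")
  ), class = "star_alignment")
}

#' @export
print.star_alignment <- function(x, ...) {
  cat("<star_alignment> query ", x$query_id, ": ",
      nrow(x$symbols), " fragments x ", ncol(x$symbols), " columns (",
      sum(x$columns$offset > 0), " insertion columns)\n", sep = "")
  invisible(x)
}

#' Number of fragments / columns of a star alignment
#' @param x A `star_alignment`.
#' @return An integer.
#' @export
n_fragments <- function(x) nrow(x$symbols)

#' @rdname n_fragments
#' @export
n_columns <- function(x) ncol(x$symbols)

#' Fragment rows of a star alignment as a tibble
#'
#' @param x A `star_alignment`.
#' @param ... Unused.
#' @return A tibble with one row per fragment: metadata plus the `symbols`
#'   row and `bits` mask as strings.
#' @method as_tibble star_alignment
#' @export
as_tibble.star_alignment <- function(x, ...) {
  dplyr::mutate(
    x$fragments,
    symbols = apply(x$symbols, 1, paste, collapse = ""),
    bits = apply(x$bits, 1, paste, collapse = "")
  )
}

# Interchange format: aligned FASTA over the star-alignment columns. The
# first record is the query row (gaps mark insertion columns, so the column
# descriptors are recoverable); fragment records encode their metadata in
# the header, pipe-separated.
frag_header <- function(fr) {
  sprintf("%s|rank=%d|qstart=%d|qend=%d|score=%s|evalue=%s",
          fr$subject_id, fr$original_rank, fr$qstart, fr$qend,
          format(fr$score, digits = 15), format(fr$evalue, digits = 15))
}

#' Write a star alignment to its aligned-FASTA interchange format
#'
#' @param x A `star_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_star_alignment <- function(x, path) {
  seqs <- c(paste(x$query_row, collapse = ""),
            apply(x$symbols, 1, paste, collapse = ""))
  names(seqs) <- c(x$query_id,
                   vapply(seq_len(nrow(x$fragments)),
                          function(i) frag_header(x$fragments[i, ]),
                          character(1)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a star alignment from its interchange format
#'
#' @param path Path written by [write_star_alignment()].
#' @return A `star_alignment`.
#' @export
read_star_alignment <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("alignment file not found: ", path), class = "divrank_io_error")
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 1) {
    abort("alignment file has no records", class = "divrank_io_error")
  }
  query_row <- strsplit(as.character(set[[1]]), "")[[1]]
  # gap columns in the query row are insertion columns after the position
  # reached so far; offsets number consecutive gaps within a run
  pos <- cumsum(query_row != GAP)
  off <- integer(length(query_row))
  run <- 0L
  for (j in seq_along(query_row)) {
    if (query_row[j] == GAP) {
      run <- run + 1L
      off[j] <- run
    } else {
      run <- 0L
    }
  }
  meta <- names(set)[-1]
  parse_meta <- function(h) {
    parts <- strsplit(h, "|", fixed = TRUE)[[1]]
    kv <- strsplit(parts[-1], "=", fixed = TRUE)
    vals <- setNames(vapply(kv, `[`, character(1), 2),
                     vapply(kv, `[`, character(1), 1))
    list(subject_id = parts[1], original_rank = as.integer(vals[["rank"]]),
         qstart = as.integer(vals[["qstart"]]), qend = as.integer(vals[["qend"]]),
         score = as.numeric(vals[["score"]]), evalue = as.numeric(vals[["evalue"]]))
  }
  fr <- purrr::map(meta, parse_meta)
  symbols <- do.call(rbind, lapply(as.character(set)[-1],
                                   function(s) strsplit(s, "")[[1]]))
  if (is.null(symbols)) symbols <- matrix(character(), 0, length(query_row))
  if (ncol(symbols) != length(query_row)) {
    abort("fragment rows and query row differ in length",
          class = "divrank_parse_error")
  }
  bits <- matrix(0L, nrow = nrow(symbols), ncol = ncol(symbols))
  bits[symbols != GAP & symbols != NONALIGNED] <- 1L
  structure(list(
    columns = tibble::tibble(pos = as.integer(pos), offset = as.integer(off)),
    query_row = query_row,
    query_id = sub("\\s.*$", "", names(set)[1]),
    symbols = symbols,
    bits = bits,
    fragments = tibble::tibble(
      subject_id = vapply(fr, `[[`, character(1), "subject_id"),
      original_rank = vapply(fr, `[[`, integer(1), "original_rank"),
      qstart = vapply(fr, `[[`, integer(1), "qstart"),
      qend = vapply(fr, `[[`, integer(1), "qend"),
      score = vapply(fr, `[[`, numeric(1), "score"),
      evalue = vapply(fr, `[[`, numeric(1), "evalue")
    )
  ), class = "star_alignment")
}
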