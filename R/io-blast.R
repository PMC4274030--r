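#' Read a protein query sequence from a FASTA file
#'
#' Reads the first record of a FASTA file as the search query. The query
#' defines the coordinate system onto which all hits are projected, so it
#' must be a plain amino-acid sequence (the 20 standard residues plus `X`).
#'
#' @param path Path to a FASTA file; only the first record is used.
#' @return A `query_record`: a list with elements `id` and `residues`.
#' @export
read_query_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("query FASTA not found: ", path), class = "divrank_io_error")
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    abort("query FASTA contains no records", class = "divrank_io_error")
  }
  id <- sub("\\s.*$", "", names(set)[1])
  query_record(id, toupper(as.character(set[[1]])))
}

#' Construct a query record
#'
#' @param id Sequence identifier.
#' @param residues Amino-acid string over the 20-letter alphabet plus `X`.
#' @return A `query_record` list with `id` and `residues`.
#' @export
query_record <- function(id, residues) {
  residues <- toupper(residues)
  if (nchar(residues) < 1) {
    abort("query must contain at least one residue", class = "divrank_contract_error")
  }
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), c(AMINO_ACIDS, "X"))
  if (length(bad) > 0) {
    abort(paste0("query contains non-amino-acid symbols: ",
                 paste(bad, collapse = ", ")),
          class = "divrank_contract_error")
  }
  structure(list(id = as.character(id), residues = residues),
            class = "query_record")
}

#' @export
print.query_record <- function(x, ...) {
  cat("<query_record> ", x$id, " (", nchar(x$residues), " aa)\n", sep = "")
  invisible(x)
}

# Columns every hit table must carry. One row per HSP: BLAST may report
# several HSPs for one subject and each is an independent aligned fragment.
HIT_COLUMNS <- c("subject_id", "original_rank", "qstart", "qend",
                 "aligned_query", "aligned_subject", "score", "evalue")

new_hit_tbl <- function(subject_id, qstart, qend, aligned_query,
                        aligned_subject, score, evalue) {
  tibble::tibble(
    subject_id = as.character(subject_id),
    original_rank = seq_along(subject_id),
    qstart = as.integer(qstart),
    qend = as.integer(qend),
    aligned_query = toupper(as.character(aligned_query)),
    aligned_subject = toupper(as.character(aligned_subject)),
    score = as.numeric(score),
    evalue = as.numeric(evalue)
  )
}

#' Validate a table of raw hits against a query
#'
#' Checks the structural invariants every aligned fragment must satisfy
#' before projection onto the star alignment: equal-length aligned strings,
#' `qstart <= qend <= L`, and agreement between the span width and the
#' number of non-gap characters in the aligned query string.
#'
#' @param hits A tibble of hits as returned by [parse_blast_xml()] or
#'   [parse_blast_tabular()].
#' @param query A `query_record` (or `NULL` to skip the length check).
#' @return `hits`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_hits <- function(hits, query = NULL) {
  missing_cols <- setdiff(HIT_COLUMNS, names(hits))
  if (length(missing_cols) > 0) {
    abort(paste0("hit table lacks columns: ", paste(missing_cols, collapse = ", ")),
          class = "divrank_contract_error")
  }
  if (nrow(hits) == 0) {
    return(invisible(hits))
  }
  if (any(nchar(hits$aligned_query) != nchar(hits$aligned_subject))) {
    i <- which(nchar(hits$aligned_query) != nchar(hits$aligned_subject))[1]
    abort(paste0("aligned query/subject strings differ in length for hit ",
                 hits$subject_id[i], " (rank ", hits$original_rank[i], ")"),
          class = "divrank_contract_error")
  }
  if (any(hits$qend < hits$qstart) || any(hits$qstart < 1)) {
    abort("hit with qend < qstart or qstart < 1", class = "divrank_coordinate_error")
  }
  if (!is.null(query) && any(hits$qend > nchar(query$residues))) {
    abort("hit coordinates exceed query length", class = "divrank_coordinate_error")
  }
  span <- hits$qend - hits$qstart + 1L
  nongap <- nchar(gsub("-", "", hits$aligned_query, fixed = TRUE))
  if (any(span != nongap)) {
    i <- which(span != nongap)[1]
    abort(paste0("aligned query string of hit ", hits$subject_id[i],
                 " has ", nongap[i], " residues but spans ", span[i],
                 " query positions"),
          class = "divrank_contract_error")
  }
  invisible(hits)
}

#' Parse a BLAST XML report (outfmt 5) into a hit table
#'
#' Each HSP becomes one row; a subject with several HSPs contributes one
#' aligned fragment per HSP. `original_rank` follows report order and is
#' the relevance order used to seed diversification.
#'
#' @param path Path to a BLAST XML (`-outfmt 5`) report.
#' @return A tibble with columns `subject_id`, `original_rank`, `qstart`,
#'   `qend`, `aligned_query`, `aligned_subject`, `score`, `evalue`.
#' @export
parse_blast_xml <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      abort(paste0("malformed BLAST XML: ", conditionMessage(e)),
            class = "divrank_parse_error")
    }
  )
  hsps <- xml2::xml_find_all(doc, ".//Hsp")
  if (length(hsps) == 0) {
    return(new_hit_tbl(character(), integer(), integer(),
                       character(), character(), numeric(), numeric()))
  }
  field <- function(node, name) xml2::xml_text(xml2::xml_find_first(node, name))
  hit_of <- function(node) xml2::xml_find_first(node, "ancestor::Hit")
  subject <- vapply(hsps, function(h) {
    hit <- hit_of(h)
    acc <- field(hit, "Hit_accession")
    if (is.na(acc) || acc == "") field(hit, "Hit_id") else acc
  }, character(1))
  qseq <- vapply(hsps, field, character(1), name = "Hsp_qseq")
  sseq <- vapply(hsps, field, character(1), name = "Hsp_hseq")
  if (anyNA(qseq) || anyNA(sseq)) {
    abort("report is unusable: Hsp_qseq/Hsp_hseq aligned strings are missing",
          class = "divrank_unusable_report_error")
  }
  new_hit_tbl(
    subject_id = subject,
    qstart = as.integer(vapply(hsps, field, character(1), name = "Hsp_query-from")),
    qend = as.integer(vapply(hsps, field, character(1), name = "Hsp_query-to")),
    aligned_query = qseq,
    aligned_subject = sseq,
    score = as.numeric(vapply(hsps, field, character(1), name = "Hsp_bit-score")),
    evalue = as.numeric(vapply(hsps, field, character(1), name = "Hsp_evalue"))
  )
}

#' Parse a tabular BLAST report with user-declared columns
#'
#' The standard 12-column `-outfmt 6` layout does not carry the aligned
#' strings; diversification needs them, so the report must have been
#' produced with a custom format including `qseq` and `sseq`
#' (e.g. `-outfmt "6 qseqid sseqid qstart qend evalue bitscore qseq sseq"`).
#'
#' @param path Path to the tab-separated report (no header row).
#' @param columns Character vector naming the columns in file order, using
#'   BLAST outfmt keywords: `sseqid`, `qstart`, `qend`, `qseq`, `sseq` are
#'   required; `bitscore`/`score` and `evalue` are used when present.
#' @return A hit tibble; see [parse_blast_xml()].
#' @export
parse_blast_tabular <- function(path, columns) {
  required <- c("sseqid", "qstart", "qend", "qseq", "sseq")
  missing_cols <- setdiff(required, columns)
  if (length(missing_cols) > 0) {
    abort(paste0("report is unusable without columns: ",
                 paste(missing_cols, collapse = ", "),
                 " (aligned fragments cannot be projected)"),
          class = "divrank_unusable_report_error")
  }
  raw <- readr::read_tsv(path, col_names = columns, comment = "#",
                         show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  score <- if ("bitscore" %in% columns) as.numeric(raw$bitscore)
           else if ("score" %in% columns) as.numeric(raw$score)
           else rep(NA_real_, nrow(raw))
  evalue <- if ("evalue" %in% columns) as.numeric(raw$evalue)
            else rep(NA_real_, nrow(raw))
  hits <- new_hit_tbl(
    subject_id = raw$sseqid,
    qstart = as.integer(raw$qstart),
    qend = as.integer(raw$qend),
    aligned_query = raw$qseq,
    aligned_subject = raw$sseq,
    score = score,
    evalue = evalue
  )
  validate_hits(hits)
  hits
}
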