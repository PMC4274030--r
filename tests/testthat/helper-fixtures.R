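# Writers for small synthetic input files used by the parser tests.

write_toy_blast_xml <- function(path, hits) {
  # hits: list of lists with subject_id and hsps (each hsp: qstart, qend,
  # qseq, sseq, bit_score, evalue)
  hsp_xml <- function(h) {
    paste0(
      "<Hsp><Hsp_bit-score>", h$bit_score %||% 50,
      "</Hsp_bit-score><Hsp_evalue>", h$evalue %||% 1e-10,
      "</Hsp_evalue><Hsp_query-from>", h$qstart,
      "</Hsp_query-from><Hsp_query-to>", h$qend,
      "</Hsp_query-to><Hsp_qseq>", h$qseq,
      "</Hsp_qseq><Hsp_hseq>", h$sseq, "</Hsp_hseq></Hsp>")
  }
  hit_xml <- function(hit, i) {
    paste0("<Hit><Hit_num>", i, "</Hit_num><Hit_id>", hit$subject_id,
           "</Hit_id><Hit_accession>", hit$subject_id,
           "</Hit_accession><Hit_hsps>",
           paste(vapply(hit$hsps, hsp_xml, character(1)), collapse = ""),
           "</Hit_hsps></Hit>")
  }
  body <- paste(mapply(hit_xml, hits, seq_along(hits)), collapse = "")
  writeLines(paste0(
    "<?xml version=\"1.0\"?>",
    "<BlastOutput><BlastOutput_iterations><Iteration><Iteration_hits>",
    body,
    "</Iteration_hits></Iteration></BlastOutput_iterations></BlastOutput>"),
    path)
  path
}

write_toy_obo <- function(path,
                          extra_terms = character(0)) {
  # molecular-function toy DAG:
  #   root <- mid_a <- leaf_a          (chain, is_a)
  #   root <- mid_b <- leaf_b          (second chain)
  #   root <- mid_a/mid_b <- diamond   (two paths to root)
  # plus one biological_process term and one obsolete term
  lines <- c(
    "format-version: 1.2",
    "",
    "[Term]", "id: GO:0000001", "name: root", "namespace: molecular_function",
    "",
    "[Term]", "id: GO:0000002", "name: mid a", "namespace: molecular_function",
    "is_a: GO:0000001 ! root",
    "",
    "[Term]", "id: GO:0000003", "name: leaf a", "namespace: molecular_function",
    "is_a: GO:0000002 ! mid a",
    "",
    "[Term]", "id: GO:0000004", "name: mid b", "namespace: molecular_function",
    "is_a: GO:0000001 ! root",
    "",
    "[Term]", "id: GO:0000005", "name: leaf b", "namespace: molecular_function",
    "is_a: GO:0000004 ! mid b",
    "",
    "[Term]", "id: GO:0000006", "name: diamond", "namespace: molecular_function",
    "is_a: GO:0000002 ! mid a",
    "is_a: GO:0000004 ! mid b",
    "",
    "[Term]", "id: GO:0100001", "name: other namespace",
    "namespace: biological_process",
    "",
    "[Term]", "id: GO:0000007", "name: gone", "namespace: molecular_function",
    "is_obsolete: true",
    extra_terms)
  writeLines(lines, path)
  path
}

# hand-built two-fragment gapless hit table over a given query string
toy_hits <- function(query, spans) {
  qs <- vapply(spans, `[`, numeric(1), 1)
  qe <- vapply(spans, `[`, numeric(1), 2)
  segs <- vapply(seq_along(spans), function(i)
    substr(query, qs[i], qe[i]), character(1))
  tibble::tibble(
    subject_id = sprintf("s%02d", seq_along(spans)),
    original_rank = seq_along(spans),
    qstart = as.integer(qs), qend = as.integer(qe),
    aligned_query = segs, aligned_subject = segs,
    score = 2 * nchar(segs), evalue = 1e-5)
}
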