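#' Load a Gene Ontology DAG from an OBO file
#'
#' Minimal OBO 1.2 reader: `[Term]` stanzas with `id`, `name`,
#' `namespace`, `is_a` and `relationship: part_of` lines. Obsolete terms
#' are dropped, the graph is restricted to one namespace, and edges whose
#' endpoints fall outside the namespace are discarded. The result must be
#' a DAG.
#'
#' @param path Path to an OBO file.
#' @param namespace Ontology namespace to keep
#'   (default `"molecular_function"`).
#' @return A `go_graph`: list with `graph` (directed [igraph::igraph],
#'   child-to-parent edges with a `type` attribute of `is_a` or `part_of`),
#'   `namespace`, and `terms` (tibble of `id`, `name`).
#' @export
load_obo <- function(path, namespace = "molecular_function") {
  if (!file.exists(path)) {
    abort(paste0("OBO file not found: ", path), class = "divrank_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]$", lines)
  bounds <- c(stanza_starts, length(lines) + 1L)

  ids <- character(0); names_ <- character(0); ns <- character(0)
  edges_from <- character(0); edges_to <- character(0); edges_type <- character(0)
  for (s in term_starts) {
    e <- min(bounds[bounds > s]) - 1L
    block <- lines[(s + 1L):e]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": *"), "", grep(paste0("^", key, ":"), block, value = TRUE))
      if (length(v) == 0) NA_character_ else v[1]
    }
    if (identical(get1("is_obsolete"), "true")) next
    id <- get1("id")
    if (is.na(id)) next
    ids <- c(ids, id)
    names_ <- c(names_, get1("name") %||% NA_character_)
    ns <- c(ns, get1("namespace"))
    isa <- sub(" *!.*$", "", sub("^is_a: *", "", grep("^is_a:", block, value = TRUE)))
    po <- grep("^relationship: *part_of ", block, value = TRUE)
    po <- sub(" *!.*$", "", sub("^relationship: *part_of *", "", po))
    edges_from <- c(edges_from, rep(id, length(isa) + length(po)))
    edges_to <- c(edges_to, isa, po)
    edges_type <- c(edges_type, rep("is_a", length(isa)), rep("part_of", length(po)))
  }
  keep <- is.na(ns) | ns == namespace
  terms <- tibble::tibble(id = ids[keep], name = names_[keep])
  ekeep <- edges_from %in% terms$id & edges_to %in% terms$id
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges_from[ekeep], to = edges_to[ekeep],
               type = edges_type[ekeep], stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = terms$id, stringsAsFactors = FALSE))
  if (!igraph::is_dag(g)) {
    abort("ontology contains a cycle: not a valid DAG",
          class = "divrank_corrupt_ontology_error")
  }
  structure(list(graph = g, namespace = namespace, terms = terms),
            class = "go_graph")
}

#' @export
print.go_graph <- function(x, ...) {
  cat("<go_graph> ", x$namespace, ": ", nrow(x$terms), " terms, ",
      igraph::ecount(x$graph), " edges\n", sep = "")
  invisible(x)
}

#' Default semantic-contribution edge weights
#'
#' 0.8 for `is_a` and 0.6 for `part_of`, the weights of Wang et al.'s
#' semantic similarity. The molecular-function ontology carries no
#' `part_of` edges, so only the `is_a` weight matters there.
#' @export
wang_weights <- c(is_a = 0.8, part_of = 0.6)

check_term <- function(term, g) {
  if (!term %in% g$terms$id) {
    abort(paste0("unknown GO term: ", term), class = "divrank_lookup_error")
  }
}

#' Semantic contributions (S-values) of a term's ancestor DAG
#'
#' The anchor term contributes 1 to itself; every ancestor `t` receives
#' the best downward-propagated contribution
#' `max over children c of t within the anchor's DAG of w(type) * S(c)`.
#' The semantic value `SV` of the anchor is the sum of all contributions.
#'
#' @param term Anchor GO term id.
#' @param g A `go_graph`.
#' @param weights Named edge-type weights in `(0, 1)`; see [wang_weights].
#' @return A list: `anchor`, `s` (named vector of contributions over the
#'   anchor plus its ancestors) and `sv` (their sum).
#' @export
s_values <- function(term, g, weights = wang_weights) {
  check_term(term, g)
  graph <- g$graph
  anc <- igraph::subcomponent(graph, term, mode = "out")
  sub <- igraph::induced_subgraph(graph, anc)
  # children before parents: topological order of the child->parent DAG
  topo <- igraph::topo_sort(sub, mode = "out")
  nm <- igraph::V(sub)$name[as.integer(topo)]
  s <- setNames(numeric(length(nm)), nm)
  s[term] <- 1
  el <- igraph::as_data_frame(sub, what = "edges")
  for (t in nm) {
    if (t == term) next
    inc <- el[el$to == t, , drop = FALSE]
    s[t] <- max(weights[inc$type] * s[inc$from])
  }
  list(anchor = term, s = s, sv = sum(s))
}

#' Wang semantic similarity of two GO terms
#'
#' The contributions of the terms shared by the two ancestor DAGs, summed
#' from both sides and normalized by the two semantic values:
#' `sum over common t of (S_A(t) + S_B(t)) / (SV(A) + SV(B))`.
#' Equals 1 iff the terms coincide; positive whenever the terms share the
#' namespace root.
#'
#' @param a,b GO term ids.
#' @param g A `go_graph`.
#' @param weights Edge-type weights; see [wang_weights].
#' @return A similarity in `(0, 1]`.
#' @export
term_similarity <- function(a, b, g, weights = wang_weights) {
  sa <- s_values(a, g, weights)
  sb <- s_values(b, g, weights)
  common <- intersect(names(sa$s), names(sb$s))
  sum(sa$s[common] + sb$s[common]) / (sa$sv + sb$sv)
}

#' Wang similarity of two annotated proteins
#'
#' Aggregates the cross-term similarity matrix of the two annotation sets.
#' The default aggregator is Wang et al.'s best-match average: each term's
#' best match on the other side, averaged over all terms of both sets.
#'
#' @param terms_a,terms_b Non-empty character vectors of GO term ids.
#' @param g A `go_graph`.
#' @param weights Edge-type weights.
#' @param combine `"bma"` (best-match average, default), `"max"` or
#'   `"average"` over the cross-term matrix.
#' @return A similarity in `[0, 1]`; symmetric in its arguments.
#' @export
protein_similarity <- function(terms_a, terms_b, g, weights = wang_weights,
                               combine = c("bma", "max", "average")) {
  combine <- match.arg(combine)
  if (length(terms_a) == 0 || length(terms_b) == 0) {
    abort("protein has no terms in the ontology namespace",
          class = "divrank_contract_error")
  }
  sim <- outer(terms_a, terms_b,
               Vectorize(function(x, y) term_similarity(x, y, g, weights)))
  switch(combine,
         bma = (sum(apply(sim, 1, max)) + sum(apply(sim, 2, max))) /
               (length(terms_a) + length(terms_b)),
         max = max(sim),
         average = mean(sim))
}

#' Functional dissimilarity of a protein result set
#'
#' The mean over unordered protein pairs of one minus the Wang protein
#' similarity. Proteins with no molecular-function annotation in the
#' graph are excluded (with a warning); at least two annotated proteins
#' must remain.
#'
#' @param annotations Named list mapping protein id to a character vector
#'   of GO terms, or a two-column data frame (`protein_id`, `go_id`).
#' @param g A `go_graph`.
#' @param weights Edge-type weights.
#' @param combine Cross-term aggregator; see [protein_similarity()].
#' @return A one-row tibble: `value` in `[0, 1]`, `n_proteins` used,
#'   `n_excluded`.
#' @export
functional_dissimilarity <- function(annotations, g, weights = wang_weights,
                                     combine = "bma") {
  if (is.data.frame(annotations)) {
    annotations <- split(annotations[[2]], annotations[[1]])
  }
  annotations <- lapply(annotations, function(ts) intersect(unique(ts), g$terms$id))
  empty <- vapply(annotations, length, integer(1)) == 0
  if (any(empty)) {
    warn(paste0(sum(empty), " protein(s) without annotations in namespace ",
                g$namespace, " excluded"))
    annotations <- annotations[!empty]
  }
  n <- length(annotations)
  if (n < 2) {
    abort("functional dissimilarity needs at least two annotated proteins",
          class = "divrank_undefined_measure_error")
  }
  pairs <- utils::combn(n, 2)
  dis <- apply(pairs, 2, function(ij) {
    1 - protein_similarity(annotations[[ij[1]]], annotations[[ij[2]]],
                           g, weights, combine)
  })
  tibble::tibble(value = mean(dis), n_proteins = n, n_excluded = sum(empty))
}

#' Read protein-to-GO annotations
#'
#' `read_gaf()` reads a GAF 2.x file (comment lines starting with `!`),
#' keeping the DB object id (column 2), GO id (column 5), evidence code
#' (column 7) and aspect (column 9), filtered to molecular function
#' (`aspect == "F"`). `read_annotation_pairs()` reads a plain two-column
#' TSV of `protein_id`, `go_id`.
#'
#' @param path Input file path.
#' @param exclude_iea Drop electronically inferred (IEA) annotations.
#' @return A tibble with `protein_id`, `go_id`.
#' @export
read_gaf <- function(path, exclude_iea = FALSE) {
  raw <- readr::read_tsv(path, comment = "!", col_names = FALSE,
                         show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 9) {
    abort("GAF file has fewer than 9 columns", class = "divrank_parse_error")
  }
  out <- tibble::tibble(protein_id = raw[[2]], go_id = raw[[5]],
                        evidence = raw[[7]], aspect = raw[[9]])
  out <- dplyr::filter(out, .data$aspect == "F")
  if (exclude_iea) out <- dplyr::filter(out, .data$evidence != "IEA")
  dplyr::distinct(dplyr::select(out, "protein_id", "go_id"))
}

#' @rdname read_gaf
#' @export
read_annotation_pairs <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("protein_id", "go_id"),
                         comment = "#", show_col_types = FALSE,
                         col_types = "cc")
  dplyr::distinct(raw)
}
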