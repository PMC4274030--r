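test_that("bundled BLOSUM62 matches the reference substitution matrix", {
  m <- read_blosum()
  expect_true(all(c("A", "W", "V", "*") %in% rownames(m)))
  expect_equal(m, t(m), ignore_attr = TRUE)
  # independent cross-check against the Biostrings copy
  ref <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  shared <- intersect(rownames(m), rownames(ref))
  expect_equal(m[shared, shared], ref[shared, shared], ignore_attr = TRUE)
})

test_that("the dissimilarity transform gives a symmetric zero-diagonal matrix", {
  d <- blosum_to_distance()
  expect_equal(unname(diag(d)), rep(0, 20))
  expect_equal(unname(d), unname(t(d)))
  expect_true(all(d >= 0))
  # spot-check the deficit-from-diagonal construction by hand:
  # d(A,R) = ((4 - (-1)) + (5 - (-1))) / 2
  m <- read_blosum()
  expect_equal(d["A", "R"], ((m["A", "A"] - m["A", "R"]) +
                             (m["R", "R"] - m["R", "A"])) / 2)
  expect_equal(d["W", "P"], ((m["W", "W"] - m["W", "P"]) +
                             (m["P", "P"] - m["P", "W"])) / 2)
  expect_error(blosum_to_distance(matrix(0, 3, 4)),
               class = "divrank_contract_error")
})

test_that("special symbols extend the matrix with the twice-the-gap rule", {
  d <- extend_with_special_symbols(blosum_to_distance())
  expect_equal(dim(d), c(22, 22))
  expect_equal(unname(diag(d)), rep(0, 22))
  expect_equal(unname(d), unname(t(d)))
  for (aa in c("A", "W", "C")) {
    expect_equal(d[".", aa], 2 * d["-", aa])
  }
  expect_equal(d["-", "."], attr(d, "gap_distance"))
  # default places the non-aligned symbol at the stated matrix maximum, 19
  expect_equal(max(d), 19)
  expect_equal(unname(d[".", "A"]), 19)

  custom <- extend_with_special_symbols(blosum_to_distance(), gap_distance = 4)
  expect_equal(unname(custom[".", "W"]), 8)
  expect_error(extend_with_special_symbols(blosum_to_distance(), gap_distance = 0),
               class = "divrank_contract_error")
})

test_that("column probabilities are within-column frequencies", {
  col1 <- c("G", "G", "G", "-")
  expect_equal(column_probability(col1, "G"), 0.75)
  expect_equal(column_probability(col1, "-"), 0.25)
  expect_equal(column_probability(rep("A", 7), "A"), 1.0)
  expect_equal(column_probability(col1, "W"), 0)
  expect_error(column_probability(character(0), "A"),
               class = "divrank_contract_error")
})

test_that("column quadratic entropy follows the p' d p closed forms", {
  d <- extend_with_special_symbols(blosum_to_distance())
  expect_equal(rao_column_entropy(rep("W", 5), d), 0)
  # 50/50 split at distance d gives 0.5 d
  expect_equal(rao_column_entropy(c("A", "A", "W", "W"), d), 0.5 * d["A", "W"])
  expect_error(rao_column_entropy(c("A", "Z"), d),
               class = "divrank_contract_error")
  set.seed(9)
  for (rep in 1:10) {
    col <- sample(rownames(d), 4, replace = TRUE)
    expect_equal(rao_column_entropy(col, d),
                 oracle_rao(matrix(col, ncol = 1), d))
  }
})

test_that("Rao diversity is a bounded column average with exact zero floor", {
  d <- extend_with_special_symbols(blosum_to_distance())
  identical_rows <- matrix(rep(strsplit("MKTAYIARQW", "")[[1]], 3),
                           nrow = 3, byrow = TRUE)
  expect_equal(rao_diversity(identical_rows, d)$value, 0)

  set.seed(10)
  for (rep in 1:8) {
    rows <- matrix(sample(rownames(d), 3 * 6, replace = TRUE), nrow = 3)
    res <- rao_diversity(rows, d)
    expect_equal(res$value, oracle_rao(rows, d), tolerance = 1e-12)
    expect_lte(res$value, max(d))
    # permutation invariance over rows and over columns
    expect_equal(rao_diversity(rows[sample(3), sample(6)], d)$value, res$value)
    # duplicating the whole row set leaves frequencies, hence the value
    expect_equal(rao_diversity(rbind(rows, rows), d)$value, res$value)
  }

  # the amino-acid-only matrix bounds the measure by its own maximum
  d20 <- blosum_to_distance()
  rows20 <- matrix(sample(rownames(d20), 4 * 8, replace = TRUE), nrow = 4)
  expect_lte(rao_diversity(rows20, d20)$value, max(d20) + 1e-12)
})

test_that("coverage counts query positions aligned by the selection", {
  q <- query_record("q", "MKTAYIARQW")
  halves <- build_star_alignment(q, toy_hits("MKTAYIARQW",
                                             list(c(1, 5), c(6, 10))))
  expect_equal(coverage(halves), 1.0)
  expect_equal(coverage(halves, prefix = 1), 0.5)

  first_half <- build_star_alignment(q, toy_hits("MKTAYIARQW", list(c(1, 5))))
  expect_equal(coverage(first_half), 0.5)
  empty_sel <- build_star_alignment(q, toy_hits("MKTAYIARQW", list(c(1, 5))))
  expect_equal(coverage(empty_sel, prefix = integer(0)), 0)
})

test_that("coverage ignores insertion columns", {
  q <- query_record("q", "ACGT")
  hits <- tibble::tibble(
    subject_id = "ins", original_rank = 1L, qstart = 1L, qend = 4L,
    aligned_query = "AC-GT", aligned_subject = "ACWGT",
    score = 10, evalue = 1e-5)
  sa <- build_star_alignment(q, hits)
  expect_equal(n_columns(sa), 5)
  expect_equal(coverage(sa), 1.0)  # 4 of 4 query positions, not 5 of 5
})

test_that("coverage curves are monotone and plateau where fragments repeat", {
  q <- query_record("q", "MKTAYIARQW")
  same_half <- build_star_alignment(
    q, toy_hits("MKTAYIARQW", list(c(1, 5), c(1, 5), c(1, 5))))
  r <- diversify(same_half, k = 3, method = "bit")
  cc <- coverage_curve(r)
  expect_equal(cc$coverage, rep(0.5, 3))

  full_first <- build_star_alignment(q, toy_hits("MKTAYIARQW", list(c(1, 10))))
  cc1 <- coverage_curve(diversify(full_first, k = 1, method = "bit"))
  expect_equal(cc1$coverage, 1.0)

  for (seed in 501:506) {
    case <- random_case(seed)
    r <- diversify(case$sa, k = n_fragments(case$sa), method = "entropy")
    cc <- coverage_curve(r)
    expect_true(all(diff(cc$coverage) >= 0))
  }
})

test_that("diversified prefixes dominate original order on cluster+tiler sets", {
  # redundant cluster first in report order, tilers later: the greedy
  # ranking must reach full coverage with a prefix no longer than the
  # original order needs
  prefix_to_full <- function(bits_in_order, qcols) {
    cum <- apply(bits_in_order[, qcols, drop = FALSE], 2, cummax)
    if (nrow(bits_in_order) == 1) cum <- matrix(cum, nrow = 1)
    cov <- rowMeans(cum)
    if (max(cov) < 1) return(NA_integer_)
    which(cov >= 1)[1]
  }
  for (seed in 601:612) {
    fx <- generate_fixture(fixture_spec(query_length = 50,
                                        n_redundant = 6, n_tilers = 3,
                                        tile_overlap = 0.2,
                                        mutation_rate = 0.05, seed = seed))
    sa <- build_star_alignment(fx$query, fx$hits)
    qcols <- sa$columns$offset == 0
    orig <- prefix_to_full(sa$bits, qcols)
    for (method in c("bit", "entropy")) {
      r <- diversify(sa, k = n_fragments(sa), method = method)
      divp <- prefix_to_full(attr(r, "sel_bits"), qcols)
      expect_lte(divp, orig)
    }
  }
})
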