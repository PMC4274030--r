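# Independent brute-force oracles. These deliberately avoid the package's
# computational paths: plain loops, direct textbook formulas.

oracle_hamming <- function(a, b) {
  n <- 0L
  for (j in seq_along(a)) if (a[j] != b[j]) n <- n + 1L
  n
}

oracle_entropy_total <- function(mat, alphabet) {
  # sum over columns of -sum_x p_x log2 p_x, straight from the definition
  total <- 0
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    for (x in unique(col)) {
      p <- sum(col == x) / length(col)
      total <- total - p * log2(p)
    }
  }
  total
}

# Per-step greedy argmax re-implementation (first max wins, matching the
# lowest-original-rank tie rule when rows are in rank order).
oracle_diversify <- function(symbols, bits, k, method) {
  n <- nrow(bits)
  d <- ncol(bits)
  alphabet22 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "-", ".")
  chosen <- 1L
  remaining <- setdiff(seq_len(n), chosen)
  k <- min(k, n)
  while (length(chosen) < k) {
    divs <- numeric(length(remaining))
    for (ri in seq_along(remaining)) {
      i <- remaining[ri]
      if (method == "bit") {
        ds <- vapply(chosen, function(c) oracle_hamming(bits[i, ], bits[c, ]),
                     numeric(1))
        divs[ri] <- mean(ds)
      } else {
        sym_set <- symbols[c(chosen, i), , drop = FALSE]
        bit_set <- bits[c(chosen, i), , drop = FALSE]
        e_aa <- oracle_entropy_total(sym_set, alphabet22)
        e_bit <- oracle_entropy_total(bit_set, c(0L, 1L))
        divs[ri] <- (e_aa / (d * log2(22)) + e_bit / d) / 2
      }
    }
    best <- remaining[which(divs >= max(divs) - 1e-9)[1]]
    chosen <- c(chosen, best)
    remaining <- setdiff(remaining, best)
  }
  chosen
}

oracle_rao <- function(rows, d) {
  # Rao quadratic entropy per column via the ordered double sum, averaged
  total <- 0
  for (h in seq_len(ncol(rows))) {
    col <- rows[, h]
    syms <- unique(col)
    q <- 0
    for (i in syms) for (j in syms) {
      q <- q + (sum(col == i) / length(col)) * (sum(col == j) / length(col)) *
        d[i, j]
    }
    total <- total + q
  }
  total / ncol(rows)
}

# A randomly parameterized generator fixture plus its star alignment;
# small sizes keep the brute-force oracles cheap.
random_case <- function(seed) {
  set.seed(seed)
  spec <- fixture_spec(
    query_length = sample(10:40, 1),
    n_redundant = sample(0:8, 1),
    n_tilers = sample(0:7, 1),
    tile_overlap = stats::runif(1, 0, 0.5),
    mutation_rate = stats::runif(1, 0, 0.3),
    seed = seed)
  if (spec$n_redundant + spec$n_tilers == 0) spec$n_tilers <- 2L
  fx <- generate_fixture(spec)
  list(spec = spec, fx = fx,
       sa = build_star_alignment(fx$query, fx$hits))
}
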