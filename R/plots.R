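#' Plot a diversity ranking
#'
#' Two views of a ranking: `type = "coverage"` draws the query-coverage
#' curve as the ranking prefix grows; `type = "score"` draws each step's
#' winning selection score (the seed has none).
#'
#' @param object A `div_ranking` from [diversify()].
#' @param type `"coverage"` or `"score"`.
#' @param drop_first Passed to [coverage_curve()] for the coverage view.
#' @param ... Unused.
#' @return A [ggplot2::ggplot].
#' @method autoplot div_ranking
#' @export
autoplot.div_ranking <- function(object, type = c("coverage", "score"),
                                 drop_first = FALSE, ...) {
  type <- match.arg(type)
  if (type == "coverage") {
    cc <- coverage_curve(object, drop_first = drop_first)
    ggplot2::ggplot(cc, ggplot2::aes(x = .data$prefix, y = .data$coverage)) +
      ggplot2::geom_step() +
      ggplot2::geom_point(size = 1) +
      ggplot2::scale_y_continuous(limits = c(0, 1)) +
      ggplot2::labs(x = "ranking prefix length", y = "query coverage",
                    title = paste0("Coverage, ", attr(object, "method"),
                                   " diversification")) +
      ggplot2::theme_minimal()
  } else {
    df <- tidy(object)
    ggplot2::ggplot(df[-1, ],
                    ggplot2::aes(x = .data$new_rank, y = .data$selection_score)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 1) +
      ggplot2::labs(x = "selection step", y = "winning Div score",
                    title = paste0("Selection scores, ", attr(object, "method"),
                                   " diversification")) +
      ggplot2::theme_minimal()
  }
}

#' Compare coverage curves of several rankings
#'
#' @param rankings Named list of `div_ranking` objects (names label the
#'   curves).
#' @param drop_first Passed to [coverage_curve()].
#' @return A [ggplot2::ggplot] with one step curve per ranking.
#' @export
plot_coverage_comparison <- function(rankings, drop_first = FALSE) {
  stopifnot(is.list(rankings), length(rankings) >= 1)
  if (is.null(names(rankings))) {
    names(rankings) <- paste0("ranking_", seq_along(rankings))
  }
  df <- purrr::imap_dfr(rankings, function(r, nm) {
    dplyr::mutate(coverage_curve(r, drop_first = drop_first), ranking = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction_used, y = .data$coverage,
                                   colour = .data$ranking)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "fraction of result set used", y = "query coverage") +
    ggplot2::theme_minimal()
}
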