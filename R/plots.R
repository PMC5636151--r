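#' Plot a true allele-frequency histogram
#'
#' Side-by-side somatic/germline bar chart of an [af_histogram()]; with a
#' list of truth sets (an admixture series) one panel per sample shows the
#' somatic mass sliding into the low-frequency bins.
#'
#' @param x An [af_histogram()] tibble, a [truth_set()], or a named list of
#'   truth sets.
#' @param bins Bin count used when `x` is one or more truth sets.
#' @return A ggplot object.
#' @export
plot_af_histogram <- function(x, bins = 10) {
  if (inherits(x, "truth_set")) x <- list(sample = x)
  if (is.list(x) && !is.data.frame(x)) {
    x <- purrr::imap(x, function(t, nm) {
      mutate(af_histogram(t, bins), sample = nm)
    }) |> bind_rows()
  }
  long <- tidyr::pivot_longer(x, c("somatic", "germline"),
                              names_to = "origin", values_to = "n")
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = (.data$af_low + .data$af_high) / 2,
                                    y = .data$n, fill = .data$origin)) +
    ggplot2::geom_col(position = "dodge",
                      width = 0.8 * (long$af_high - long$af_low)[1]) +
    ggplot2::labs(x = "true allele frequency", y = "variants",
                  fill = NULL) +
    ggplot2::theme_minimal()
  if ("sample" %in% names(long)) {
    p <- p + ggplot2::facet_wrap(~sample)
  }
  p
}

#' Plot sensitivity and precision against admixture
#' @param curve An [admixture_curve()] tibble.
#' @return A ggplot object.
#' @export
plot_admixture_curve <- function(curve) {
  long <- tidyr::pivot_longer(as_tibble(curve),
                              c("sensitivity", "precision"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$admixture, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "admixture (fraction normal)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_admixture_curve
#' @param object An `admixture_curve`.
#' @param ... Unused.
#' @export
autoplot.admixture_curve <- function(object, ...) {
  plot_admixture_curve(object)
}

#' Plot a caller-concordance table
#' @param conc A [concordance()] table.
#' @return A ggplot stacked bar chart of call counts by support level.
#' @export
plot_concordance <- function(conc) {
  long <- tidyr::pivot_longer(as_tibble(conc),
                              c("truth_matched", "unmatched"),
                              names_to = "class", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$support), .data$n,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "number of supporting callers", y = "calls",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_concordance
#' @param object A `concordance_table`.
#' @param ... Unused.
#' @export
autoplot.concordance_table <- function(object, ...) {
  plot_concordance(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
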