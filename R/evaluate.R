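#' Score a callset against a truth set
#'
#' A true positive is a truth SNV matched by at least one call; a false
#' positive is a call matching no truth SNV; a false negative is a truth
#' SNV with no matching call. Matching is by position, optionally also by
#' alternate allele (the default, which is stricter). Evaluation is always
#' restricted to SNV truth records, and to target regions when given —
#' calls outside the regions are dropped before scoring, and each call can
#' match at most one truth record.
#'
#' @param calls Callset tibble (`contig`, `pos`, `alt`; extra columns
#'   ignored; a `vclass` column restricts calls to SNVs).
#' @param truth A [truth_set()] or tibble with `contig`, `pos`, `alt`,
#'   `vclass`.
#' @param match_mode `"position_allele"` (default) or `"position"`.
#' @param regions Optional [target_regions()] tibble.
#' @param labels Named list of stratum labels (tool, params_id, admixture,
#'   ...) carried into summaries.
#' @return An object of class `snv_eval` with counts `tp`, `fp`, `fn` and
#'   derived `sensitivity`, `precision`, `harmonic_mean`. Use
#'   [generics::glance()] for a one-row tibble or [generics::tidy()] for
#'   the per-record classification.
#' @export
compare_calls <- function(calls, truth,
                          match_mode = c("position_allele", "position"),
                          regions = NULL, labels = list()) {
  match_mode <- match.arg(match_mode)
  tr <- as_tibble(truth)
  if ("vclass" %in% names(tr)) tr <- tr[tr$vclass == "SNV", , drop = FALSE]
  cl <- as_tibble(calls)
  if ("vclass" %in% names(cl)) cl <- cl[cl$vclass == "SNV", , drop = FALSE]
  if (!is.null(regions)) {
    tr <- tr[in_targets(regions, tr$contig, tr$pos), , drop = FALSE]
    cl <- cl[in_targets(regions, cl$contig, cl$pos), , drop = FALSE]
  }
  key <- function(d) {
    if (match_mode == "position_allele") {
      paste(d$contig, d$pos, d$alt)
    } else {
      paste(d$contig, d$pos)
    }
  }
  tkey <- key(tr); ckey <- unique(key(cl))
  tp <- sum(tkey %in% ckey)
  fn <- nrow(tr) - tp
  fp <- sum(!(ckey %in% tkey))
  structure(
    list(tp = tp, fp = fp, fn = fn,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         harmonic_mean = harmonic_mean(tp, fp, fn),
         match_mode = match_mode, labels = labels,
         truth_matched = tkey %in% ckey,
         call_matched = ckey %in% tkey,
         truth = tr, call_keys = ckey),
    class = "snv_eval")
}

harmonic_mean <- function(tp, fp, fn) {
  s <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  if (is.na(s) || is.na(p)) return(NA_real_)
  if (s + p == 0) return(0)
  2 * s * p / (s + p)
}

#' Build an evaluation result directly from counts
#'
#' For scoring published or externally computed counts without re-running
#' a comparison (e.g. a caller's reported TP/FP against a known truth
#' size).
#'
#' @param tp,fp True/false positive counts.
#' @param fn False negatives; alternatively give `truth_n` and `fn` is
#'   `truth_n - tp`.
#' @param truth_n Total truth SNVs evaluated.
#' @param labels Named list of stratum labels.
#' @return An `snv_eval` object.
#' @export
eval_from_counts <- function(tp, fp, fn = NULL, truth_n = NULL,
                             labels = list()) {
  if (is.null(fn)) {
    if (is.null(truth_n)) abort("give either fn or truth_n")
    fn <- truth_n - tp
  }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(
    list(tp = tp, fp = fp, fn = fn,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         harmonic_mean = harmonic_mean(tp, fp, fn),
         match_mode = NA_character_, labels = labels),
    class = "snv_eval")
}

#' @export
print.snv_eval <- function(x, ...) {
  s <- summarize_eval(x)
  cat("<snv_eval> TP ", x$tp, ", FP ", x$fp, ", FN ", x$fn,
      " | sensitivity ", s$sensitivity_pct, ", precision ",
      s$precision_pct, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row metric summary of an evaluation
#' @param x An `snv_eval`.
#' @param ... Unused.
#' @return Tibble with stratum labels, counts and metrics.
#' @export
glance.snv_eval <- function(x, ...) {
  metrics <- tibble(tp = x$tp, fp = x$fp, fn = x$fn,
                    sensitivity = x$sensitivity, precision = x$precision,
                    harmonic_mean = x$harmonic_mean)
  if (length(x$labels) == 0) return(metrics)
  bind_cols(as_tibble(x$labels), metrics)
}

#' Per-record classification of an evaluation
#' @param x An `snv_eval` produced by [compare_calls()].
#' @param ... Unused.
#' @return Tibble with `record` (truth id or call key) and `status`
#'   (`"TP"`, `"FN"`, `"FP"`).
#' @export
tidy.snv_eval <- function(x, ...) {
  if (is.null(x$truth)) abort("count-only evaluations have no records to tidy")
  bind_rows(
    tibble(record = x$truth$id %||% paste(x$truth$contig, x$truth$pos),
           status = ifelse(x$truth_matched, "TP", "FN")),
    tibble(record = x$call_keys[!x$call_matched], status = "FP"))
}

#' Percentage summary with round-half-up formatting
#'
#' Percentages are `round-half-up(100 * value, decimals)` — the convention
#' under which TP 56,869 of 59,664 truth SNVs prints as sensitivity 95.3%
#' and 24 false positives alongside print as precision 100.0%. Precision is
#' `"NA"` when no calls were made (a silent caller is not rewarded);
#' sensitivity is 0 when `tp = 0` and `fn > 0`.
#'
#' @param x An `snv_eval`.
#' @param decimals Decimal places (default 1).
#' @return Tibble with `sensitivity_pct` and `precision_pct` strings.
#' @export
summarize_eval <- function(x, decimals = 1) {
  stopifnot(decimals >= 0)
  fmt <- function(v) {
    if (is.na(v)) return("NA")
    paste0(formatC(round_half_up(100 * v, decimals),
                   format = "f", digits = decimals), "%")
  }
  sens <- if (x$tp == 0 && x$fn > 0) 0 else x$sensitivity
  tibble(sensitivity_pct = fmt(sens), precision_pct = fmt(x$precision))
}

#' Select the best parameter set per group by harmonic mean
#'
#' Mirrors parameter-sweep reporting: within each tool-by-admixture group
#' the parameter set with the highest harmonic mean of sensitivity and
#' precision wins; ties break toward higher sensitivity, then the
#' lexicographically smallest `params_id`.
#'
#' @param results Tibble of [glance()]-style rows with at least
#'   `harmonic_mean`, `sensitivity`, `params_id` and the grouping columns.
#' @param group_by Character vector of grouping columns present in
#'   `results` (default `c("tool", "admixture")`, intersected with what is
#'   there).
#' @return One row per group.
#' @export
select_best_params <- function(results, group_by = c("tool", "admixture")) {
  if (nrow(results) == 0) abort("empty result group")
  gb <- intersect(group_by, names(results))
  results |>
    group_by(across(all_of(gb))) |>
    arrange(desc(.data$harmonic_mean), desc(.data$sensitivity),
            .data$params_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' Concordance of calls across multiple callers
#'
#' For every site in the union of calls, counts how many callers support
#' it, split by whether the site matches a truth SNV.
#'
#' @param callsets Named list (length >= 2) of callset tibbles.
#' @param truth A [truth_set()] (or tibble with `contig`, `pos`, `alt`,
#'   `vclass`).
#' @param match_mode `"position_allele"` or `"position"`.
#' @param regions Optional [target_regions()] restriction.
#' @return A tibble of class `concordance_table`: `support` (number of
#'   callers), `truth_matched`, `unmatched`, `total`, `proportion` (of the
#'   call union).
#' @export
concordance <- function(callsets, truth,
                        match_mode = c("position_allele", "position"),
                        regions = NULL) {
  match_mode <- match.arg(match_mode)
  if (length(callsets) < 2) abort("concordance needs at least two callsets")
  tr <- as_tibble(truth)
  if ("vclass" %in% names(tr)) tr <- tr[tr$vclass == "SNV", , drop = FALSE]
  if (!is.null(regions)) {
    tr <- tr[in_targets(regions, tr$contig, tr$pos), , drop = FALSE]
  }
  key <- function(d) {
    if (match_mode == "position_allele") paste(d$contig, d$pos, d$alt)
    else paste(d$contig, d$pos)
  }
  keysets <- lapply(callsets, function(cl) {
    cl <- as_tibble(cl)
    if ("vclass" %in% names(cl)) cl <- cl[cl$vclass == "SNV", , drop = FALSE]
    if (!is.null(regions)) {
      cl <- cl[in_targets(regions, cl$contig, cl$pos), , drop = FALSE]
    }
    unique(key(cl))
  })
  support <- table(unlist(keysets))
  tkey <- key(tr)
  matched <- names(support) %in% tkey
  n_union <- length(support)
  out <- tibble(support = as.integer(support), truth_hit = matched) |>
    count(.data$support, .data$truth_hit) |>
    tidyr::pivot_wider(names_from = "truth_hit", values_from = "n",
                       values_fill = 0L)
  full <- tibble(support = seq_along(callsets))
  out <- left_join(full, out, by = "support")
  out$truth_matched <- out[["TRUE"]] %||% 0L
  out$unmatched <- out[["FALSE"]] %||% 0L
  out$truth_matched[is.na(out$truth_matched)] <- 0L
  out$unmatched[is.na(out$unmatched)] <- 0L
  out <- out |>
    transmute(.data$support, .data$truth_matched, .data$unmatched,
              total = .data$truth_matched + .data$unmatched,
              proportion = .data$total / n_union)
  class(out) <- c("concordance_table", class(out))
  attr(out, "n_union") <- n_union
  out
}

#' Sensitivity/precision response to admixture
#'
#' Arranges one best evaluation per admixture level into a curve, the
#' tabular form of sensitivity-vs-admixture benchmarking plots.
#'
#' @param results Tibble with one row per admixture level, containing
#'   `admixture`, `sensitivity`, `precision` (e.g. from
#'   [select_best_params()]).
#' @return Tibble sorted by `admixture`, class `admixture_curve`.
#' @export
admixture_curve <- function(results) {
  stopifnot(all(c("admixture", "sensitivity", "precision") %in%
                  names(results)))
  if (anyDuplicated(results$admixture)) {
    abort("duplicate admixture level in curve input")
  }
  out <- arrange(as_tibble(results), .data$admixture)
  class(out) <- c("admixture_curve", class(out))
  out
}
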