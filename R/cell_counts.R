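#' Cell-count summary for one culture condition
#'
#' Integer counts from a fixed imaged volume: total cells (nuclear stain) and
#' marker-positive cells (e.g. a neuronal-progenitor marker). Reported
#' dispersions ("+/-" values) may be attached as metadata; they are not used
#' in the arithmetic because the underlying n and error type are not part of
#' the counts.
#'
#' @param condition Condition label.
#' @param total_cells Positive integer: total cell count.
#' @param marker_positive Non-negative integer `<= total_cells`.
#' @param total_sd,marker_sd Optional reported dispersions (metadata only).
#' @param region_dims_um Optional `(x, y, z)` of the counted volume, in um.
#' @return A `count_summary`.
#' @export
count_summary <- function(condition, total_cells, marker_positive,
                          total_sd = NA_real_, marker_sd = NA_real_,
                          region_dims_um = NULL) {
  if (total_cells <= 0)
    stop_fibralign("total_cells must be positive", "fibralign_input_error")
  if (marker_positive < 0 || marker_positive > total_cells)
    stop_fibralign("need 0 <= marker_positive <= total_cells",
                   "fibralign_input_error")
  structure(list(condition = as.character(condition),
                 total_cells = total_cells,
                 marker_positive = marker_positive,
                 total_sd = total_sd, marker_sd = marker_sd,
                 region_dims_um = region_dims_um),
            class = "count_summary")
}

#' Marker-positive fraction, in percent
#'
#' `100 * marker_positive / total_cells`, rounded half-up to 1 decimal, the
#' form in which such fractions are conventionally reported.
#'
#' @param c A [count_summary()].
#' @return Percentage with 1 decimal.
#' @examples
#' positive_fraction(count_summary("SPRPix", 2600, 930))   # 35.8
#' positive_fraction(count_summary("rSS-PCL", 1850, 174))  # 9.4
#' @export
positive_fraction <- function(c) {
  stopifnot(inherits(c, "count_summary"))
  if (c$total_cells <= 0)
    stop_fibralign("division by zero total", "fibralign_division_error")
  round_half_up(100 * c$marker_positive / c$total_cells, 1)
}

#' Fold change between two positive quantities
#'
#' @param numerator,denominator Positive reals.
#' @param decimals Decimals in the rounded ratio (default 1).
#' @return `numerator / denominator`, rounded half-up.
#' @examples
#' fold_change(2600, 1850)  # 1.4
#' fold_change(930, 174)    # 5.3
#' @export
fold_change <- function(numerator, denominator, decimals = 1) {
  if (!is.finite(denominator) || denominator <= 0)
    stop_fibralign("denominator must be positive", "fibralign_division_error")
  round_half_up(numerator / denominator, decimals)
}

#' Compare two culture conditions
#'
#' Assembles the marker-positive fractions of a reference condition `a` and
#' an alternative condition `b`, and three fold-changes of `b` over `a`:
#' total cells, marker-positive fraction, and marker-positive count. The
#' fraction fold is computed from the unrounded fractions, then rounded.
#'
#' @param a Reference [count_summary()].
#' @param b Alternative [count_summary()].
#' @return A `comparison_report` with `fraction_a_pct`, `fraction_b_pct`,
#'   `total_fold`, `fraction_fold`, `marker_fold`.
#' @examples
#' compare_conditions(count_summary("rSS-PCL", 1850, 174),
#'                    count_summary("SPRPix", 2600, 930))
#' @export
compare_conditions <- function(a, b) {
  stopifnot(inherits(a, "count_summary"), inherits(b, "count_summary"))
  fa_raw <- 100 * a$marker_positive / a$total_cells
  fb_raw <- 100 * b$marker_positive / b$total_cells
  structure(
    list(condition_a = a$condition, condition_b = b$condition,
         fraction_a_pct = round_half_up(fa_raw, 1),
         fraction_b_pct = round_half_up(fb_raw, 1),
         total_fold = fold_change(b$total_cells, a$total_cells),
         fraction_fold = fold_change(fb_raw, fa_raw),
         marker_fold = fold_change(b$marker_positive, a$marker_positive)),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s (ref) vs %s\n",
              x$condition_a, x$condition_b))
  cat(sprintf("  marker-positive fraction: %.1f%% vs %.1f%%\n",
              x$fraction_a_pct, x$fraction_b_pct))
  cat(sprintf("  fold-changes (%s / %s): total %.1f, fraction %.1f, marker count %.1f\n",
              x$condition_b, x$condition_a,
              x$total_fold, x$fraction_fold, x$marker_fold))
  invisible(x)
}

#' Read condition counts from CSV and compare two of them
#'
#' The CSV needs columns `condition`, `total_cells`, `marker_positive`
#' (optional `total_sd`, `marker_sd`).
#'
#' @param path CSV path.
#' @param ref,alt Condition labels: reference and alternative.
#' @return A `comparison_report`.
#' @export
compare_counts_csv <- function(path, ref, alt) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "total_cells", "marker_positive")
  if (!all(need %in% names(df)))
    stop_fibralign(sprintf("CSV must have columns: %s",
                           paste(need, collapse = ", ")),
                   "fibralign_input_error")
  pick <- function(lab) {
    i <- match(lab, df$condition)
    if (is.na(i))
      stop_fibralign(sprintf("condition '%s' not found in %s", lab, path),
                     "fibralign_input_error")
    count_summary(df$condition[i], df$total_cells[i], df$marker_positive[i],
                  total_sd = if ("total_sd" %in% names(df)) df$total_sd[i] else NA_real_,
                  marker_sd = if ("marker_sd" %in% names(df)) df$marker_sd[i] else NA_real_)
  }
  compare_conditions(pick(ref), pick(alt))
}
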