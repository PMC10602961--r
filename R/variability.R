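#' Comparative statistics for splitting values and hemodynamic parameters
#'
#' Utilities reproducing the comparison arithmetic used when tabulating
#' flow-splitting strategies against a reference strategy and when
#' quantifying segmentation-induced parameter scatter: integer-percent
#' deviations, scaled-MAD outlier masks, relative standard deviations and
#' before/after reduction summaries.
#'
#' @name variability_analysis
NULL

# half-away-from-zero rounding to integers (reproduces e.g. -1054.55 -> -1055)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Integer-percent deviation of a splitting value from the reference
#'
#' The deviation of a method's value from the reference value, expressed as
#' an integer percent of the method's own value:
#' `round((value - reference) / value * 100)` with half-away-from-zero
#' rounding. The method's own value in the denominator is the convention
#' used in tabulated splitting-value comparisons (a method predicting 0.002
#' against a reference of 0.020 deviates by -900 percent).
#'
#' @param value Splitting value(s) of the compared method; non-zero.
#' @param reference Reference splitting value(s).
#' @return Integer percent(s).
#' @examples
#' deviation_vs_reference(0.002, 0.020) # -900
#' @export
deviation_vs_reference <- function(value, reference) {
  if (any(value == 0)) stop("deviation_vs_reference: value 0 makes the percentage undefined")
  round_half_away((value - reference) / value * 100)
}

#' Elementwise deviation table against a reference method
#'
#' Applies [deviation_vs_reference()] to every non-reference cell of a long
#' splitting-value table. Zero-valued cells are kept with `NA` deviation
#' (undefined percentage), never dropped.
#'
#' @param table Data frame with columns `outlet`, `method`, `fraction`, and
#'   optionally grouping columns (e.g. `vessel_model`) that identify which
#'   rows share a reference.
#' @param reference_method Method label of the reference column (default
#'   `"bc5"`).
#' @return A tibble like `table` (minus the reference rows) with an added
#'   integer column `deviation_pct`.
#' @export
deviation_table <- function(table, reference_method = "bc5") {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("outlet", "method", "fraction") %in% names(table)))
  if (!reference_method %in% table$method) {
    stop(sprintf("reference method '%s' not present in table", reference_method))
  }
  keys <- intersect(c("vessel_model", "tree", "member", "outlet"), names(table))
  ref <- dplyr::select(
    dplyr::filter(table, .data$method == reference_method),
    dplyr::all_of(keys), reference = "fraction"
  )
  out <- dplyr::left_join(
    dplyr::filter(table, .data$method != reference_method),
    ref, by = keys
  )
  if (any(is.na(out$reference))) {
    stop("deviation_table: some rows have no matching reference cell")
  }
  dev <- rep(NA_real_, nrow(out))
  nz <- out$fraction != 0
  dev[nz] <- deviation_vs_reference(out$fraction[nz], out$reference[nz])
  out$deviation_pct <- dev
  dplyr::select(out, -"reference")
}

#' Scaled-MAD outlier mask
#'
#' Flags values deviating from the median by more than three scaled median
#' absolute deviations (MAD times the normal-consistency constant 1.4826).
#' When the MAD is zero (over half the values identical), any strict
#' deviation from the median is flagged.
#'
#' @param values Numeric vector, length >= 3.
#' @return Logical mask, `TRUE` = outlier.
#' @examples
#' mad_outliers(c(1, 1, 1, 1, 100))
#' @export
mad_outliers <- function(values) {
  if (length(values) < 3) stop("mad_outliers: need at least 3 values")
  if (any(!is.finite(values))) stop("mad_outliers: values must be finite")
  med <- stats::median(values)
  dev <- abs(values - med)
  smad <- stats::mad(values) # 1.4826 * median(|x - median|)
  if (smad == 0) dev > 0 else dev > 3 * smad
}

#' Relative standard deviation (percent of the mean)
#'
#' `100 * sd(values) / mean(values)` with the sample (n - 1) standard
#' deviation; the usual "deviation from the mean" scatter measure.
#'
#' @param values Numeric vector with non-zero mean.
#' @return Percent.
#' @examples
#' relative_sd(c(9, 11)) # 14.142
#' @export
relative_sd <- function(values) {
  m <- mean(values)
  if (m == 0) stop("relative_sd: zero mean makes the relative SD undefined")
  100 * stats::sd(values) / m
}

#' Integer-percent reduction between a before/after pair
#'
#' `round((after - before) / before * 100)` with half-away-from-zero
#' rounding; a drop from 12.2 to 3.8 percent reports -69.
#'
#' @param before Positive percent before exclusion.
#' @param after Percent after exclusion.
#' @return Integer percent (negative = reduction).
#' @export
reduction_percent <- function(before, after) {
  if (any(before <= 0)) stop("reduction_percent: 'before' must be positive")
  round_half_away((after - before) / before * 100)
}

#' Scatter-reduction experiment over a metrics ensemble
#'
#' Quantifies how much of the parameter scatter is attributable to the
#' splitting strategy versus the segmentation, on a long table of per-member
#' per-method metric values:
#'
#' * **method exclusion** (one row per parameter): for each ensemble member
#'   the relative SD of the parameter across methods is computed and
#'   averaged over members, before and after dropping `exclude_methods`.
#' * **segmentation exclusion** (one row per parameter x method): the
#'   relative SD across ensemble members, before and after dropping the
#'   members flagged by [mad_outliers()] within that parameter/method cell
#'   plus any caller-supplied `exclude_members` (e.g. segmentations with
#'   visible surface artifacts, which are a visual call, not auto-detected).
#'
#' Cells with fewer than two surviving values are recorded as `NA`, never
#' silently dropped.
#'
#' @param metrics Data frame with columns `member`, `method`, `parameter`,
#'   `value`.
#' @param exclude_methods Methods dropped in the method-exclusion rows
#'   (default `c("bc1", "bc3")`).
#' @param exclude_members Members always dropped in the
#'   segmentation-exclusion rows (default none).
#' @return An `interplay_summary` tibble with columns `section`
#'   (`"method_exclusion"` / `"segmentation_exclusion"`), `parameter`,
#'   `method` (`NA` for the method-exclusion rows), `before`, `after`
#'   (relative SDs, percent) and `reduction` (integer percent).
#' @export
interplay_experiment <- function(metrics, exclude_methods = c("bc1", "bc3"),
                                 exclude_members = NULL) {
  metrics <- tibble::as_tibble(metrics)
  stopifnot(all(c("member", "method", "parameter", "value") %in% names(metrics)))
  if (length(unique(metrics$member)) < 3) {
    stop("interplay_experiment: need >= 3 ensemble members")
  }
  if (length(unique(metrics$method)) < 2) {
    stop("interplay_experiment: need >= 2 methods")
  }
  rsd_or_na <- function(v) if (length(v) >= 2 && mean(v) != 0) relative_sd(v) else NA_real_

  per_member <- function(df, methods_keep) {
    v <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(df, .data$method %in% methods_keep), .data$member),
      rsd = rsd_or_na(.data$value), .groups = "drop"
    )
    mean(v$rsd)
  }
  methods <- unique(metrics$method)
  part1 <- dplyr::summarise(
    dplyr::group_by(metrics, .data$parameter),
    before = per_member(dplyr::pick(dplyr::everything()), methods),
    after = per_member(dplyr::pick(dplyr::everything()),
                       setdiff(methods, exclude_methods)),
    .groups = "drop"
  )
  part1 <- dplyr::mutate(part1, section = "method_exclusion", method = NA_character_)

  part2 <- dplyr::summarise(
    dplyr::group_by(metrics, .data$parameter, .data$method),
    before = rsd_or_na(.data$value),
    after = {
      v <- .data$value
      keep <- !mad_outliers(v) & !(.data$member %in% exclude_members)
      rsd_or_na(v[keep])
    },
    .groups = "drop"
  )
  part2 <- dplyr::mutate(part2, section = "segmentation_exclusion")

  out <- dplyr::bind_rows(part1, part2)
  out$reduction <- mapply(function(b, a) {
    if (is.na(b) || is.na(a) || b <= 0) NA_real_ else reduction_percent(b, a)
  }, out$before, out$after)
  out <- dplyr::select(out, "section", "parameter", "method",
                       "before", "after", "reduction")
  class(out) <- c("interplay_summary", class(out))
  out
}

#' Plot before/after scatter reductions
#'
#' @param object An `interplay_summary` from [interplay_experiment()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot interplay_summary
#' @export
autoplot.interplay_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("before", "after"),
                              names_to = "stage", values_to = "relative_sd")
  long$stage <- factor(long$stage, levels = c("before", "after"))
  long$panel <- ifelse(is.na(long$method), "method exclusion",
                       paste("segmentation exclusion:", long$method))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$parameter, y = .data$relative_sd,
                                     fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(y = "relative SD (%)", x = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
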