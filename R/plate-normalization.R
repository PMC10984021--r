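#' Cross-plate grand means of the loading controls
#'
#' Duplicate control wells on each plate are averaged per control type, then
#' averaged across plates, yielding one grand mean per control type (GM, WM,
#' mixed).
#'
#' @param controls A `data.frame` with columns `plate_id`, `control_type`,
#'   `value` (one row per control well).
#' @return Named numeric vector of grand means per control type.
#' @export
control_grand_means <- function(controls) {
  if (!nrow(controls)) stopf("empty control set")
  per_plate <- aggregate(value ~ control_type + plate_id, controls, mean)
  out <- tapply(per_plate$value, per_plate$control_type, mean)
  setNames(as.numeric(out), names(out))
}

#' Per-plate correction factor from its control wells
#'
#' Each control value on the plate is divided by the cross-plate grand mean
#' of its control type; ratios are averaged over the duplicate wells of each
#' control, then over the three control types, with equal weight.
#'
#' @param plate_controls Control rows of one plate (`control_type`, `value`).
#' @param grand_means Output of [control_grand_means()].
#' @return A single multiplicative plate factor (1 = plate on target).
#' @export
plate_factor <- function(plate_controls, grand_means) {
  if (any(grand_means <= 0)) stopf("grand means must be positive")
  ratio <- plate_controls$value / grand_means[plate_controls$control_type]
  per_type <- tapply(ratio, plate_controls$control_type, mean)
  mean(per_type)
}

#' Apply a plate correction factor to measured values
#'
#' By default values are divided by the plate factor, which makes the
#' corrected control values equal across plates (a plate reading high is
#' scaled down). `direction = "multiply"` applies the factor literally as a
#' multiplier instead.
#'
#' @param values Numeric vector.
#' @param factor Positive plate factor (recycled).
#' @param direction `"divide"` (default) or `"multiply"`.
#' @return Corrected values.
#' @export
apply_normalization <- function(values, factor,
                                direction = c("divide", "multiply")) {
  direction <- match.arg(direction)
  if (any(factor <= 0)) stopf("plate factor must be positive")
  if (direction == "divide") values / factor else values * factor
}

#' Control-based batch correction of a long value table
#'
#' Convenience wrapper: computes grand means and per-plate factors from the
#' control rows and returns the table with corrected values and a
#' `plate_factor` audit column.
#'
#' @param df A `data.frame` with columns `plate_id`, `content`
#'   (`sample`/`control_*`/`blank`) and `value`.
#' @param direction Passed to [apply_normalization()].
#' @return `df` with `value` corrected and `plate_factor` appended.
#' @export
normalize_plates <- function(df, direction = c("divide", "multiply")) {
  direction <- match.arg(direction)
  ctrl <- df[grepl("^control_", df$content), ]
  if (!nrow(ctrl)) stopf("no control wells present")
  missing_ctrl <- setdiff(unique(df$plate_id), unique(ctrl$plate_id))
  if (length(missing_ctrl))
    stopf("plates without control wells: %s",
          paste(missing_ctrl, collapse = ", "))
  controls <- data.frame(plate_id = ctrl$plate_id,
                         control_type = sub("^control_", "", ctrl$content),
                         value = ctrl$value, stringsAsFactors = FALSE)
  grand <- control_grand_means(controls)
  factors <- vapply(split(controls, controls$plate_id), plate_factor, 0,
                    grand_means = grand)
  f <- factors[df$plate_id]
  df$value <- apply_normalization(df$value, f, direction)
  df$plate_factor <- unname(f)
  df
}
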