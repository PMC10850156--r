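# Puncta-count thresholding and colocalization. A cell is positive for a
# channel when it carries at least `threshold` puncta (4 by default) inside
# its nucleus ROI; colocalization fractions are the conditional fractions
# between the two positive sets. Empty denominators yield an explicit
# "undefined" sentinel, never a division error.

#' Sentinel for an undefined fraction
#'
#' @param reason short explanation of why the denominator was empty.
#' @return An object of class `undefined_fraction` (numeric `NA` carrier).
#' @export
undefined_fraction <- function(reason) {
  structure(NA_real_, reason = reason, class = "undefined_fraction")
}

#' @export
print.undefined_fraction <- function(x, ...) {
  cat(sprintf("undefined fraction (%s)\n", attr(x, "reason")))
  invisible(x)
}

#' Test whether a fraction is defined
#' @param x a fraction returned by [colocalization_fractions()].
#' @return Logical.
#' @export
is_defined <- function(x) !inherits(x, "undefined_fraction")

#' Flag SYP+ / vGLUT2+ cells by puncta threshold
#'
#' A cell is positive for a channel when its puncta count is greater than or
#' equal to the threshold; channels are thresholded independently.
#'
#' @param records data.frame with `cell_id`, `syp_count`, `vglut2_count`.
#' @param threshold puncta threshold (default 4); a length-2 vector gives
#'   per-channel thresholds `c(syp, vglut2)`.
#' @return The table with logical columns `is_syp_pos`, `is_vglut2_pos`.
#' @export
classify_cells <- function(records, threshold = 4) {
  if (nrow(records) == 0)
    ek_stop("empty input: no cells to classify", "ek_empty_error")
  if (any(records$syp_count < 0) || any(records$vglut2_count < 0) ||
      any(records$syp_count != round(records$syp_count)) ||
      any(records$vglut2_count != round(records$vglut2_count)))
    ek_stop("puncta counts must be non-negative integers", "ek_data_error")
  thr <- rep_len(threshold, 2)
  records$is_syp_pos <- records$syp_count >= thr[1]
  records$is_vglut2_pos <- records$vglut2_count >= thr[2]
  records
}

#' Colocalization fractions between the two positive sets
#'
#' Returns the fraction of SYP+ cells that are also vGLUT2+, and the
#' fraction of vGLUT2+ cells that are also SYP+ (set semantics: a
#' double-positive cell counts in both denominators).
#'
#' @param records output of [classify_cells()].
#' @return List with `frac_syp_vglut2`, `frac_vglut2_syp` (each a number in
#'   [0, 1] or an [undefined_fraction()]), and the underlying counts
#'   `n_syp`, `n_vglut2`, `n_double`.
#' @export
colocalization_fractions <- function(records) {
  if (!all(c("is_syp_pos", "is_vglut2_pos") %in% names(records)))
    ek_stop("run classify_cells() first: positivity flags missing",
            "ek_data_error")
  n_syp <- sum(records$is_syp_pos)
  n_vglut2 <- sum(records$is_vglut2_pos)
  n_double <- sum(records$is_syp_pos & records$is_vglut2_pos)
  f1 <- if (n_syp == 0) undefined_fraction("no SYP+ cells") else
    n_double / n_syp
  f2 <- if (n_vglut2 == 0) undefined_fraction("no vGLUT2+ cells") else
    n_double / n_vglut2
  list(frac_syp_vglut2 = f1, frac_vglut2_syp = f2,
       n_syp = n_syp, n_vglut2 = n_vglut2, n_double = n_double)
}

#' Automated-vs-manual count validation
#'
#' Compares automated per-image cell counts to manual counts: per-image
#' overcount (auto - manual) and percentage overcount
#' (100 * (auto - manual) / manual), with their means and standard
#' deviations.
#'
#' @param manual,automated paired per-image counts.
#' @return List with `mean_overcount`, `sd_overcount`, `mean_pct`,
#'   `sd_pct`, `mean_manual`, and the per-image vectors.
#' @export
count_validation <- function(manual, automated) {
  if (length(manual) == 0)
    ek_stop("empty input: no images to validate", "ek_empty_error")
  if (length(manual) != length(automated))
    ek_stop("manual and automated counts must be paired", "ek_data_error")
  if (any(manual <= 0))
    ek_stop("manual counts must be positive for percentage overcount",
            "ek_data_error")
  over <- automated - manual
  pct <- 100 * over / manual
  list(mean_overcount = mean(over),
       sd_overcount = if (length(over) > 1) stats::sd(over) else 0,
       mean_pct = mean(pct),
       sd_pct = if (length(pct) > 1) stats::sd(pct) else 0,
       mean_manual = mean(manual),
       overcount = over, pct = pct)
}
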