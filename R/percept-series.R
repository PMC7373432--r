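#' Drift parameters for synthetic weekly percept series
#'
#' Emulates a drawn percept that migrates and changes size from week to week:
#' the weekly mean centroid drifts by a fixed magnitude along a fixed
#' direction, the area changes multiplicatively, and within-week repetitions
#' scatter around the weekly center.
#'
#' @param center_mm Seed ellipse center `(x, y)` in mm on the template.
#' @param radii_mm Seed ellipse semi-axes in mm.
#' @param centroid_drift_mm_per_week Drift magnitude (mm per week).
#' @param drift_direction Unit-normalized direction of drift (default caudal,
#'   i.e. `(0, 1)` toward increasing y).
#' @param area_change_frac_per_week Multiplicative area change per week
#'   (e.g. -0.1 shrinks the area 10% per week).
#' @param jitter_mm SD of the isotropic within-week repetition scatter (mm).
#' @return A `percept_drift_params` object.
#' @export
percept_drift_params <- function(center_mm, radii_mm,
                                 centroid_drift_mm_per_week = 0,
                                 drift_direction = c(0, 1),
                                 area_change_frac_per_week = 0,
                                 jitter_mm = 0) {
  if (jitter_mm < 0) abort("`jitter_mm` must be non-negative.")
  if (area_change_frac_per_week <= -1)
    abort("`area_change_frac_per_week` must exceed -1.")
  d <- drift_direction / sqrt(sum(drift_direction^2))
  structure(list(center_mm = center_mm, radii_mm = radii_mm,
                 centroid_drift_mm_per_week = centroid_drift_mm_per_week,
                 drift_direction = d,
                 area_change_frac_per_week = area_change_frac_per_week,
                 jitter_mm = jitter_mm),
            class = "percept_drift_params")
}

#' Generate a weekly series of synthetic percept masks
#'
#' Rasterizes one elliptical percept per repetition per week. Week `w`'s
#' nominal center is the seed center displaced by
#' `(w - 1) * centroid_drift_mm_per_week` along the drift direction; its
#' nominal area is the seed area scaled by
#' `(1 + area_change_frac_per_week)^(w - 1)` (semi-axes scale by the square
#' root). Repetitions add isotropic Gaussian jitter to the center. Masks
#' drifting partly outside the labeled template are clipped and flagged.
#'
#' @param template A `percept_template`.
#' @param pd A [percept_drift_params()].
#' @param weeks Number of weeks (>= 2).
#' @param reps_per_week Repetitions per week (>= 1).
#' @param ... Metadata passed to each mask (subject, electrode,
#'   amplitude_mA, ...).
#' @return List of `percept_mask`s with `week` and `repetition` metadata.
#' @export
generate_percept_series <- function(template, pd, weeks, reps_per_week = 3,
                                    ...) {
  stopifnot(inherits(pd, "percept_drift_params"))
  if (weeks < 2) abort("`weeks` must be >= 2.")
  if (reps_per_week < 1) abort("`reps_per_week` must be >= 1.")
  out <- list()
  for (w in seq_len(weeks)) {
    ctr_w <- pd$center_mm +
      (w - 1) * pd$centroid_drift_mm_per_week * pd$drift_direction
    scale_w <- sqrt((1 + pd$area_change_frac_per_week)^(w - 1))
    for (r in seq_len(reps_per_week)) {
      ctr <- ctr_w + rnorm(2, 0, pd$jitter_mm)
      out[[length(out) + 1]] <- ellipse_mask(
        template, ctr, pd$radii_mm * scale_w,
        week = w, repetition = r, ...)
    }
  }
  out
}
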