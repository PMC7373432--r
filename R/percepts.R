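#' Area of a percept mask in square centimeters
#'
#' Pixel count times the template's per-pixel area, which is calibrated so the
#' template's palm region measures exactly the average palmar area (75 cm2).
#'
#' @param mask A `percept_mask`.
#' @return Area (cm2).
#' @export
mask_area_cm2 <- function(mask) {
  stopifnot(inherits(mask, "percept_mask"))
  n <- sum(mask$pixels)
  if (n == 0) abort("percept mask is empty.")
  n * mask$template$cm2_per_px
}

#' Centroid of a percept mask in millimeters
#'
#' Unweighted mean of the member-pixel centers, converted to mm with the
#' hand-length calibration (189 mm fingertip-to-wrist). Coordinates are
#' `(x, y)` from the template's top-left corner, y increasing downward.
#'
#' @param mask A `percept_mask`.
#' @return Named numeric `c(x = , y = )` in mm.
#' @export
mask_centroid_mm <- function(mask) {
  stopifnot(inherits(mask, "percept_mask"))
  idx <- which(mask$pixels, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("percept mask is empty.")
  s <- mask$template$mm_per_px
  c(x = (mean(idx[, "col"]) - 0.5) * s,
    y = (mean(idx[, "row"]) - 0.5) * s)
}

#' Overlap fraction between two percept masks
#'
#' Intersection area divided by the smaller mask's area, so a mask fully
#' contained in another scores 1 regardless of the larger mask's size. The
#' display convention keeps only the more focal (smaller) percept of a pair
#' overlapping by more than 0.70.
#'
#' @param a,b `percept_mask`s on the same template.
#' @return Fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b) {
  stopifnot(inherits(a, "percept_mask"), inherits(b, "percept_mask"))
  if (!identical(a$template$template_id, b$template$template_id) ||
      !identical(dim(a$pixels), dim(b$pixels)))
    abort("masks are on different templates.")
  sum(a$pixels & b$pixels) / min(sum(a$pixels), sum(b$pixels))
}

#' Reference amplitude for weekly stability analysis
#'
#' The amplitude tracked across weeks is the minimum stimulus amplitude tested
#' at least once per week for the maximal number of weeks; coverage must span
#' at least two weeks, otherwise the electrode is excluded.
#'
#' @param trials Data frame with `amplitude_mA` and `week`.
#' @return The reference amplitude (mA), or an error if no amplitude covers
#'   two or more weeks.
#' @export
select_reference_amplitude <- function(trials) {
  stopifnot(all(c("amplitude_mA", "week") %in% names(trials)))
  cov <- trials |>
    dplyr::distinct(.data$amplitude_mA, .data$week) |>
    dplyr::count(.data$amplitude_mA, name = "n_weeks")
  if (max(cov$n_weeks) < 2)
    abort("no amplitude was tested in two or more weeks; electrode excluded.")
  min(cov$amplitude_mA[cov$n_weeks == max(cov$n_weeks)])
}

#' Weekly centroid/area stability series for one electrode
#'
#' Per week, the mean centroid and mean area over all repetitions at the
#' reference amplitude; derived week-over-week values are the Euclidean
#' migration of the mean centroid with respect to the previous week and the
#' change in mean area (reported signed and absolute). Pairs of weeks
#' separated by a gap are skipped and recorded.
#'
#' @param masks List of `percept_mask`s whose metadata carries `week`.
#' @return A `stability_series` tibble: `week`, `n_reps`, `centroid_x_mm`,
#'   `centroid_y_mm`, `area_cm2`, `migration_mm`, `area_change_cm2`,
#'   `abs_area_change_cm2` (derived columns `NA` for the first week and after
#'   gaps); attribute `gaps` lists skipped week pairs.
#' @export
weekly_stability <- function(masks) {
  stopifnot(length(masks) >= 1,
            all(vapply(masks, inherits, logical(1), "percept_mask")))
  per_mask <- purrr::map_dfr(masks, function(m) {
    cen <- mask_centroid_mm(m)
    tibble::tibble(week = m$meta$week, centroid_x_mm = cen["x"],
                   centroid_y_mm = cen["y"], area_cm2 = mask_area_cm2(m))
  })
  if (any(is.na(per_mask$week))) abort("every mask needs a week label.")
  weekly <- per_mask |>
    dplyr::group_by(week = .data$week) |>
    dplyr::summarise(n_reps = dplyr::n(),
                     centroid_x_mm = mean(.data$centroid_x_mm),
                     centroid_y_mm = mean(.data$centroid_y_mm),
                     area_cm2 = mean(.data$area_cm2), .groups = "drop") |>
    dplyr::arrange(.data$week)
  if (nrow(weekly) < 2) abort("need masks from at least two weeks.")
  dw <- c(NA, diff(weekly$week))
  consecutive <- !is.na(dw) & dw == 1
  mig <- sqrt(diff(weekly$centroid_x_mm)^2 + diff(weekly$centroid_y_mm)^2)
  dar <- diff(weekly$area_cm2)
  weekly$migration_mm <- c(NA, mig)
  weekly$area_change_cm2 <- c(NA, dar)
  weekly$migration_mm[!consecutive] <- NA
  weekly$area_change_cm2[!consecutive] <- NA
  weekly$abs_area_change_cm2 <- abs(weekly$area_change_cm2)
  gaps <- weekly$week[which(!is.na(dw) & dw > 1)]
  out <- structure(weekly, gaps = gaps)
  class(out) <- c("stability_series", class(out))
  out
}

#' Pool weekly stability across electrodes
#'
#' Binds per-electrode [weekly_stability()] series and summarises the
#' week-pair medians of centroid migration and (absolute and signed) area
#' change across electrodes.
#'
#' @param series Named list of `stability_series` (names = electrode ids).
#' @return Tibble: `week` (the later week of each pair), `n_electrodes`,
#'   `median_migration_mm`, `median_area_change_cm2`,
#'   `median_abs_area_change_cm2`.
#' @export
pool_stability <- function(series) {
  purrr::imap_dfr(series, function(s, id)
    dplyr::mutate(tibble::as_tibble(s), electrode = id)) |>
    dplyr::filter(!is.na(.data$migration_mm)) |>
    dplyr::group_by(week = .data$week) |>
    dplyr::summarise(
      n_electrodes = dplyr::n(),
      median_migration_mm = median(.data$migration_mm),
      median_area_change_cm2 = median(.data$area_change_cm2),
      median_abs_area_change_cm2 = median(.data$abs_area_change_cm2),
      .groups = "drop")
}

#' Least-squares slope of percept area against stimulation amplitude
#'
#' OLS regression of percept area (cm2) on amplitude (mA) with the two-sided
#' p-value for the null hypothesis of zero slope. Together with the intensity
#' slope from the magnitude-estimation fit, this classifies whether amplitude
#' modulates area, intensity, or both.
#'
#' @param trials Data frame with `amplitude_mA` and `area_cm2`;
#'   at least 3 distinct amplitudes.
#' @return Tibble: `beta_area` (cm2 per mA), `p_area`, `n`.
#' @export
area_amplitude_slope <- function(trials) {
  stopifnot(all(c("amplitude_mA", "area_cm2") %in% names(trials)))
  if (length(unique(trials$amplitude_mA)) < 3)
    abort("need >= 3 distinct amplitudes.")
  f <- lm(area_cm2 ~ amplitude_mA, data = trials)
  s <- summary(f)
  p <- if (sd(trials$area_cm2) == 0) 1 else unname(s$coefficients[2, 4])
  tibble::tibble(beta_area = unname(coef(f)[2]), p_area = p,
                 n = nrow(trials))
}

#' Classify amplitude modulation of intensity vs area for one electrode
#'
#' @param intensity_fit An `intensity_fit` (see [fit_intensity_models()]).
#' @param area_slope One-row tibble from [area_amplitude_slope()].
#' @param alpha_area Significance cut for the area slope (default 0.05) and
#' @param alpha_int for the intensity slope (default 0.01).
#' @return One of `"intensity-and-area"`, `"intensity-only"`, `"area-only"`,
#'   `"neither"`.
#' @export
classify_modulation <- function(intensity_fit, area_slope,
                                alpha_area = 0.05, alpha_int = 0.01) {
  int_sig <- intensity_fit$p_int < alpha_int
  area_sig <- area_slope$p_area < alpha_area
  if (int_sig && area_sig) "intensity-and-area"
  else if (int_sig) "intensity-only"
  else if (area_sig) "area-only"
  else "neither"
}

#' @rdname weekly_stability
#' @param object A `stability_series`.
#' @param ... Unused.
#' @method autoplot stability_series
#' @export
autoplot.stability_series <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("migration_mm", "abs_area_change_cm2"),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$week, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Week", y = NULL) +
    ggplot2::theme_minimal()
}
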