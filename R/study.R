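#' Configuration for a synthetic stimulation study
#'
#' Defines the roster and ground-truth parameter ranges of a simulated
#' multi-week sensory mapping study. Defaults describe a small but complete
#' study: every electrode gets 2AFC detection staircases, JND blocks at the
#' two standard amplitudes (2.5 and 4 mA), six magnitude-estimation blocks,
#' weekly percept drawings, descriptor reports, weekly threshold-charge
#' records, and weekly lead-tip coordinates. All stimulation parameters stay
#' inside the hardware bounds (0–6 mA, 1–300 Hz, 50–1000 us).
#'
#' @param n_subjects Number of subjects.
#' @param electrodes_per_subject Electrodes per subject.
#' @param weeks Study duration in weeks (>= 2).
#' @param reps_per_week Percept drawing repetitions per week.
#' @param mu_range Range (mA) from which each electrode's true detection
#'   threshold is drawn.
#' @param sigma_frac Psychometric spread as a fraction of the threshold.
#' @param detection_sessions Staircase runs per electrode (different days).
#' @param jnd_standards_mA Standard amplitudes for the JND task.
#' @param jnd_mu_mA True JND (amplitude difference at 75% accuracy, mA) at
#'   each standard; defaults follow the Weber-like growth seen with higher
#'   standards (recycled).
#' @param jnd_sigma_mA Discrimination spread at each standard (recycled).
#' @param jnd_levels,jnd_trials_per_level Comparison grid per standard.
#' @param mag_levels,mag_blocks Magnitude-estimation design (levels linearly
#'   spaced from threshold to `max_amplitude_mA`; the first block is the
#'   discarded scale-setting block).
#' @param mag_noise_sd Rating noise SD (on the raw rating scale).
#' @param drift_mm_per_week,area_change_frac_per_week,jitter_mm Percept drift
#'   ground truth passed to [percept_drift_params()].
#' @param pulse_width_us Pulse width used for charge records.
#' @param max_amplitude_mA Stimulator ceiling (6 mA).
#' @param descriptor_profile Named numeric vector of probabilities over
#'   descriptor combinations (names are `+`-joined tokens); defaults to a
#'   mixed-modality-dominant profile.
#' @param n_reports Descriptor reports per electrode.
#' @return A `study_config` list.
#' @export
study_config <- function(n_subjects = 2, electrodes_per_subject = 3,
                         weeks = 4, reps_per_week = 3,
                         mu_range = c(1, 2.5), sigma_frac = 0.2,
                         detection_sessions = 2,
                         jnd_standards_mA = c(2.5, 4),
                         jnd_mu_mA = c(0.08, 0.3),
                         jnd_sigma_mA = c(0.04, 0.15),
                         jnd_levels = 8, jnd_trials_per_level = 40,
                         mag_levels = 8, mag_blocks = 6,
                         mag_noise_sd = 0.5,
                         drift_mm_per_week = 5,
                         area_change_frac_per_week = -0.05,
                         jitter_mm = 2,
                         pulse_width_us = 200,
                         max_amplitude_mA = 6,
                         descriptor_profile = NULL,
                         n_reports = 40) {
  if (weeks < 2) abort("`weeks` must be >= 2.")
  if (is.null(descriptor_profile)) {
    descriptor_profile <- c(
      "electrical" = 0.15,
      "electrical+pressure" = 0.35,
      "electrical+pressure+vibration" = 0.2,
      "pressure" = 0.1, "touch" = 0.05, "vibration" = 0.1,
      "touch+vibration" = 0.05)
    descriptor_profile <- descriptor_profile / sum(descriptor_profile)
  }
  if (abs(sum(descriptor_profile) - 1) > 1e-8)
    abort("descriptor_profile probabilities must sum to 1.")
  structure(as.list(environment()), class = "study_config")
}

# Deterministic per-electrode RNG substream: one master seed per study, fixed
# offsets per (subject, electrode, stage).
substream_seed <- function(seed, subject, electrode, stage) {
  (seed + 7919L * subject + 104729L * electrode + 15485863L * stage) %% .Machine$integer.max
}

#' Generate a complete synthetic study on disk
#'
#' Emits the same file formats the analysis pipeline consumes — CSV trial,
#' rating, report, electrode, charge and lead-track tables; percept masks as
#' PNG with JSON sidecars — plus a `ground_truth.json` recording every
#' generating parameter. The same `(config, seed)` pair always produces
#' byte-identical tables.
#'
#' @param config A [study_config()].
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed; all randomness derives from it.
#' @return Invisibly, a list with the generated tables, the masks, the
#'   template, and `ground_truth`.
#' @export
generate_study <- function(config, dir, seed = 1) {
  stopifnot(inherits(config, "study_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  template <- arm_template()
  cfg <- config

  det <- list(); jnd <- list(); mag <- list(); rep_rows <- list()
  charges <- list(); masks_all <- list(); gt_el <- list()
  mask_centers <- list(
    c(31, 135), c(9, 98), c(54, 40), c(86, 45), c(62, 240), c(63, 450))

  for (s in seq_len(cfg$n_subjects)) {
    for (e in seq_len(cfg$electrodes_per_subject)) {
      el_id <- sprintf("S%d-E%d", s, e)
      set.seed(substream_seed(seed, s, e, 1L))
      mu <- runif(1, cfg$mu_range[1], cfg$mu_range[2])
      sigma <- cfg$sigma_frac * mu
      obs <- observer_params(mu, sigma)
      slope <- runif(1, 0.8, 1.6)
      mp <- magnitude_params(slope = slope, intercept = 0,
                             noise_sd = cfg$mag_noise_sd, floor = mu)

      # detection staircases (one per session/day)
      sc_cfg <- staircase_config(start_amplitude = min(1.5 * mu,
                                                       cfg$max_amplitude_mA),
                                 max_amplitude = cfg$max_amplitude_mA)
      for (day in seq_len(cfg$detection_sessions)) {
        run <- run_staircase(function(a) simulate_2afc(obs, a), sc_cfg)
        det[[length(det) + 1]] <- dplyr::mutate(
          run$trials, subject = s, electrode = el_id, session = day,
          .before = 1)
      }

      # JND blocks at each standard
      set.seed(substream_seed(seed, s, e, 2L))
      for (j in seq_along(cfg$jnd_standards_mA)) {
        std <- cfg$jnd_standards_mA[j]
        mu_d <- cfg$jnd_mu_mA[(j - 1) %% length(cfg$jnd_mu_mA) + 1]
        sig_d <- cfg$jnd_sigma_mA[(j - 1) %% length(cfg$jnd_sigma_mA) + 1]
        deltas <- seq(mu_d / 4, mu_d + 3 * sig_d,
                      length.out = cfg$jnd_levels)
        dobs <- observer_params(mu = mu_d, sigma = sig_d)
        for (d in deltas) {
          corr <- simulate_2afc(dobs, rep(d, cfg$jnd_trials_per_level))
          jnd[[length(jnd) + 1]] <- tibble::tibble(
            subject = s, electrode = el_id, standard_amplitude_mA = std,
            test_amplitude_mA = std + d, correct = corr)
        }
      }

      # magnitude estimation: linearly spaced block, first block discarded
      set.seed(substream_seed(seed, s, e, 3L))
      amps <- seq(mu, cfg$max_amplitude_mA, length.out = cfg$mag_levels)
      for (b in seq_len(cfg$mag_blocks)) {
        order_b <- sample(amps)
        mag[[length(mag) + 1]] <- tibble::tibble(
          subject = s, electrode = el_id, block = b,
          amplitude_mA = order_b,
          rating = simulate_magnitude_rating(mp, order_b))
      }

      # descriptor reports
      set.seed(substream_seed(seed, s, e, 4L))
      combos <- names(cfg$descriptor_profile)
      picks <- sample(combos, cfg$n_reports, replace = TRUE,
                      prob = cfg$descriptor_profile)
      rep_rows[[length(rep_rows) + 1]] <- tibble::tibble(
        subject = s, electrode = el_id, combo = picks)

      # weekly percept masks at the reference amplitude
      set.seed(substream_seed(seed, s, e, 5L))
      ctr_i <- ((s - 1) * cfg$electrodes_per_subject + e - 1) %%
        length(mask_centers) + 1
      ctr <- mask_centers[[ctr_i]][1:2]
      pd <- percept_drift_params(
        center_mm = ctr, radii_mm = c(9, 12),
        centroid_drift_mm_per_week = cfg$drift_mm_per_week,
        area_change_frac_per_week = cfg$area_change_frac_per_week,
        jitter_mm = cfg$jitter_mm)
      ms <- generate_percept_series(template, pd, weeks = cfg$weeks,
                                    reps_per_week = cfg$reps_per_week,
                                    subject = s, electrode = el_id,
                                    amplitude_mA = round(1.2 * mu, 2))
      masks_all[[el_id]] <- ms

      # weekly threshold-charge records (mild week effect + noise)
      set.seed(substream_seed(seed, s, e, 6L))
      for (w in seq_len(cfg$weeks)) {
        amp_w <- mu * (1 + 0.02 * (w - 1)) * exp(rnorm(1, 0, 0.05))
        charges[[length(charges) + 1]] <- tibble::tibble(
          subject = s, electrode = el_id, week = w,
          amplitude_mA = amp_w, pulse_width_us = cfg$pulse_width_us)
      }

      gt_el[[el_id]] <- list(subject = s, electrode = el_id, mu = mu,
                             sigma = sigma, mag_slope = slope,
                             drift_mm_per_week = cfg$drift_mm_per_week,
                             area_change_frac_per_week =
                               cfg$area_change_frac_per_week)
    }
  }

  # electrode metadata + lead tracks
  set.seed(seed + 17L)
  levels_pool <- c("C6", "C7", "C8", "T1")
  electrodes <- purrr::map_dfr(seq_len(cfg$n_subjects), function(s)
    tibble::tibble(subject = s,
                   electrode = sprintf("S%d-E%d", s,
                                       seq_len(cfg$electrodes_per_subject)),
                   lead = ((seq_len(cfg$electrodes_per_subject) - 1) %% 3) + 1,
                   contact = seq_len(cfg$electrodes_per_subject),
                   spinal_level = sample(levels_pool,
                                         cfg$electrodes_per_subject,
                                         replace = TRUE)))
  lead_tracks <- purrr::map_dfr(seq_len(cfg$n_subjects), function(s) {
    purrr::map_dfr(1:3, function(l) {
      drift <- c(0, cumsum(pmax(8 / (1:(cfg$weeks - 1))^1.5 +
                                  rnorm(cfg$weeks - 1, 0, 1), 0)))
      tibble::tibble(subject = s, lead = l, week = seq_len(cfg$weeks),
                     tip_x_px = 100 + rnorm(cfg$weeks, 0, 0.5),
                     tip_y_px = 200 + drift / 0.1)
    })
  })

  detection <- dplyr::bind_rows(det)
  jnd_trials <- dplyr::bind_rows(jnd)
  ratings <- dplyr::bind_rows(mag)
  charges <- dplyr::bind_rows(charges) |>
    dplyr::mutate(charge_nC = threshold_charge(.data$amplitude_mA,
                                               .data$pulse_width_us))
  vocab <- unlist(descriptor_vocabulary(), use.names = FALSE)
  reports <- dplyr::bind_rows(rep_rows)
  for (tok in vocab)
    reports[[tok]] <- as.integer(vapply(
      strsplit(reports$combo, "+", fixed = TRUE),
      function(x) tok %in% x, logical(1)))
  reports$laterality <- "ipsilateral"
  reports$combo <- NULL

  wcsv <- function(d, f) write.csv(d, file.path(dir, f), row.names = FALSE)
  wcsv(detection, "trials_detection.csv")
  wcsv(jnd_trials, "trials_jnd.csv")
  wcsv(ratings, "ratings.csv")
  wcsv(reports, "reports.csv")
  wcsv(electrodes, "electrodes.csv")
  wcsv(charges, "charges.csv")
  wcsv(lead_tracks, "lead_tracks.csv")
  for (el_id in names(masks_all))
    for (m in masks_all[[el_id]])
      write_mask_png(m, file.path(dir, "masks",
                                  sprintf("%s_w%d_r%d.png", el_id,
                                          m$meta$week, m$meta$repetition)))
  ground_truth <- list(seed = seed,
                       config = unclass(config)[!vapply(unclass(config),
                                                        is.null, logical(1))],
                       electrodes = gt_el)
  jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(detection = detection, jnd = jnd_trials, ratings = ratings,
                 reports = reports, electrodes = electrodes,
                 charges = charges, lead_tracks = lead_tracks,
                 masks = masks_all, template = template,
                 ground_truth = ground_truth))
}

#' Run the full analysis pipeline on a study directory
#'
#' Reads the tables and masks written by [generate_study()] (or arranged in
#' the same layout from real exports) and runs every stage: psychometric
#' detection fits with exclusion and optional pTLR, subject threshold
#' aggregation, JND fits per standard, magnitude preprocessing with intensity
#' model comparison, 3- and 5-bin discriminability, weekly percept stability
#' with pooled medians and AR(1) area trend, modality fractions, sunburst
#' counts, dermatome proportions, weekly charge ANOVA per subject, and lead
#' migration. Writes CSV/JSON artifacts under `dir/outputs` plus a manifest
#' with input hashes.
#'
#' @param dir Study directory.
#' @param n_sim_ptlr Bootstrap simulations per detection fit (0 skips pTLR).
#' @param seed Seed for the bootstrap stage.
#' @return A `study_report` list of stage results.
#' @export
run_study_pipeline <- function(dir, n_sim_ptlr = 0, seed = 1) {
  rd <- function(f) tibble::as_tibble(read.csv(file.path(dir, f)))
  detection <- rd("trials_detection.csv")
  jnd_trials <- rd("trials_jnd.csv")
  ratings <- rd("ratings.csv")
  reports <- rd("reports.csv")
  electrodes <- rd("electrodes.csv")
  charges <- rd("charges.csv")
  lead_tracks <- rd("lead_tracks.csv")
  template <- arm_template()
  set.seed(seed)

  # --- detection thresholds -------------------------------------------------
  fits <- detection |>
    dplyr::group_by(.data$subject, .data$electrode, .data$session) |>
    dplyr::group_map(function(d, key) {
      lv <- aggregate_levels(d)
      included <- exclusion_check(lv) == "include"
      fit <- fit_psychometric(lv)
      if (included && fit$converged && n_sim_ptlr > 0)
        fit <- gof_ptlr(fit, n_sim = n_sim_ptlr)
      tibble::tibble(subject = key$subject, electrode = key$electrode,
                     session = key$session, included = included,
                     alpha = fit$alpha, beta = fit$beta,
                     threshold_mA = fit$threshold75,
                     deviance = fit$deviance,
                     ptlr = if (is.null(fit$ptlr)) NA_real_ else fit$ptlr,
                     converged = fit$converged)
    }) |> dplyr::bind_rows()
  usable <- fits |>
    dplyr::filter(.data$included, .data$converged,
                  is.na(.data$ptlr) | .data$ptlr >= 0.05)
  subject_thresholds <- aggregate_thresholds(usable)

  # --- JND ------------------------------------------------------------------
  jnd_fits <- jnd_trials |>
    dplyr::group_by(.data$subject, .data$electrode,
                    .data$standard_amplitude_mA) |>
    dplyr::group_map(function(d, key) {
      f <- estimate_jnd(d, standard_amplitude_mA = key$standard_amplitude_mA)
      tibble::tibble(subject = key$subject, electrode = key$electrode,
                     standard_amplitude_mA = key$standard_amplitude_mA,
                     jnd_mA = f$jnd_mA, beta = f$beta,
                     converged = f$converged)
    }) |> dplyr::bind_rows()
  jnd_summary <- jnd_fits |>
    dplyr::filter(.data$converged) |>
    dplyr::group_by(.data$subject, .data$standard_amplitude_mA) |>
    dplyr::summarise(mean_jnd_mA = mean(.data$jnd_mA),
                     sd_jnd_mA = sd(.data$jnd_mA),
                     n_electrodes = dplyr::n(), .groups = "drop")

  # --- magnitude estimation -------------------------------------------------
  mag_norm <- ratings |>
    dplyr::group_by(.data$subject, .data$electrode) |>
    dplyr::group_map(function(d, key) {
      out <- preprocess_magnitude(d)
      dplyr::mutate(out, subject = key$subject, electrode = key$electrode)
    }) |> dplyr::bind_rows()
  intensity_fits <- mag_norm |>
    dplyr::group_by(.data$subject, .data$electrode) |>
    dplyr::group_map(function(d, key) {
      f <- fit_intensity_models(d$amplitude_mA, d$rating_norm)
      dplyr::mutate(glance(f), subject = key$subject,
                    electrode = key$electrode, .before = 1)
    }) |> dplyr::bind_rows()
  bins3 <- bin_discriminability(mag_norm, k = 3)
  bins5 <- bin_discriminability(mag_norm, k = 5)

  # --- percept stability ----------------------------------------------------
  mask_files <- list.files(file.path(dir, "masks"), pattern = "\\.png$",
                           full.names = TRUE)
  stability <- NULL; pooled_stability <- NULL; area_trend <- NULL
  if (length(mask_files)) {
    masks <- lapply(mask_files, read_mask_png, template = template)
    by_el <- split(masks, vapply(masks, function(m)
      as.character(m$meta$electrode), character(1)))
    stability <- lapply(by_el, weekly_stability)
    pooled_stability <- pool_stability(stability)
    area_panel <- purrr::imap_dfr(stability, function(s, id)
      dplyr::mutate(tibble::as_tibble(s), electrode = id))
    if (length(unique(area_panel$week)) >= 4) {
      wk_mean <- area_panel |>
        dplyr::group_by(.data$week) |>
        dplyr::summarise(area = mean(.data$area_cm2), .groups = "drop")
      area_trend <- ar1_regression(wk_mean$area, wk_mean$week)
    }
  }

  # --- modality / dermatomes ------------------------------------------------
  modality <- modality_fractions(reports)
  sunburst <- sunburst_counts(reports)
  modality_by_subject <- reports |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_map(function(d, key)
      dplyr::mutate(modality_fractions(d), subject = key$subject,
                    .before = 1)) |>
    dplyr::bind_rows()
  percept_regions <- if (length(mask_files)) {
    masks <- lapply(mask_files, read_mask_png, template = template)
    tibble::tibble(
      electrode = vapply(masks, function(m) as.character(m$meta$electrode),
                         character(1)),
      region = vapply(masks, assign_body_region, character(1))) |>
      dplyr::distinct()
  } else NULL
  dermatomes <- if (!is.null(percept_regions))
    dermatome_proportions(electrodes, percept_regions) else NULL

  # --- charge stability + lead migration ------------------------------------
  charge_anova <- charges |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_map(function(d, key) {
      a <- tryCatch(
        anova_by_week(dplyr::transmute(d, value = .data$charge_nC,
                                       week = .data$week)),
        error = function(e) NULL)
      if (is.null(a))  # too few electrodes per week for an ANOVA
        return(tibble::tibble(subject = key$subject, F = NA_real_,
                              p = NA_real_, n_weeks = NA_integer_))
      tibble::tibble(subject = key$subject, F = a$F, p = a$p,
                     n_weeks = a$n_weeks)
    }) |> dplyr::bind_rows()
  migration <- lead_tracks |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_map(function(d, key) {
      m <- rostrocaudal_migration(d, mm_per_px = 0.1)
      dplyr::mutate(m$per_week, subject = key$subject, .before = 1)
    }) |> dplyr::bind_rows()

  # --- artifacts ------------------------------------------------------------
  out_dir <- file.path(dir, "outputs")
  dir.create(out_dir, showWarnings = FALSE)
  wcsv <- function(d, f) write.csv(d, file.path(out_dir, f), row.names = FALSE)
  wcsv(fits, "detection_fits.csv")
  wcsv(subject_thresholds, "subject_thresholds.csv")
  wcsv(jnd_fits, "jnd_fits.csv")
  wcsv(intensity_fits, "intensity_fits.csv")
  wcsv(bins3$confusion, "confusion_3bin.csv")
  wcsv(bins5$confusion, "confusion_5bin.csv")
  if (!is.null(pooled_stability)) wcsv(pooled_stability, "stability_pooled.csv")
  wcsv(modality_by_subject, "modality_by_subject.csv")
  if (!is.null(dermatomes)) wcsv(dermatomes, "dermatome_proportions.csv")
  wcsv(charge_anova, "charge_anova.csv")
  wcsv(migration, "lead_migration.csv")
  jsonlite::write_json(sunburst, file.path(out_dir, "sunburst_counts.json"),
                       digits = NA)
  inputs <- list.files(dir, pattern = "\\.(csv|json|png)$", recursive = TRUE,
                       full.names = TRUE)
  inputs <- inputs[!startsWith(inputs, out_dir)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("sensorymap")),
    seed = seed, n_sim_ptlr = n_sim_ptlr,
    inputs = as.list(setNames(unname(tools::md5sum(inputs)),
                              basename(inputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(list(
    detection_fits = fits, subject_thresholds = subject_thresholds,
    jnd_fits = jnd_fits, jnd_summary = jnd_summary,
    intensity_fits = intensity_fits, bins3 = bins3, bins5 = bins5,
    stability = stability, pooled_stability = pooled_stability,
    area_trend = area_trend, modality = modality,
    modality_by_subject = modality_by_subject, sunburst = sunburst,
    dermatomes = dermatomes, charge_anova = charge_anova,
    migration = migration, manifest = manifest),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  detection fits: %d (%d usable)\n", nrow(x$detection_fits),
              sum(x$detection_fits$included & x$detection_fits$converged)))
  cat(sprintf("  3-bin accuracy %.1f%%, 5-bin accuracy %.1f%%\n",
              100 * x$bins3$overall_accuracy, 100 * x$bins5$overall_accuracy))
  if (!is.null(x$pooled_stability)) {
    cat("  pooled weekly stability:\n")
    print(x$pooled_stability)
  }
  invisible(x)
}
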