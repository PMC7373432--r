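#' Preprocess a free magnitude-estimation session
#'
#' During the first block the subject establishes their subjective scale while
#' experiencing the full amplitude range, so block-1 trials are dropped. The
#' remaining ratings are normalized to their mean (zeros — "no sensation
#' perceived" — included in the mean), giving each electrode/session a mean
#' response of 1 so data can be compared across electrodes and days.
#'
#' @param session Data frame with `amplitude_mA`, `rating`, and optionally
#'   `block` (ordered block index; block 1 is dropped when present).
#' @return Tibble with `amplitude_mA` and `rating_norm`; attribute `flagged`
#'   is `TRUE` (and all `rating_norm` are `NA`) when every retained rating is
#'   zero, leaving the normalization undefined.
#' @examples
#' preprocess_magnitude(tibble::tibble(block = 2, amplitude_mA = 1:3,
#'                                     rating = c(2, 4, 6)))
#' @export
preprocess_magnitude <- function(session) {
  stopifnot(all(c("amplitude_mA", "rating") %in% names(session)))
  if (any(session$rating < 0, na.rm = TRUE)) abort("ratings must be non-negative.")
  s <- tibble::as_tibble(session)
  if ("block" %in% names(s)) {
    if (length(unique(s$block)) < 2)
      abort("need at least 2 blocks (the first is dropped).")
    s <- dplyr::filter(s, .data$block != min(.data$block))
  }
  m <- mean(s$rating)
  out <- tibble::tibble(amplitude_mA = s$amplitude_mA,
                        rating_norm = if (m > 0) s$rating / m else NA_real_)
  attr(out, "flagged") <- !(m > 0)
  if (!(m > 0)) warn("all ratings are zero; normalization undefined, session flagged.")
  out
}

#' Compare linear, logarithmic and sigmoid intensity models
#'
#' Fits perceived intensity against stimulation amplitude three ways: OLS line
#' (with the two-sided F-test p-value `p_int` for zero slope), logarithmic
#' `y = a + b log(x)`, and a 3-parameter logistic
#' `y = L / (1 + exp(-k (x - x0)))` by nonlinear least squares. Models are
#' compared on adjusted R-squared; the linear model wins ties (it is preferred
#' when "at least as good").
#'
#' @param x Amplitudes (mA), at least 4 distinct values.
#' @param y Normalized ratings.
#' @return An `intensity_fit`: `slope_int` (per mA), `intercept`, `p_int`,
#'   `adj_r2_linear`, `adj_r2_log`, `adj_r2_sigmoid` (`NA` if the logistic
#'   fit fails to converge), and `best_model`.
#' @export
fit_intensity_models <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 4) abort("need >= 4 distinct amplitudes.")
  if (any(x <= 0)) abort("amplitudes must be positive.")
  n <- length(y)

  lin <- lm(y ~ x)
  sl <- summary(lin)
  slope <- unname(coef(lin)[2])
  p_int <- if (sd(y) == 0) 1 else unname(sl$coefficients[2, 4])
  adj_lin <- if (sd(y) == 0) NA_real_ else sl$adj.r.squared

  logm <- lm(y ~ log(x))
  adj_log <- if (sd(y) == 0) NA_real_ else summary(logm)$adj.r.squared

  adj_sig <- NA_real_
  sig <- tryCatch({
    L0 <- max(y); x00 <- stats::weighted.mean(x, w = y + 1e-9)
    k0 <- 4 / max(diff(range(x)), 1e-6)
    minpack.lm::nlsLM(y ~ L / (1 + exp(-k * (x - x0))),
                      start = list(L = max(L0, 1e-6), k = k0, x0 = x00),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  if (!is.null(sig) && sd(y) > 0) {
    rss <- sum(stats::resid(sig)^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    adj_sig <- 1 - (1 - r2) * (n - 1) / (n - 3)
  }

  cand <- c(linear = adj_lin, log = adj_log, sigmoid = adj_sig)
  best <- if (all(is.na(cand))) "linear" else {
    mx <- max(cand, na.rm = TRUE)
    # linear wins ties (within numerical noise)
    if (!is.na(adj_lin) && adj_lin >= mx - 1e-10) "linear"
    else names(cand)[which.max(cand)]
  }

  structure(list(slope_int = slope, intercept = unname(coef(lin)[1]),
                 p_int = p_int, adj_r2_linear = adj_lin, adj_r2_log = adj_log,
                 adj_r2_sigmoid = adj_sig, best_model = best,
                 n = n, linear_fit = lin),
            class = "intensity_fit")
}

#' @export
print.intensity_fit <- function(x, ...) {
  cat(sprintf("<intensity_fit> slope = %.4f per mA (p_int = %.3g), best model: %s\n",
              x$slope_int, x$p_int, x$best_model))
  cat(sprintf("  adj R2 — linear %.3f, log %.3f, sigmoid %s\n",
              x$adj_r2_linear, x$adj_r2_log,
              ifelse(is.na(x$adj_r2_sigmoid), "NA",
                     sprintf("%.3f", x$adj_r2_sigmoid))))
  invisible(x)
}

#' @rdname fit_intensity_models
#' @param x An `intensity_fit`.
#' @param ... Unused.
#' @method tidy intensity_fit
#' @export
tidy.intensity_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope_int),
                 p.value = c(NA_real_, x$p_int))
}

#' @rdname fit_intensity_models
#' @method glance intensity_fit
#' @export
glance.intensity_fit <- function(x, ...) {
  tibble::tibble(slope_int = x$slope_int, p_int = x$p_int,
                 adj_r2_linear = x$adj_r2_linear, adj_r2_log = x$adj_r2_log,
                 adj_r2_sigmoid = x$adj_r2_sigmoid,
                 best_model = x$best_model, n = x$n)
}

# Equal-width bin index on [0, 1]: half-open bins [i/k, (i+1)/k), final bin
# closed so the maximum (1) maps to bin k.
bin_unit <- function(v, k) pmin(floor(v * k) + 1L, k)

#' Binned intensity discriminability (3- or 5-target analysis)
#'
#' Per electrode, stimulation amplitude is normalized to the maximum amplitude
#' tested and the reported intensity to the maximum reported intensity (each
#' over all of that electrode's sessions); both are partitioned into `k`
#' linearly spaced bins. Accuracy is the fraction of trials whose intensity
#' bin matches their amplitude bin, pooled over all trials across electrodes
#' and subjects; per-bin accuracy conditions on the amplitude bin.
#'
#' @param trials Data frame with `electrode`, `amplitude_mA` and a rating
#'   column (`rating_norm` if present, else `rating`).
#' @param k Number of bins (3 or 5 in the standard analysis; any k >= 2).
#' @param per_electrode If `TRUE`, also report per-electrode accuracies.
#' @return A `bin_discrim`: `overall_accuracy`, `per_bin` (tibble:
#'   `amplitude_bin`, `n`, `accuracy`), `confusion` (tibble of counts
#'   `amplitude_bin` x `rating_bin`), `k`, `n_trials`, `skipped_electrodes`.
#' @export
bin_discriminability <- function(trials, k = 3, per_electrode = FALSE) {
  if (k < 2) abort("`k` must be >= 2.")
  stopifnot(all(c("electrode", "amplitude_mA") %in% names(trials)))
  rating_col <- if ("rating_norm" %in% names(trials)) "rating_norm" else "rating"
  if (!rating_col %in% names(trials)) abort("need a `rating` or `rating_norm` column.")
  tr <- tibble::as_tibble(trials)
  tr$.rating <- tr[[rating_col]]
  tr <- tr |>
    dplyr::group_by(.data$electrode) |>
    dplyr::mutate(.max_r = max(.data$.rating),
                  .max_a = max(.data$amplitude_mA)) |>
    dplyr::ungroup()
  skipped <- as.character(unique(tr$electrode[tr$.max_r <= 0 | tr$.max_a <= 0]))
  binned <- tr |>
    dplyr::filter(.data$.max_r > 0, .data$.max_a > 0) |>
    dplyr::mutate(amplitude_bin = bin_unit(.data$amplitude_mA / .data$.max_a, k),
                  rating_bin = bin_unit(.data$.rating / .data$.max_r, k))
  if (length(skipped))
    warn(paste0("electrodes skipped (max rating 0): ",
                paste(skipped, collapse = ", ")))
  if (nrow(binned) == 0) abort("no usable trials after skipping electrodes.")
  overall <- mean(binned$amplitude_bin == binned$rating_bin)
  per_bin <- binned |>
    dplyr::group_by(amplitude_bin = .data$amplitude_bin) |>
    dplyr::summarise(n = dplyr::n(),
                     accuracy = mean(.data$amplitude_bin == .data$rating_bin),
                     .groups = "drop")
  confusion <- binned |>
    dplyr::count(.data$amplitude_bin, .data$rating_bin) |>
    tidyr::complete(amplitude_bin = seq_len(k), rating_bin = seq_len(k),
                    fill = list(n = 0L))
  out <- structure(list(overall_accuracy = overall, per_bin = per_bin,
                        confusion = confusion, k = k, n_trials = nrow(binned),
                        skipped_electrodes = skipped),
                   class = "bin_discrim")
  if (per_electrode) {
    out$per_electrode <- binned |>
      dplyr::group_by(.data$electrode) |>
      dplyr::summarise(accuracy = mean(.data$amplitude_bin == .data$rating_bin),
                       n = dplyr::n(), .groups = "drop")
  }
  out
}

#' @export
print.bin_discrim <- function(x, ...) {
  cat(sprintf("<bin_discrim> k = %d bins, %d trials, overall accuracy %.1f%%\n",
              x$k, x$n_trials, 100 * x$overall_accuracy))
  print(x$per_bin)
  invisible(x)
}

#' @rdname bin_discriminability
#' @param object A `bin_discrim`.
#' @param ... Unused.
#' @method autoplot bin_discrim
#' @export
autoplot.bin_discrim <- function(object, ...) {
  d <- object$confusion |>
    dplyr::group_by(.data$amplitude_bin) |>
    dplyr::mutate(frac = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$amplitude_bin),
                                  y = .data$frac,
                                  fill = factor(.data$rating_bin))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Amplitude bin", y = "Fraction of trials",
                  fill = "Intensity bin") +
    ggplot2::theme_minimal()
}
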