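#' Aggregate 2AFC trials into binomial levels
#'
#' Merges repeated identical amplitudes into one binomial level (amplitude,
#' n_correct, n_total) — the form the psychometric fitter consumes.
#'
#' @param trials Data frame with columns `amplitude_mA` and logical/0-1
#'   `correct`.
#' @return Tibble with `amplitude_mA`, `n_correct`, `n_total`, sorted by
#'   amplitude.
#' @export
aggregate_levels <- function(trials) {
  stopifnot(all(c("amplitude_mA", "correct") %in% names(trials)))
  trials |>
    dplyr::group_by(amplitude_mA = .data$amplitude_mA) |>
    dplyr::summarise(n_correct = sum(as.logical(.data$correct)),
                     n_total = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$amplitude_mA)
}

# Binomial log-likelihood of the cumulative-normal psychometric function
# psi(x) = gamma + (1 - gamma - lam) * pnorm(beta * (x - alpha))
# at levels (x, k, n). Probabilities are clamped away from 0/1 so degenerate
# parameter values yield a finite (very poor) likelihood instead of -Inf.
psycho_loglik <- function(alpha, beta, x, k, n, gamma, lam, eps = 1e-12) {
  p <- gamma + (1 - gamma - lam) * pnorm(beta * (x - alpha))
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(dbinom(k, n, p, log = TRUE))
}

# Saturated (one free probability per level) log-likelihood.
saturated_loglik <- function(k, n) {
  p <- ifelse(n > 0, k / n, 0.5)
  sum(dbinom(k, n, pmin(pmax(p, 1e-12), 1 - 1e-12), log = TRUE))
}

#' Fit a cumulative-normal psychometric function by maximum likelihood
#'
#' Fits \eqn{\Psi(x) = \gamma + (1-\gamma-\lambda)\,\Phi(\beta(x-\alpha))} to
#' binomial 2AFC data with the guess rate and lapse rate held fixed (0.5 and 0
#' by default, the 2AFC convention). Optimization is multi-start quasi-Newton
#' (BFGS) on \eqn{(\alpha, \log\beta)} seeded from a coarse grid, so the
#' likelihood surface's plateaus for near-degenerate data do not trap the fit.
#'
#' @param data Either a tibble of levels (`amplitude_mA`, `n_correct`,
#'   `n_total`) or raw trials (`amplitude_mA`, `correct`), which are
#'   aggregated first.
#' @param gamma Fixed guess rate (default 0.5).
#' @param lam Fixed lapse rate (default 0).
#' @param n_starts Number of grid seeds refined by BFGS.
#' @return A `psychometric_fit`: `alpha` (location, mA), `beta` (slope, per
#'   mA; `1/sigma`), `gamma`, `lam`, `loglik`, `deviance` (twice the
#'   log-likelihood gap to the saturated model), `threshold75` (mA),
#'   `converged`, plus the levels used. Degenerate data (all levels fully
#'   correct or at chance) return `converged = FALSE`.
#' @examples
#' set.seed(1)
#' obs <- observer_params(2, 0.4)
#' x <- seq(1, 3.5, length.out = 6)
#' lv <- tibble::tibble(amplitude_mA = x,
#'                      n_total = 60,
#'                      n_correct = rbinom(6, 60, psi_fun(obs)(x)))
#' fit <- fit_psychometric(lv)
#' fit$alpha
#' @export
fit_psychometric <- function(data, gamma = 0.5, lam = 0, n_starts = 8) {
  lv <- if (all(c("n_correct", "n_total") %in% names(data))) {
    tibble::as_tibble(data)
  } else {
    aggregate_levels(data)
  }
  lv <- lv |> dplyr::filter(.data$n_total > 0) |>
    dplyr::group_by(amplitude_mA = .data$amplitude_mA) |>
    dplyr::summarise(n_correct = sum(.data$n_correct),
                     n_total = sum(.data$n_total), .groups = "drop") |>
    dplyr::arrange(.data$amplitude_mA)
  if (nrow(lv) < 2) abort("need at least 2 stimulus levels to fit.")
  if (any(lv$amplitude_mA <= 0)) abort("amplitudes must be positive.")
  if (any(lv$n_correct > lv$n_total)) abort("n_correct exceeds n_total.")
  x <- lv$amplitude_mA; k <- lv$n_correct; n <- lv$n_total
  acc <- k / n
  degenerate <- all(k == n) || all(k == 0) || length(unique(acc)) == 1

  rng <- range(x); span <- max(diff(rng), min(x) * 0.1, 1e-6)
  alpha_grid <- seq(rng[1] - 0.5 * span, rng[2] + 0.5 * span, length.out = 15)
  logbeta_grid <- log(1 / (span * c(2, 1, 0.5, 0.2, 0.1, 0.05, 0.02)))
  grid <- expand.grid(alpha = alpha_grid, logbeta = logbeta_grid)
  grid$ll <- mapply(function(a, lb)
    psycho_loglik(a, exp(lb), x, k, n, gamma, lam), grid$alpha, grid$logbeta)
  seeds <- grid[order(-grid$ll), ][seq_len(min(n_starts, nrow(grid))), ]

  nll <- function(par) -psycho_loglik(par[1], exp(par[2]), x, k, n, gamma, lam)
  best <- NULL
  ok <- FALSE
  for (i in seq_len(nrow(seeds))) {
    o <- tryCatch(
      optim(c(seeds$alpha[i], seeds$logbeta[i]), nll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value - 1e-12) best <- o
    if (o$convergence == 0) ok <- TRUE
  }
  if (is.null(best)) {
    i <- which.max(grid$ll)
    best <- list(par = c(grid$alpha[i], grid$logbeta[i]), value = -grid$ll[i],
                 convergence = 1L)
  }
  alpha <- best$par[1]; beta <- exp(best$par[2])
  ll <- -best$value
  dev <- 2 * (saturated_loglik(k, n) - ll)
  fit <- structure(
    list(alpha = alpha, beta = beta, gamma = gamma, lam = lam,
         loglik = ll, deviance = max(dev, 0),
         threshold75 = NA_real_,
         converged = ok && !degenerate, degenerate = degenerate,
         levels = lv),
    class = "psychometric_fit")
  fit$threshold75 <- tryCatch(threshold_at(fit, 0.75), error = function(e) NA_real_)
  fit
}

#' Stimulus amplitude at a given accuracy level
#'
#' Inverts the fitted psychometric function: returns the amplitude `x` with
#' \eqn{\Psi(x) = p}. At `p = 0.75` with `gamma = 0.5`, `lam = 0` this is
#' exactly the fitted location `alpha` — the detection threshold (or JND)
#' convention.
#'
#' @param fit A `psychometric_fit`.
#' @param p Target accuracy; must satisfy `gamma < p < 1 - lam`.
#' @return Amplitude (mA).
#' @export
threshold_at <- function(fit, p = 0.75) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (p <= fit$gamma || p >= 1 - fit$lam)
    abort(sprintf("p = %g is unattainable: need gamma (%g) < p < 1 - lam (%g).",
                  p, fit$gamma, 1 - fit$lam))
  q <- (p - fit$gamma) / (1 - fit$gamma - fit$lam)
  fit$alpha + qnorm(q) / fit$beta
}

#' Accuracy-band exclusion rule for a psychometric task
#'
#' Tasks whose per-level accuracies all sit below 0.6 (never rises out of the
#' chance region) or all above 0.9 (never falls into the transition region)
#' carry no information about the threshold and are excluded.
#'
#' @param data Levels or raw trials as in [fit_psychometric()].
#' @param lower,upper Band edges (defaults 0.6 and 0.9).
#' @return `"include"` or `"exclude"`.
#' @export
exclusion_check <- function(data, lower = 0.6, upper = 0.9) {
  lv <- if (all(c("n_correct", "n_total") %in% names(data)))
    tibble::as_tibble(data) else aggregate_levels(data)
  acc <- lv$n_correct / lv$n_total
  if (max(acc) < lower || min(acc) > upper) "exclude" else "include"
}

#' Estimate a just-noticeable difference from 2AFC comparison trials
#'
#' Comparison trials present a standard amplitude and a test amplitude;
#' `correct` codes whether the subject chose the truly-higher-amplitude
#' window. Trials are pooled over whether the test fell above or below the
#' standard by fitting over the absolute difference |test - standard|; the JND
#' is the |difference| at which the fitted function reaches 75% accuracy.
#'
#' @param trials Data frame with `test_amplitude_mA` (or precomputed
#'   `delta_mA`) and `correct`.
#' @param standard_amplitude_mA The fixed standard amplitude (mA); required
#'   unless `delta_mA` is supplied.
#' @param ... Passed to [fit_psychometric()].
#' @return A `psychometric_fit` with extra fields `jnd_mA` and
#'   `standard_amplitude_mA`.
#' @export
estimate_jnd <- function(trials, standard_amplitude_mA = NULL, ...) {
  if (!"delta_mA" %in% names(trials)) {
    if (is.null(standard_amplitude_mA))
      abort("supply `standard_amplitude_mA` or a `delta_mA` column.")
    trials$delta_mA <- abs(trials$test_amplitude_mA - standard_amplitude_mA)
  }
  lv <- trials |>
    dplyr::filter(.data$delta_mA > 0) |>
    dplyr::transmute(amplitude_mA = .data$delta_mA, correct = .data$correct)
  fit <- fit_psychometric(lv, ...)
  fit$jnd_mA <- fit$threshold75
  fit$standard_amplitude_mA <- standard_amplitude_mA
  fit
}

#' Parametric-bootstrap goodness of fit (pTLR)
#'
#' Simulates `n_sim` datasets from the fitted psychometric function at the
#' observed levels and trial counts, refits each, and compares deviances
#' (transformed likelihood ratios against the saturated model). The returned
#' pTLR is the proportion of simulated deviances at least as large as the
#' observed one — equivalently, the proportion of simulated likelihood ratios
#' smaller than the data's. It spans 0–1 with higher values signifying a
#' better fit; fits with pTLR < 0.05 are conventionally discarded.
#'
#' @param fit A converged `psychometric_fit`.
#' @param n_sim Number of bootstrap datasets (default 1000).
#' @return The fit with fields `ptlr`, `ptlr_n_sim`, `ptlr_failures` added
#'   (and `ptlr_flagged` if more than 10% of refits failed).
#' @export
gof_ptlr <- function(fit, n_sim = 1000) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!fit$converged)
    abort("goodness of fit requires a converged psychometric fit.")
  lv <- fit$levels
  x <- lv$amplitude_mA; n <- lv$n_total
  p_fit <- fit$gamma + (1 - fit$gamma - fit$lam) * pnorm(fit$beta * (x - fit$alpha))
  devs <- rep(NA_real_, n_sim)
  for (s in seq_len(n_sim)) {
    k_s <- rbinom(length(x), n, p_fit)
    devs[s] <- tryCatch(
      refit_deviance(x, k_s, n, fit),
      error = function(e) NA_real_)
  }
  fail <- sum(is.na(devs))
  ok <- devs[!is.na(devs)]
  fit$ptlr <- mean(ok >= fit$deviance - 1e-9)
  fit$ptlr_n_sim <- n_sim
  fit$ptlr_failures <- fail
  fit$ptlr_flagged <- fail > 0.1 * n_sim
  fit
}

# Fast single-dataset refit for the bootstrap: warm-started at the
# data-generating parameters with a small fallback grid.
refit_deviance <- function(x, k, n, fit) {
  nll <- function(par) -psycho_loglik(par[1], exp(par[2]), x, k, n,
                                      fit$gamma, fit$lam)
  starts <- rbind(c(fit$alpha, log(fit$beta)),
                  c(fit$alpha, log(fit$beta) + 1),
                  c(fit$alpha, log(fit$beta) - 1))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(optim(starts[i, ], nll, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-10)),
                  error = function(e) NULL)
    if (!is.null(o) && o$value < best) best <- o$value
  }
  if (!is.finite(best)) stop("refit failed")
  max(2 * (saturated_loglik(k, n) - (-best)), 0)
}

#' Aggregate per-electrode thresholds to subject summaries
#'
#' Thresholds measured for the same electrode on different days are averaged
#' first; the subject summary is then the arithmetic mean and sample SD over
#' its electrodes.
#'
#' @param thresholds Data frame with `subject`, `electrode`, `threshold_mA`
#'   and optionally `day` (any repeated electrode rows are day-averaged).
#' @return Tibble: `subject`, `mean_threshold_mA`, `sd_threshold_mA`,
#'   `n_electrodes`.
#' @export
aggregate_thresholds <- function(thresholds) {
  stopifnot(all(c("subject", "electrode", "threshold_mA") %in% names(thresholds)))
  thresholds |>
    dplyr::filter(!is.na(.data$threshold_mA)) |>
    dplyr::group_by(.data$subject, .data$electrode) |>
    dplyr::summarise(threshold_mA = mean(.data$threshold_mA), .groups = "drop") |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(mean_threshold_mA = mean(.data$threshold_mA),
                     sd_threshold_mA = sd(.data$threshold_mA),
                     n_electrodes = dplyr::n(), .groups = "drop")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> alpha = %.4f mA, beta = %.4f /mA (sigma = %.4f mA)\n",
    x$alpha, x$beta, 1 / x$beta))
  cat(sprintf("  gamma = %g, lapse = %g fixed; threshold(75%%) = %.4f mA\n",
              x$gamma, x$lam, x$threshold75))
  cat(sprintf("  loglik = %.3f, deviance = %.3f%s, converged: %s\n",
              x$loglik, x$deviance,
              if (!is.null(x$ptlr)) sprintf(", pTLR = %.3f", x$ptlr) else "",
              x$converged))
  invisible(x)
}

#' @rdname fit_psychometric
#' @param x A `psychometric_fit`.
#' @param ... Unused.
#' @method tidy psychometric_fit
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "beta"),
                 estimate = c(x$alpha, x$beta),
                 unit = c("mA", "per mA"))
}

#' @rdname fit_psychometric
#' @method glance psychometric_fit
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, beta = x$beta, sigma = 1 / x$beta,
                 threshold75_mA = x$threshold75,
                 loglik = x$loglik, deviance = x$deviance,
                 ptlr = if (is.null(x$ptlr)) NA_real_ else x$ptlr,
                 converged = x$converged)
}

#' @rdname fit_psychometric
#' @param object A `psychometric_fit`.
#' @method autoplot psychometric_fit
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  lv <- object$levels |>
    dplyr::mutate(accuracy = .data$n_correct / .data$n_total)
  xs <- seq(min(lv$amplitude_mA) * 0.8, max(lv$amplitude_mA) * 1.1,
            length.out = 200)
  curve <- tibble::tibble(
    amplitude_mA = xs,
    accuracy = object$gamma +
      (1 - object$gamma - object$lam) * pnorm(object$beta * (xs - object$alpha)))
  ggplot2::ggplot(lv, ggplot2::aes(x = .data$amplitude_mA, y = .data$accuracy)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_total), alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0.75, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = object$threshold75, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "Amplitude (mA)", y = "Proportion correct",
                  size = "Trials") +
    ggplot2::theme_minimal()
}
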