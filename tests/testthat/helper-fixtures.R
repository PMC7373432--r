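# Shared fixture builders. Everything is generated in code; no stored data.

# Minimal hand-built template: a w x h raster fully labeled as palm, with
# explicit calibration constants, for tests that need exact px-to-physical
# arithmetic.
flat_template <- function(w = 20, h = 20, mm_per_px = 1, cm2_per_px = 0.25) {
  structure(list(
    labels = matrix(4L, nrow = h, ncol = w),
    regions = arm_regions,
    mm_per_px = mm_per_px, cm2_per_px = cm2_per_px,
    hand_length_mm = 189, palm_area_cm2 = 75,
    landmarks = list(), template_id = sprintf("flat-%dx%d", w, h)),
    class = "percept_template")
}

# Mask from explicit pixel (row, col) indices on a template.
mask_from_pixels <- function(template, rows, cols, ...) {
  px <- matrix(FALSE, nrow(template$labels), ncol(template$labels))
  px[cbind(rows, cols)] <- TRUE
  percept_mask(template, px, ...)
}

# Binomial levels simulated from a known observer.
simulate_levels <- function(obs, amplitudes, n_per_level) {
  tibble::tibble(
    amplitude_mA = amplitudes,
    n_total = n_per_level,
    n_correct = rbinom(length(amplitudes), n_per_level,
                       psi_fun(obs)(amplitudes)))
}

# Independent brute-force grid search over (alpha, beta) for the binomial
# cumulative-normal likelihood; the oracle for the MLE fitter.
grid_oracle_loglik <- function(levels, gamma = 0.5, lam = 0,
                               n_grid = 201) {
  x <- levels$amplitude_mA; k <- levels$n_correct; n <- levels$n_total
  alphas <- seq(min(x) - diff(range(x)), max(x) + diff(range(x)),
                length.out = n_grid)
  betas <- exp(seq(log(0.05 / diff(range(x))), log(50 / diff(range(x))),
                   length.out = n_grid))
  best <- -Inf
  for (a in alphas) {
    p <- outer(x - a, betas)            # (x - a) * beta
    psi <- gamma + (1 - gamma - lam) * pnorm(p)
    psi <- pmin(pmax(psi, 1e-12), 1 - 1e-12)
    ll <- colSums(dbinom(k, n, psi, log = TRUE))
    best <- max(best, max(ll))
  }
  best
}

# By-hand one-way ANOVA F from explicit sums of squares.
anova_oracle_F <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all_v) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}
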