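#' Threshold charge from first-phase amplitude and pulse width
#'
#' Charge delivered by the first stimulation phase: amplitude (mA) times
#' pulse width (us) gives nanocoulombs directly (1 mA x 1 us = 1 nC).
#'
#' @param amplitude_mA First-phase amplitude (mA), positive.
#' @param pulse_width_us First-phase pulse width (us), positive.
#' @return Charge (nC).
#' @examples
#' threshold_charge(2, 200) # 400
#' @export
threshold_charge <- function(amplitude_mA, pulse_width_us) {
  if (any(amplitude_mA <= 0) || any(pulse_width_us <= 0))
    abort("amplitude and pulse width must be positive.")
  amplitude_mA * pulse_width_us
}

#' One-way ANOVA of threshold charge across weeks, with Tukey HSD
#'
#' Classical one-way ANOVA testing for week-to-week differences in per-
#' electrode threshold charge, followed by Tukey HSD adjusted pairwise
#' comparisons on all week pairs (Tukey–Kramer for unbalanced weeks). Weeks
#' with fewer than two values are dropped with a warning.
#'
#' @param values Data frame with `value` (e.g. charge, nC) and `week`.
#' @return A `week_anova`: `F`, `p`, `df` (num, den), `tukey` (tibble:
#'   `week_a`, `week_b`, `diff`, `p_adj`), `n_weeks`, `dropped_weeks`.
#' @export
anova_by_week <- function(values) {
  stopifnot(all(c("value", "week") %in% names(values)))
  counts <- table(values$week)
  dropped <- names(counts)[counts < 2]
  if (length(dropped))
    warn(paste0("weeks with < 2 values dropped: ",
                paste(dropped, collapse = ", ")))
  v <- values[!as.character(values$week) %in% dropped, , drop = FALSE]
  if (length(unique(v$week)) < 2)
    abort("need at least 2 weeks with >= 2 values each.")
  v$week_f <- factor(v$week)
  fit <- aov(value ~ week_f, data = v)
  an <- anova(fit)
  tk <- TukeyHSD(fit)$week_f
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey <- tibble::tibble(
    week_a = vapply(pairs, `[`, character(1), 2),
    week_b = vapply(pairs, `[`, character(1), 1),
    diff = unname(tk[, "diff"]),
    p_adj = unname(tk[, "p adj"]))
  structure(list(F = an$`F value`[1], p = an$`Pr(>F)`[1],
                 df = unname(an$Df), tukey = tukey,
                 n_weeks = length(unique(v$week)), dropped_weeks = dropped),
            class = "week_anova")
}

#' @export
print.week_anova <- function(x, ...) {
  cat(sprintf("<week_anova> F(%d, %d) = %.3f, p = %.4g over %d weeks\n",
              x$df[1], x$df[2], x$F, x$p, x$n_weeks))
  invisible(x)
}

#' Linear trend regression with AR(1) errors
#'
#' Regression of a time-ordered response on the week index allowing first-
#' order autocorrelated errors, for trend inference when serial correlation
#' would bias OLS standard errors. Estimation is iterated feasible GLS
#' (Prais–Winsten): the error autocorrelation rho is re-estimated from lag-1
#' residual products and the quasi-differenced regression is refit until rho
#' converges; the first observation is retained with its stationary
#' weighting. A Durbin–Watson statistic on the OLS residuals is reported as
#' the first-order autocorrelation diagnostic.
#'
#' @param y Time-ordered response values.
#' @param t Time index (week); defaults to `seq_along(y)`.
#' @param max_iter,tol Iteration control for the rho update.
#' @return An `ar1_fit`: `beta_t` (trend per unit `t`), `intercept`, `rho`,
#'   `p` (two-sided trend p-value from the transformed regression),
#'   `se_beta`, `dw` (Durbin–Watson), `nonstationary` flag, `n`,
#'   `iterations`.
#' @export
ar1_regression <- function(y, t = seq_along(y), max_iter = 50, tol = 1e-8) {
  stopifnot(length(y) == length(t))
  keep <- is.finite(y) & is.finite(t)
  y <- y[keep]; t <- t[keep]
  n <- length(y)
  if (n < 4) abort("need at least 4 time points.")
  ord <- order(t); y <- y[ord]; t <- t[ord]

  ols <- lm(y ~ t)
  e <- stats::resid(ols)
  dw <- sum(diff(e)^2) / sum(e^2)
  rho <- 0
  beta <- coef(ols)
  fit_tr <- ols
  for (it in seq_len(max_iter)) {
    denom <- sum(e[-n]^2)
    rho_new <- if (denom > 0) sum(e[-1] * e[-n]) / denom else 0
    rho_new <- max(min(rho_new, 0.999), -0.999)
    if (abs(rho_new - rho) < tol) { rho <- rho_new; break }
    rho <- rho_new
    # Prais–Winsten transform: quasi-difference, keep first obs weighted
    w1 <- sqrt(1 - rho^2)
    ys <- c(w1 * y[1], y[-1] - rho * y[-n])
    i_s <- c(w1, rep(1 - rho, n - 1))
    ts <- c(w1 * t[1], t[-1] - rho * t[-n])
    fit_tr <- lm(ys ~ 0 + i_s + ts)
    beta <- coef(fit_tr)
    # residuals on the original scale for the next rho update
    e <- y - (beta["i_s"] + beta["ts"] * t)
  }
  if (it == 1) { # rho stayed 0: plain OLS inference
    s <- summary(ols)
    beta_t <- unname(coef(ols)[2]); se <- s$coefficients[2, 2]
    p <- s$coefficients[2, 4]
    icpt <- unname(coef(ols)[1])
  } else {
    s <- summary(fit_tr)
    beta_t <- unname(beta["ts"]); se <- s$coefficients["ts", 2]
    p <- s$coefficients["ts", 4]
    icpt <- unname(beta["i_s"])
  }
  structure(list(beta_t = beta_t, intercept = icpt, rho = rho, p = p,
                 se_beta = se, dw = dw,
                 nonstationary = abs(rho) >= 0.999, n = n, iterations = it),
            class = "ar1_fit")
}

#' @export
print.ar1_fit <- function(x, ...) {
  cat(sprintf("<ar1_fit> trend beta = %.4f (p = %.3g), rho = %.3f, DW = %.2f, n = %d\n",
              x$beta_t, x$p, x$rho, x$dw, x$n))
  if (x$nonstationary) cat("  warning: |rho| at bound, flagged non-stationary\n")
  invisible(x)
}

#' @rdname ar1_regression
#' @param x An `ar1_fit`.
#' @param ... Unused.
#' @method tidy ar1_fit
#' @export
tidy.ar1_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "trend", "rho"),
                 estimate = c(x$intercept, x$beta_t, x$rho),
                 std.error = c(NA, x$se_beta, NA),
                 p.value = c(NA, x$p, NA))
}

#' @rdname ar1_regression
#' @method glance ar1_fit
#' @export
glance.ar1_fit <- function(x, ...) {
  tibble::tibble(beta_t = x$beta_t, rho = x$rho, p = x$p, dw = x$dw,
                 n = x$n, nonstationary = x$nonstationary)
}

#' Least-squares 2D affine transform from landmark pairs
#'
#' Estimates the affine map minimizing the summed squared target residuals
#' over at least three non-collinear landmark pairs — the arithmetic used to
#' align each week's X-ray to the previous week's before measuring lead
#' displacement.
#'
#' @param source,target Numeric n x 2 matrices of corresponding points (px).
#' @return An `affine2d`: `A` (2 x 2 matrix), `b` (length-2 translation),
#'   `rms` residual, and `transform(points)` applying the map.
#' @export
affine_from_landmarks <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) < 3 || !identical(dim(source), dim(target)) ||
      ncol(source) != 2)
    abort("need matching n x 2 matrices with n >= 3.")
  X <- cbind(source, 1)
  if (qr(X)$rank < 3)
    abort("landmarks are collinear; affine transform is rank-deficient.")
  coefs <- qr.solve(X, target)            # 3 x 2: [A' ; b']
  A <- t(coefs[1:2, , drop = FALSE])
  b <- as.numeric(coefs[3, ])
  pred <- X %*% coefs
  rms <- sqrt(mean(rowSums((target - pred)^2)))
  structure(list(A = A, b = b, rms = rms,
                 transform = function(p) {
                   p <- matrix(as.numeric(p), ncol = 2)
                   t(A %*% t(p) + b)
                 }),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("<affine2d>\n  A =\n")
  print(round(x$A, 6))
  cat(sprintf("  b = (%.4f, %.4f), residual RMS = %.4g px\n",
              x$b[1], x$b[2], x$rms))
  invisible(x)
}

#' Image scale from an SCS contact
#'
#' SCS contacts are 3 mm long; the contact most parallel to the imaging plane
#' sets the image scale.
#'
#' @param p1,p2 Length-2 pixel coordinates of the contact's endpoints.
#' @param contact_length_mm Physical contact length (default 3 mm).
#' @return Scale in mm per pixel.
#' @export
contact_scale <- function(p1, p2, contact_length_mm = 3) {
  d <- sqrt(sum((as.numeric(p1) - as.numeric(p2))^2))
  if (d == 0) abort("contact endpoints coincide; no scale defined.")
  contact_length_mm / d
}

#' Rostro-caudal lead migration from weekly tip coordinates
#'
#' Projects the week-over-week displacement of each lead's rostral tip onto
#' the rostro-caudal axis and converts to mm. Positive values signify caudal
#' migration, negative rostral. Per-week medians across leads summarize each
#' subject.
#'
#' @param track Data frame: `lead`, `week`, `tip_x_px`, `tip_y_px`.
#' @param mm_per_px Image scale (e.g. from [contact_scale()]).
#' @param axis Unit direction of increasing caudal position in pixel
#'   coordinates (default `(0, 1)`: down-image is caudal).
#' @return List with `per_lead` (tibble: `lead`, `week`,
#'   `migration_mm`, `NA` across gaps) and `per_week` (tibble: `week`,
#'   `median_migration_mm`, `n_leads`).
#' @export
rostrocaudal_migration <- function(track, mm_per_px, axis = c(0, 1)) {
  stopifnot(all(c("lead", "week", "tip_x_px", "tip_y_px") %in% names(track)))
  if (mm_per_px <= 0) abort("`mm_per_px` must be positive.")
  axis <- axis / sqrt(sum(axis^2))
  per_lead <- track |>
    dplyr::arrange(.data$lead, .data$week) |>
    dplyr::group_by(.data$lead) |>
    dplyr::mutate(
      migration_mm = (axis[1] * (.data$tip_x_px - dplyr::lag(.data$tip_x_px)) +
                      axis[2] * (.data$tip_y_px - dplyr::lag(.data$tip_y_px))) *
        mm_per_px,
      migration_mm = ifelse(.data$week - dplyr::lag(.data$week) == 1,
                            .data$migration_mm, NA_real_)) |>
    dplyr::ungroup() |>
    dplyr::select("lead", "week", "migration_mm")
  per_week <- per_lead |>
    dplyr::filter(!is.na(.data$migration_mm)) |>
    dplyr::group_by(week = .data$week) |>
    dplyr::summarise(median_migration_mm = median(.data$migration_mm),
                     n_leads = dplyr::n(), .groups = "drop")
  list(per_lead = per_lead, per_week = per_week)
}
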