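test_that("threshold charge is the first-phase amplitude-width product", {
  expect_equal(threshold_charge(2.0, 200), 400)
  expect_equal(threshold_charge(1.0, 1), 1)
  expect_equal(threshold_charge(2 * 1.3, 150), 2 * threshold_charge(1.3, 150))
  expect_error(threshold_charge(0, 100), "positive")
})

test_that("one-way ANOVA matches the by-hand sum-of-squares oracle", {
  groups <- list(c(1, 2, 3), c(2, 3, 4), c(7, 8, 9))
  d <- tibble::tibble(value = unlist(groups),
                      week = rep(1:3, times = lengths(groups)))
  out <- anova_by_week(d)
  expect_equal(out$F, anova_oracle_F(groups), tolerance = 1e-9)
  # unbalanced groups against the same oracle
  g2 <- list(rnorm(4, 1), rnorm(7, 1.5), rnorm(3, 0.5), rnorm(5, 1))
  d2 <- tibble::tibble(value = unlist(g2),
                       week = rep(1:4, times = lengths(g2)))
  expect_equal(anova_by_week(d2)$F, anova_oracle_F(g2), tolerance = 1e-9)
  # identical group distributions: F = 0
  d0 <- tibble::tibble(value = rep(c(1, 2, 3), 2), week = rep(1:2, each = 3))
  expect_equal(anova_by_week(d0)$F, 0)
})

test_that("Tukey HSD adjusted p-values are reported for all week pairs", {
  set.seed(71)
  d <- tibble::tibble(value = c(rnorm(6, 0), rnorm(6, 0.2), rnorm(6, 3)),
                      week = rep(1:3, each = 6))
  out <- anova_by_week(d)
  expect_equal(nrow(out$tukey), 3)
  expect_true(all(out$tukey$p_adj >= 0 & out$tukey$p_adj <= 1))
  # the separated week stands out
  p13 <- out$tukey$p_adj[out$tukey$week_a == "1" & out$tukey$week_b == "3"]
  expect_lt(p13, 0.01)
  # weeks with < 2 values are dropped with a warning
  d2 <- dplyr::bind_rows(d, tibble::tibble(value = 1, week = 9))
  expect_warning(out2 <- anova_by_week(d2), "dropped")
  expect_equal(out2$n_weeks, 3)
})

test_that("ANOVA type-I error is calibrated at the nominal level", {
  set.seed(72)
  rej <- replicate(2000, {
    d <- tibble::tibble(value = rnorm(15), week = rep(1:3, each = 5))
    anova_by_week(d)$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.015)
})

test_that("AR(1) regression reduces to OLS when residuals carry no lag-1 structure", {
  # construct residuals orthogonal to (1, t) with exactly zero lag-1
  # autocorrelation: mix two detrended noise vectors, solving the quadratic
  # lagprod(r0 + theta * z) = 0 for theta
  set.seed(70)
  t <- 1:20; n <- 20
  r0 <- resid(lm(rnorm(n) ~ t))
  z <- resid(lm(rnorm(n) ~ t))
  lagprod <- function(v) sum(v[-1] * v[-n])
  A <- lagprod(z); B <- sum(r0[-1] * z[-n]) + sum(z[-1] * r0[-n])
  C <- lagprod(r0)
  theta <- (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)
  e <- r0 + theta * z
  expect_equal(lagprod(e), 0, tolerance = 1e-10)
  y <- 2 + 0.5 * t + e
  f <- ar1_regression(y, t)
  ols <- unname(coef(lm(y ~ t))[2])
  expect_equal(f$beta_t, ols, tolerance = 1e-6)
  expect_equal(f$rho, 0, tolerance = 1e-6)
  # exact line: slope exact, p ~ 0
  f2 <- ar1_regression(1 - 0.2 * (1:10), 1:10)
  expect_equal(f2$beta_t, -0.2, tolerance = 1e-9)
  expect_lt(f2$p, 1e-9)
  expect_error(ar1_regression(1:3, 1:3), "4 time points")
})

test_that("AR(1) regression recovers trend and autocorrelation", {
  set.seed(73)
  n <- 200
  betas <- numeric(50); rhos <- numeric(50)
  for (i in 1:50) {
    e <- as.numeric(stats::arima.sim(list(ar = 0.5), n, sd = 0.5))
    y <- -0.2 * (1:n) + e
    f <- ar1_regression(y, 1:n)
    betas[i] <- f$beta_t; rhos[i] <- f$rho
  }
  expect_lt(abs(median(betas) + 0.2), 0.03)
  expect_lt(abs(median(rhos) - 0.5), 0.1)
})

test_that("AR(1) trend inference agrees with an independent GLS fit", {
  skip_if_not_installed("nlme")
  set.seed(74)
  n <- 120
  e <- as.numeric(stats::arima.sim(list(ar = 0.6), n, sd = 1))
  y <- 3 - 0.15 * (1:n) + e
  f <- ar1_regression(y, 1:n)
  g <- nlme::gls(y ~ t, data = data.frame(y = y, t = 1:n),
                 correlation = nlme::corAR1(form = ~t), method = "ML")
  expect_equal(f$beta_t, unname(coef(g)[2]), tolerance = 0.02)
  expect_equal(f$rho, coef(g$modelStruct$corStruct, unconstrained = FALSE),
               tolerance = 0.1, ignore_attr = TRUE)
})

test_that("landmark affine estimation is exact on noise-free data", {
  # identity
  p <- matrix(c(0, 0, 10, 0, 0, 10, 7, 3), ncol = 2, byrow = TRUE)
  f_id <- affine_from_landmarks(p, p)
  expect_equal(f_id$A, diag(2), tolerance = 1e-10)
  expect_equal(f_id$b, c(0, 0), tolerance = 1e-10)
  expect_equal(f_id$rms, 0, tolerance = 1e-10)
  # pure translation
  f_tr <- affine_from_landmarks(p, p + matrix(rep(c(3, -2), each = 4), ncol = 2))
  expect_equal(f_tr$A, diag(2), tolerance = 1e-10)
  expect_equal(f_tr$b, c(3, -2), tolerance = 1e-10)
  # random affine on 6 points, checked against a normal-equations oracle
  set.seed(75)
  A <- matrix(rnorm(4, sd = 0.5), 2, 2) + diag(2)
  b <- rnorm(2)
  src <- matrix(runif(12, 0, 100), ncol = 2)
  dst <- t(A %*% t(src) + b)
  f <- affine_from_landmarks(src, dst)
  expect_equal(f$A, A, tolerance = 1e-9)
  expect_equal(f$b, b, tolerance = 1e-9)
  X <- cbind(src, 1)
  oracle <- solve(t(X) %*% X, t(X) %*% dst)   # normal equations
  expect_equal(rbind(t(f$A), f$b), oracle, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(f$transform(src), dst, tolerance = 1e-8, ignore_attr = TRUE)
  # collinear landmarks are rejected
  col_p <- cbind(1:4, 2 * (1:4))
  expect_error(affine_from_landmarks(col_p, col_p), "collinear")
})

test_that("contact scale is 3 mm over the pixel distance", {
  expect_equal(contact_scale(c(0, 0), c(30, 0)), 0.1)
  expect_equal(contact_scale(c(0, 0), c(0, 3)), 1.0)
  expect_equal(contact_scale(c(0, 0), c(60, 0)),
               contact_scale(c(0, 0), c(30, 0)) / 2)
  expect_error(contact_scale(c(1, 1), c(1, 1)), "coincide")
})

test_that("rostro-caudal migration projects, scales, and summarizes", {
  tr <- tibble::tibble(lead = 1, week = 1:2, tip_x_px = 0,
                       tip_y_px = c(100, 150))
  out <- rostrocaudal_migration(tr, mm_per_px = 0.1)
  expect_equal(out$per_lead$migration_mm, c(NA, 5))
  # no movement
  tr0 <- tibble::tibble(lead = 1, week = 1:3, tip_x_px = 5, tip_y_px = 7)
  expect_equal(rostrocaudal_migration(tr0, 0.1)$per_week$median_migration_mm,
               c(0, 0))
  # three leads with displacements {2, -1, 4} mm -> median 2
  tr3 <- tibble::tibble(lead = rep(1:3, each = 2), week = rep(1:2, 3),
                        tip_x_px = 0,
                        tip_y_px = c(0, 20, 0, -10, 0, 40))
  out3 <- rostrocaudal_migration(tr3, 0.1)
  expect_equal(out3$per_week$median_migration_mm, 2)
  # gaps in weeks yield NA, not a spurious two-week displacement
  trg <- tibble::tibble(lead = 1, week = c(1, 3), tip_x_px = 0,
                        tip_y_px = c(0, 10))
  expect_true(all(is.na(rostrocaudal_migration(trg, 0.1)$per_lead$migration_mm[-1])))
})
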