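test_that("the reaction norm evaluates to its closed-form values", {
  p <- rn_params(z = 18, w = 20, a = 0.2, b = 0.1)
  expect_equal(eval_reaction_norm(p, 28), 0)
  expect_equal(eval_reaction_norm(p, 8), 0)
  expect_equal(eval_reaction_norm(p, 18), 0.2 * exp(1.8))
  expect_error(rn_params(z = 18, w = -2, a = 0.2, b = 0.1),
               class = "thermnorm_invalid_params")
  expect_error(rn_params(z = 18, w = 20, a = 0, b = 0.1),
               class = "thermnorm_invalid_params")
})

test_that("T_opt solves the stationarity quadratic and sits above z for b > 0", {
  # hand-set example: u* is the positive root of 0.1 u^2 + 0.2 u - 0.1 = 0
  p <- rn_params(z = 18, w = 20, a = 0.2, b = 0.1)
  u_star <- (-0.2 + sqrt(0.04 + 0.04)) / 0.2
  expect_equal(derive_topt(p), 18 + 10 * u_star, tolerance = 1e-6)
  expect_equal(derive_topt(p), grid_topt(p), tolerance = 1e-4)

  # symmetric limit: no skew puts the optimum at the niche midpoint
  expect_equal(derive_topt(rn_params(18, 20, 0.2, 0)), 18, tolerance = 1e-8)

  ps <- random_params(100, seed = 301)
  for (i in seq_len(nrow(ps))) {
    p <- rn_params(ps$z[i], ps$w[i], ps$a[i], ps$b[i])
    t_opt <- derive_topt(p)
    expect_equal(t_opt, quadratic_topt(p), tolerance = 1e-4)
    if (p$b > 1e-6) expect_gt(t_opt, p$z)
    if (p$b < -1e-6) expect_lt(t_opt, p$z)
  }
})

test_that("T_max equals the analytic upper zero z + w/2", {
  expect_equal(derive_tmax(rn_params(18, 20, 0.2, 0.1)), 28, tolerance = 1e-6)
  expect_equal(derive_tmax(rn_params(21, 14, 0.3, 0.05)), 28, tolerance = 1e-6)
  ps <- random_params(100, seed = 302)
  for (i in seq_len(nrow(ps))) {
    p <- rn_params(ps$z[i], ps$w[i], ps$a[i], ps$b[i])
    expect_equal(derive_tmax(p), p$z + p$w / 2, tolerance = 1e-6)
  }
})

test_that("the curve is left-skewed around T_opt when b > 0", {
  ps <- random_params(50, seed = 303)
  ps <- ps[ps$b > 0.01, ]
  for (i in seq_len(nrow(ps))) {
    p <- rn_params(ps$z[i], ps$w[i], ps$a[i], ps$b[i])
    t_opt <- derive_topt(p)
    dmax <- min(t_opt - (p$z - p$w / 2), (p$z + p$w / 2) - t_opt)
    for (delta in dmax * c(0.2, 0.5, 0.9)) {
      expect_lt(eval_reaction_norm(p, t_opt + delta),
                eval_reaction_norm(p, t_opt - delta))
    }
    # the optimum dominates a dense grid over the positive-growth range
    grid <- seq(p$z - p$w / 2, p$z + p$w / 2, by = 1e-3)
    expect_gte(eval_reaction_norm(p, t_opt) + 1e-12,
               max(eval_reaction_norm(p, grid)))
  }
})

test_that("noiseless data at the assay grid are recovered to high accuracy", {
  truths <- list(c(18, 20, 0.2, 0.1), c(15, 26, 0.15, 0.08),
                 c(20, 16, 0.4, 0.02), c(14, 30, 0.1, 0.15),
                 c(21, 24, 0.25, -0.05))
  for (tr in truths) {
    p <- rn_params(tr[1], tr[2], tr[3], tr[4])
    temps <- c(15, 18, 22, 24, 26, 27)
    fit <- fit_reaction_norm(temps, eval_reaction_norm(p, temps))
    est <- unname(c(fit$params$z, fit$params$w, fit$params$a, fit$params$b))
    expect_equal(est, tr, tolerance = 1e-3)
    expect_lt(fit$params$sigma, 1e-5)
    # residuals + fitted values reconstruct the observations
    expect_equal(fit$fitted_values + fit$residuals, fit$rate)
  }
})

test_that("fitting rejects unusable inputs", {
  expect_error(fit_reaction_norm(c(15, 22, 27), c(0.2, 0.8, 0.1)),
               class = "thermnorm_insufficient_data")
  expect_error(fit_reaction_norm(c(15, 15, 22, 22, 27), c(0.2, 0.21, 0.8, 0.79, 0.1)),
               class = "thermnorm_insufficient_data")
})

test_that("fits are invariant to record order, duplication, and rate rescaling", {
  p <- rn_params(18, 22, 0.2, 0.1)
  temps <- c(15, 18, 22, 24, 26, 27)
  y <- eval_reaction_norm(p, temps)

  f1 <- fit_reaction_norm(temps, y)
  ord <- c(4, 1, 6, 2, 5, 3)
  f2 <- fit_reaction_norm(temps[ord], y[ord])
  expect_equal(unclass(f1$params)[1:4], unclass(f2$params)[1:4],
               tolerance = 1e-6)

  # duplicating one noiseless observation cannot move a perfect fit
  f3 <- fit_reaction_norm(c(temps, 22), c(y, y[3]))
  expect_equal(unclass(f1$params)[1:4], unclass(f3$params)[1:4],
               tolerance = 1e-4)

  # doubling all rates doubles a and leaves the shape parameters alone
  f4 <- fit_reaction_norm(temps, 2 * y)
  expect_equal(f4$params$a, 2 * f1$params$a, tolerance = 1e-4)
  expect_equal(c(f4$params$z, f4$params$w, f4$params$b),
               c(f1$params$z, f1$params$w, f1$params$b), tolerance = 1e-4)
})

test_that("censored records are excluded from the fit", {
  p <- rn_params(18, 22, 0.2, 0.1)
  temps <- c(15, 18, 22, 24, 26, 27)
  u <- make_noiseless_unit(p, temps)
  u$growth_rate[6] <- 0            # no growth recorded at 27
  cen <- censor_no_growth(u)
  fit <- fit_reaction_norm(cen)
  expect_equal(fit$n_obs, 5)
  expect_false(27 %in% fit$temp)
})

test_that("the observed maximum growth rate reports value and temperature", {
  mm <- observed_mu_max(c(15, 22, 26), c(0.4, 0.9, 0.7))
  expect_equal(mm$mu_max, 0.9)
  expect_equal(mm$temp, 22)
  # ties break toward the lowest qualifying temperature
  tie <- observed_mu_max(c(15, 22, 26), c(0.7, 0.7, 0.7))
  expect_equal(tie$temp, 15)
  zero <- observed_mu_max(c(15, 22), c(0, 0))
  expect_equal(zero$mu_max, 0)
  expect_equal(zero$temp, 15)
  expect_error(observed_mu_max(numeric(), numeric()),
               class = "thermnorm_invalid_input")
  # censored rows do not count
  u <- make_unit(c(`22` = 0.5, `27` = 0.9))
  u$censored <- c(FALSE, TRUE)
  expect_equal(observed_mu_max(u)$mu_max, 0.5)
})
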