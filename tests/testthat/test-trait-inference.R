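test_that("two-SD standardization gives mean zero and SD one half", {
  x <- rep(c(400, 1100, 2200), each = 10)
  s <- standardize_pco2(x)
  expect_equal(mean(s), 0, tolerance = 1e-14)
  expect_equal(sd(s), 0.5, tolerance = 1e-14)
  expect_equal(s, (x - mean(x)) / (2 * sd(x)))
  expect_error(standardize_pco2(rep(400, 30)),
               class = "thermnorm_invalid_input")
  expect_error(standardize_pco2(400), class = "thermnorm_invalid_input")
})

test_that("the trait linear model interpolates planted noiseless effects", {
  design <- make_design()
  y <- 1.0 + 0.5 * design$temp_high
  res <- fit_trait_lm(design, y)
  expect_equal(unname(res$coefficients), c(1.0, 0.5, 0, 0), tolerance = 1e-12)
  expect_equal(res$adjusted_r2, 1)

  res2 <- fit_trait_lm(design, rep(2, nrow(design)))
  expect_equal(unname(res2$coefficients), c(2, 0, 0, 0), tolerance = 1e-12)
})

test_that("the trait linear model matches a normal-equations solve", {
  design <- make_design()
  set.seed(42)
  for (i in 1:10) {
    y <- rnorm(nrow(design))
    res <- fit_trait_lm(design, y)
    X <- cbind(1, design$temp_high, design$pco2_std,
               design$temp_high * design$pco2_std)
    expect_equal(unname(res$coefficients), normal_equations_coef(X, y),
                 tolerance = 1e-10)
  }
})

test_that("degenerate designs are rejected with a useful message", {
  design <- make_design()
  expect_error(fit_trait_lm(design[1:4, ], rnorm(4)),
               class = "thermnorm_insufficient_data")
  one_temp <- design[design$temp_high == 1, ]
  expect_error(fit_trait_lm(one_temp, rnorm(nrow(one_temp))),
               regexp = "selection temperatures")
  collinear <- design
  collinear$pco2_std <- collinear$temp_high  # pCO2 aliases the temperature
  expect_error(fit_trait_lm(collinear, rnorm(nrow(collinear))),
               class = "thermnorm_invalid_input", regexp = "collinear")
})

test_that("t statistics are invariant under the two-SD reparameterization", {
  design <- make_design()
  set.seed(7)
  y <- 21 + 0.7 * design$temp_high - 0.4 * design$pco2_std + rnorm(30, 0, 0.3)
  raw <- summary(lm(y ~ temp_high * pco2, data = design))$coefficients
  std <- summary(lm(y ~ temp_high * pco2_std, data = design))$coefficients
  expect_equal(raw["pco2", "t value"], std["pco2_std", "t value"],
               tolerance = 1e-10)
  expect_equal(std["pco2_std", "Estimate"],
               raw["pco2", "Estimate"] * 2 * sd(design$pco2),
               tolerance = 1e-10)
})

test_that("constant bootstrap draws collapse coefficient intervals to points", {
  design <- make_design()
  truth <- 21 + 0.7 * design$temp_high
  boots <- lapply(seq_len(nrow(design)), function(i) {
    make_fake_boot(rep(truth[i], 50), replicate_id = design$replicate_id[i])
  })
  eff <- bootstrap_trait_inference(boots, design, "t_opt")
  expect_equal(unname(eff$coefficients$ci_hi - eff$coefficients$ci_lo),
               rep(0, 4), tolerance = 1e-12)
  cf <- eff$coefficients
  expect_true(cf$significant[cf$term == "temp_effect"])
  expect_equal(cf$estimate[cf$term == "temp_effect"], 0.7, tolerance = 1e-10)
})

test_that("a significant interaction masks the main effects", {
  design <- make_design()
  set.seed(11)
  base <- 27 + 2 * design$temp_high - 1.5 * design$pco2_std +
    2 * design$temp_high * design$pco2_std
  boots <- lapply(seq_len(nrow(design)), function(i) {
    make_fake_boot(base[i] + rnorm(200, 0, 0.1),
                   replicate_id = design$replicate_id[i])
  })
  eff <- bootstrap_trait_inference(boots, design, "t_max")
  cf <- eff$coefficients
  expect_true(cf$significant[cf$term == "interaction"])
  expect_true(eff$interaction_masks_main_effects)
  expect_false(any(cf$interpretable[cf$term %in% c("temp_effect", "pco2_effect")]))
  expect_true(all(cf$interpretable[cf$term %in% c("intercept", "interaction")]))
})

test_that("misaligned bootstrap lengths are rejected; failed iterations skipped", {
  design <- make_design()
  boots <- lapply(seq_len(nrow(design)), function(i) make_fake_boot(rnorm(60)))
  bad <- boots
  bad[[3]] <- make_fake_boot(rnorm(50))
  expect_error(bootstrap_trait_inference(bad, design, "t_opt"),
               class = "thermnorm_invalid_input")
  # drop some iterations from one unit: those columns are skipped listwise
  holey <- boots
  holey[[5]]$draws <- holey[[5]]$draws[-(1:10), ]
  eff <- bootstrap_trait_inference(holey, design, "t_opt")
  expect_equal(eff$n_skipped, 10L)
  expect_equal(eff$n_bootstrap, 50L)
})

test_that("mu_max inference uses normal-theory intervals on a single fit", {
  design <- make_design()
  y <- 1.0 - 0.2 * design$pco2_std
  # a noiseless fixture makes lm's summary complain about the perfect fit
  eff <- suppressWarnings(mu_max_inference(design, y))
  cf <- eff$coefficients
  expect_equal(cf$estimate, c(1.0, 0, -0.2, 0), tolerance = 1e-10)
  expect_equal(cf$ci_hi - cf$ci_lo, rep(0, 4), tolerance = 1e-8)

  set.seed(3)
  y2 <- 1.0 - 0.1 * design$pco2_std + rnorm(30, 0, 0.02)
  eff2 <- mu_max_inference(design, y2)
  fit <- lm(y2 ~ temp_high * pco2_std, data = design)
  expect_equal(unname(as.matrix(eff2$coefficients[, c("ci_lo", "ci_hi")])),
               unname(confint(fit)), tolerance = 1e-10)
  expect_true(eff2$coefficients$significant[3])
})

test_that("treatment-cell summaries average replicates with sane intervals", {
  design <- make_design(n_rep = 1)
  traits <- tibble::tibble(t_opt = 21 + design$temp_high,
                           t_max = 28 + design$temp_high,
                           mu_max = 1 - 0.1 * design$pco2_std)
  boots <- lapply(seq_len(nrow(design)),
                  function(i) make_fake_boot(rep(traits$t_opt[i], 30),
                                             rep(traits$t_max[i], 30)))
  tab <- summarize_traits_by_treatment(design, traits, boots)
  expect_equal(nrow(tab), 6 * 3)
  one <- tab[tab$trait == "t_opt" & tab$selection_temp == 15 & tab$pco2 == 400, ]
  expect_equal(one$mean, 21)
  expect_equal(one$n, 1L)
  mu <- tab[tab$trait == "mu_max", ]
  expect_equal(mu$ci_hi - mu$ci_lo, rep(0, 6))  # single unit per cell

  # planted 0.7 degree separation shows up in the cell means
  design5 <- make_design(n_rep = 5)
  traits5 <- tibble::tibble(t_opt = 21.3 + 0.7 * design5$temp_high,
                            t_max = 28, mu_max = 1)
  boots5 <- lapply(seq_len(nrow(design5)),
                   function(i) make_fake_boot(rep(traits5$t_opt[i], 30),
                                              rep(28, 30)))
  tab5 <- summarize_traits_by_treatment(design5, traits5, boots5)
  t_opt_means <- tapply(tab5$mean[tab5$trait == "t_opt"],
                        tab5$selection_temp[tab5$trait == "t_opt"], mean)
  expect_equal(unname(diff(t_opt_means)), 0.7, tolerance = 1e-12)
})
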