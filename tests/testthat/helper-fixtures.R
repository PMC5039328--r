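# Shared fixtures: everything is generated in code at test time.

# one replicate's records as a tidy tibble
make_unit <- function(rates, temps = as.numeric(names(rates)),
                      id = "U1", selection_temp = 15, pco2 = 400) {
  tibble::tibble(replicate_id = id, selection_temp = selection_temp,
                 pco2 = pco2, assay_temp = temps,
                 growth_rate = unname(rates))
}

# noiseless records from known curve parameters at the standard assay grid
make_noiseless_unit <- function(params, temps = c(15, 18, 22, 24, 26, 27),
                                id = "U1") {
  make_unit(pmax(eval_reaction_norm(params, temps), 0), temps, id = id)
}

# random valid parameter sets within the plausible region used for fitting
random_params <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    z = runif(n, 10, 25),
    w = runif(n, 8, 40),
    a = runif(n, 0.05, 0.5),
    b = runif(n, -0.3, 0.3)
  )
}

# dense-grid argmax oracle for the optimum temperature, independent of the
# optimizer used in the package
grid_topt <- function(p, resolution = 1e-4) {
  grid <- seq(p$z - p$w / 2, p$z + p$w / 2, by = resolution)
  grid[which.max(eval_reaction_norm(p, grid))]
}

# positive root of the stationarity quadratic b*u^2 + (4/w)*u - b = 0,
# solved with the textbook formula (test-side oracle)
quadratic_topt <- function(p) {
  if (abs(p$b) < 1e-14) return(p$z)
  A <- p$b; B <- 4 / p$w; C <- -p$b
  roots <- c((-B + sqrt(B^2 - 4 * A * C)) / (2 * A),
             (-B - sqrt(B^2 - 4 * A * C)) / (2 * A))
  u <- roots[abs(roots) < 1][1]
  p$z + (p$w / 2) * u
}

# brute-force OLS through the normal equations
normal_equations_coef <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# a bootstrap-distribution stand-in with prescribed draws, shaped like the
# output of residual_bootstrap()
make_fake_boot <- function(t_opt_draws, t_max_draws = t_opt_draws,
                           replicate_id = "U1") {
  n <- length(t_opt_draws)
  structure(list(
    replicate_id = replicate_id,
    draws = tibble::tibble(iteration = seq_len(n), z = NA_real_, w = NA_real_,
                           a = NA_real_, b = NA_real_,
                           t_opt = t_opt_draws, t_max = t_max_draws),
    n_iter = n, n_failed = 0L, seed = 0L, mode = "permute", inflate = TRUE,
    unreliable = FALSE,
    point = list(t_opt = mean(t_opt_draws), t_max = mean(t_max_draws))
  ), class = "rn_boot")
}

# balanced two-temperature x three-pCO2 design table
make_design <- function(n_rep = 5) {
  g <- expand.grid(selection_temp = c(15, 26.3), pco2 = c(400, 1100, 2200),
                   rep = seq_len(n_rep), KEEP.OUT.ATTRS = FALSE)
  g$replicate_id <- sprintf("T%g_C%d_R%d", g$selection_temp, g$pco2, g$rep)
  trait_design(g[, c("replicate_id", "selection_temp", "pco2")])
}
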