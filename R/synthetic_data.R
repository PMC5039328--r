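#' Solve reaction-norm parameters from planted trait values
#'
#' Inverse mapping used by the scenario generator: given a target optimal
#' temperature, maximum persistence temperature and peak growth rate, and a
#' fixed exponential shape `b`, finds the (z, w, a) for which the reaction
#' norm attains exactly those traits. The gap `t_max - t_opt` is bounded
#' above by `1/b`, so targets must respect `t_max - t_opt < 1/b`.
#'
#' @param t_opt Target optimal growth temperature, degrees C.
#' @param t_max Target maximum persistence temperature, degrees C (must
#'   exceed `t_opt`).
#' @param mu_peak Target growth rate at the optimum, per day.
#' @param b Exponential shape, per degree C (default 0.1).
#' @return An [rn_params()] object.
#' @export
rn_params_for_traits <- function(t_opt, t_max, mu_peak, b = 0.1) {
  if (t_max <= t_opt) {
    abort("`t_max` must exceed `t_opt`.", class = "thermnorm_invalid_input")
  }
  if (b > 0 && t_max - t_opt >= 1 / b) {
    abort(sprintf("gap t_max - t_opt = %.2f is unattainable for b = %g (limit 1/b = %.2f)",
                  t_max - t_opt, b, 1 / b),
          class = "thermnorm_invalid_input")
  }
  gap <- function(w) {
    z <- t_max - w / 2
    topt_closed_form(z, w, b) - t_opt
  }
  w <- uniroot(gap, lower = 2 * (t_max - t_opt) + 1e-6, upper = 500,
               tol = 1e-10)$root
  z <- t_max - w / 2
  u_opt <- (t_opt - z) / (w / 2)
  a <- mu_peak / (exp(b * t_opt) * (1 - u_opt^2))
  rn_params(z, w, a, b)
}

#' Define a synthetic assay scenario
#'
#' A scenario fixes the factorial design (selection temperatures, pCO2
#' levels, replicates per cell, assay temperatures), the true reaction-norm
#' parameters of each treatment cell, and the observation model: Gaussian
#' noise on the rate scale, small between-replicate parameter jitter, and
#' truncation of negative observed rates to zero (the assays cannot measure
#' negative growth).
#'
#' @param cell_params A tibble with one row per treatment cell and columns
#'   `selection_temp`, `pco2`, `z`, `w`, `a`, `b`.
#' @param n_replicates Replicate populations per cell (default 5).
#' @param assay_temps Assay temperatures, degrees C.
#' @param noise_sd Residual SD of observed rates, per day (default 0.05).
#' @param replicate_z_sd Between-replicate SD of `z`, degrees C
#'   (default 0.1).
#' @param replicate_a_cv Between-replicate multiplicative coefficient of
#'   variation of `a` (default 0.02).
#' @param truncate_negative Set negative observed rates to 0 (default
#'   `TRUE`).
#' @return A list of class `rn_scenario`.
#' @export
scenario_spec <- function(cell_params,
                          n_replicates = 5L,
                          assay_temps = DESIGN_ASSAY_TEMPS,
                          noise_sd = 0.05,
                          replicate_z_sd = 0.1,
                          replicate_a_cv = 0.02,
                          truncate_negative = TRUE) {
  cell_params <- tibble::as_tibble(cell_params)
  need <- c("selection_temp", "pco2", "z", "w", "a", "b")
  if (!all(need %in% names(cell_params))) {
    abort(paste0("`cell_params` needs columns: ", paste(need, collapse = ", ")),
          class = "thermnorm_invalid_input")
  }
  if (any(cell_params$w <= 0) || any(cell_params$a <= 0)) {
    abort("every cell needs w > 0 and a > 0.",
          class = "thermnorm_invalid_input")
  }
  if (anyDuplicated(cell_params[, c("selection_temp", "pco2")])) {
    abort("duplicate treatment cell in `cell_params`.",
          class = "thermnorm_invalid_input")
  }
  if (n_replicates < 1 || noise_sd < 0) {
    abort("invalid scenario sizes.", class = "thermnorm_invalid_input")
  }
  structure(list(cell_params = cell_params,
                 n_replicates = as.integer(n_replicates),
                 assay_temps = assay_temps, noise_sd = noise_sd,
                 replicate_z_sd = replicate_z_sd,
                 replicate_a_cv = replicate_a_cv,
                 truncate_negative = truncate_negative),
            class = "rn_scenario")
}

#' Scenario emulating the factorial evolution-assay study
#'
#' Two selection temperatures (15.0 / 26.3 degrees C) crossed with three
#' pCO2 levels (400 / 1100 / 2200 micro-atm), five replicate populations
#' per cell, assayed at 15, 18, 22, 24, 26 and 27 degrees C. Planted traits
#' follow the patterns this analysis is designed to detect: the optimum
#' temperature is 0.7 degrees C higher in warm-selected populations
#' (21.3 vs 22.0 degrees C); T_max is flat at 28.7 degrees C under warm
#' selection but declines from 28 to 27 to 26 degrees C with rising pCO2
#' under cold selection; the peak growth rate declines with pCO2, more
#' steeply under cold selection (0.2 per day across the pCO2 range) than
#' under warm selection (0.09 per day).
#'
#' @inheritParams scenario_spec
#' @return An `rn_scenario`.
#' @export
reference_scenario <- function(noise_sd = 0.05,
                                n_replicates = 5L,
                                replicate_z_sd = 0.1,
                                replicate_a_cv = 0.02) {
  grid <- expand.grid(selection_temp = DESIGN_SELECTION_TEMPS,
                      pco2 = DESIGN_PCO2_LEVELS, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    st <- grid$selection_temp[i]
    pc <- grid$pco2[i]
    frac <- (pc - 400) / 1800
    if (st < 20) {  # cold-selected
      t_opt <- 21.3
      t_max <- c(`400` = 28, `1100` = 27, `2200` = 26)[[as.character(pc)]]
      mu <- 1.15 - 0.2 * frac
    } else {        # warm-selected
      t_opt <- 22.0
      t_max <- 28.7
      mu <- 1.10 - 0.09 * frac
    }
    p <- rn_params_for_traits(t_opt, t_max, mu, b = 0.1)
    tibble::tibble(selection_temp = st, pco2 = pc,
                   z = p$z, w = p$w, a = p$a, b = p$b)
  })
  scenario_spec(dplyr::bind_rows(rows), n_replicates = n_replicates,
                noise_sd = noise_sd, replicate_z_sd = replicate_z_sd,
                replicate_a_cv = replicate_a_cv)
}

#' Generate a synthetic assay dataset from a scenario
#'
#' Draws per-replicate true parameters (cell parameters plus jitter),
#' evaluates the reaction norm at the assay temperatures, adds Gaussian
#' noise on the rate scale, and truncates negative observations to zero
#' when the scenario says so. Fully reproducible given `seed`.
#'
#' @param spec An `rn_scenario`.
#' @param seed Integer seed.
#' @return A list with `data` (validated assay tibble), `truth` (one row
#'   per unit: true parameters and derived traits) and the `spec`.
#' @export
generate_dataset <- function(spec, seed = 1) {
  if (!inherits(spec, "rn_scenario")) {
    abort("`spec` must be an `rn_scenario`.", class = "thermnorm_invalid_input")
  }
  set.seed(as.integer(seed) %% 2147483629)
  recs <- list()
  truth <- list()
  for (i in seq_len(nrow(spec$cell_params))) {
    cell <- spec$cell_params[i, ]
    for (r in seq_len(spec$n_replicates)) {
      z_r <- cell$z + rnorm(1, 0, spec$replicate_z_sd)
      a_r <- cell$a * exp(rnorm(1, 0, spec$replicate_a_cv))
      id <- sprintf("T%04.1f_C%04d_R%d", cell$selection_temp, cell$pco2, r)
      mu_true <- rn_curve(spec$assay_temps, z_r, cell$w, a_r, cell$b)
      obs <- mu_true + rnorm(length(spec$assay_temps), 0, spec$noise_sd)
      if (spec$truncate_negative) obs <- pmax(obs, 0)
      recs[[length(recs) + 1]] <- tibble::tibble(
        replicate_id = id, selection_temp = cell$selection_temp,
        pco2 = cell$pco2, assay_temp = spec$assay_temps,
        growth_rate = obs)
      p_r <- rn_params(z_r, cell$w, a_r, cell$b)
      truth[[length(truth) + 1]] <- tibble::tibble(
        replicate_id = id, selection_temp = cell$selection_temp,
        pco2 = cell$pco2, z = z_r, w = cell$w, a = a_r, b = cell$b,
        t_opt = derive_topt(p_r), t_max = derive_tmax(p_r),
        mu_max = max(mu_true))
    }
  }
  list(data = as_assay_data(dplyr::bind_rows(recs)),
       truth = dplyr::bind_rows(truth),
       spec = spec)
}

#' Write / read a scenario as YAML
#'
#' @param spec An `rn_scenario`.
#' @param path File path.
#' @return `write_scenario_yaml()` returns `path` invisibly;
#'   `read_scenario_yaml()` returns the `rn_scenario`.
#' @export
write_scenario_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "rn_scenario"))
  x <- unclass(spec)
  # doubles as 17-digit strings so the round trip is exact
  num2chr <- function(v) if (is.double(v)) sprintf("%.17g", v) else v
  x <- lapply(x, function(el) if (is.data.frame(el)) el else num2chr(el))
  x$cell_params <- lapply(seq_len(nrow(spec$cell_params)), function(i) {
    lapply(as.list(spec$cell_params[i, ]), num2chr)
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  cells <- dplyr::bind_rows(lapply(x$cell_params, tibble::as_tibble))
  for (cl in setdiff(names(cells), "replicate_id")) {
    cells[[cl]] <- as.numeric(cells[[cl]])
  }
  scenario_spec(cells,
                n_replicates = as.integer(x$n_replicates),
                assay_temps = as.numeric(x$assay_temps),
                noise_sd = as.numeric(x$noise_sd),
                replicate_z_sd = as.numeric(x$replicate_z_sd),
                replicate_a_cv = as.numeric(x$replicate_a_cv),
                truncate_negative = as.logical(x$truncate_negative))
}
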