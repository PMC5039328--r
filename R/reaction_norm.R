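#' Reaction-norm parameter set
#'
#' Container for the four parameters of the unimodal, left-skewed thermal
#' reaction norm
#' \deqn{f(T) = a\,e^{bT}\left[1 - \left(\frac{T - z}{w/2}\right)^2\right]}
#' plus the residual noise scale of the Gaussian observation model.
#' `w` is the thermal niche width — the range of temperatures over which
#' growth is positive, so `f(z - w/2) = f(z + w/2) = 0` exactly. The
#' remaining parameters have no individual biological meaning but jointly
#' set the rise rate, peak height and optimum location.
#'
#' @param z Location parameter, degrees C (midpoint of the niche).
#' @param w Thermal niche width, degrees C; must be positive.
#' @param a Scale, per day; must be positive.
#' @param b Exponential shape, per degree C. Positive values give the
#'   left-skewed shape typical of thermal performance curves.
#' @param sigma Residual standard deviation, per day (maximum-likelihood
#'   estimate when produced by [fit_reaction_norm()]).
#' @return An object of class `rn_params`.
#' @examples
#' p <- rn_params(z = 18, w = 20, a = 0.2, b = 0.1)
#' eval_reaction_norm(p, c(8, 18, 28))
#' @export
rn_params <- function(z, w, a, b, sigma = 0) {
  vals <- c(z = z, w = w, a = a, b = b, sigma = sigma)
  if (any(!is.finite(vals))) {
    abort("reaction-norm parameters must be finite numbers.",
          class = "thermnorm_invalid_params")
  }
  if (w <= 0) {
    abort("thermal niche width `w` must be positive.",
          class = "thermnorm_invalid_params")
  }
  if (a <= 0) {
    abort("scale `a` must be positive.", class = "thermnorm_invalid_params")
  }
  if (sigma < 0) {
    abort("`sigma` must be non-negative.", class = "thermnorm_invalid_params")
  }
  structure(list(z = z, w = w, a = a, b = b, sigma = sigma),
            class = "rn_params")
}

#' @export
print.rn_params <- function(x, ...) {
  cat(sprintf(
    "Thermal reaction norm parameters\n  z = %.4f °C, w = %.4f °C, a = %.5f /day, b = %.5f /°C, sigma = %.5f /day\n",
    x$z, x$w, x$a, x$b, x$sigma))
  invisible(x)
}

as_rn_params <- function(p) {
  if (inherits(p, "rn_params")) return(p)
  if (is.numeric(p) && length(p) >= 4) {
    nm <- names(p)
    if (!is.null(nm) && all(c("z", "w", "a", "b") %in% nm)) {
      return(rn_params(p[["z"]], p[["w"]], p[["a"]], p[["b"]],
                       if ("sigma" %in% nm) p[["sigma"]] else 0))
    }
    return(rn_params(p[1], p[2], p[3], p[4], if (length(p) >= 5) p[5] else 0))
  }
  abort("cannot interpret `params` as reaction-norm parameters.",
        class = "thermnorm_invalid_params")
}

# bare evaluation on raw parameter vector (z, w, a, b); no validation —
# used in the optimizer's inner loop
rn_curve <- function(temp, z, w, a, b) {
  u <- (temp - z) / (w / 2)
  a * exp(b * temp) * (1 - u^2)
}

#' Evaluate the thermal reaction norm
#'
#' @param params An [rn_params()] object (or a named numeric vector with
#'   elements `z`, `w`, `a`, `b`).
#' @param temp Assay temperature(s), degrees C.
#' @return Predicted growth rate per day; negative outside
#'   `(z - w/2, z + w/2)`.
#' @export
eval_reaction_norm <- function(params, temp) {
  p <- as_rn_params(params)
  rn_curve(temp, p$z, p$w, p$a, p$b)
}

# residuals and Jacobian for the Levenberg-Marquardt fit; par = (z, w, a, b)
rn_resid <- function(par, temp, rate) {
  rate - rn_curve(temp, par[1], par[2], par[3], par[4])
}

rn_jac <- function(par, temp, rate) {
  z <- par[1]; w <- par[2]; a <- par[3]; b <- par[4]
  u <- (temp - z) / (w / 2)
  e <- exp(b * temp)
  br <- 1 - u^2
  # d(residual)/d(par) = -d f/d(par)
  cbind(-a * e * 4 * u / w,      # z
        -a * e * 2 * u^2 / w,    # w
        -e * br,                 # a
        -a * temp * e * br)      # b
}

#' Control settings for reaction-norm fitting
#'
#' The likelihood surface of the reaction norm has local optima, so the fit
#' is restarted from a fixed grid of starting values: `n_z_starts` values of
#' `z` spread over the observed temperature range, crossed with `w_starts`
#' and `b_starts`; the scale `a` is seeded from the highest observed rate at
#' each (z, b) start. Box constraints keep the optimizer in a biologically
#' meaningful region; `z` is bounded by the observed temperature range
#' widened by `z_margin`.
#'
#' @param n_z_starts Number of starting values for `z`.
#' @param w_starts Starting values for the niche width, degrees C.
#' @param b_starts Starting values for the exponential shape, per degree C.
#' @param w_bounds,a_bounds,b_bounds Lower/upper optimization bounds.
#' @param z_margin Degrees C added on both sides of the observed temperature
#'   range to bound `z`.
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @return A list of class `rn_fit_control`.
#' @export
rn_fit_control <- function(n_z_starts = 5,
                           w_starts = c(10, 20, 30),
                           b_starts = c(0.01, 0.05, 0.1, 0.2),
                           w_bounds = c(1, 60),
                           a_bounds = c(1e-6, 10),
                           b_bounds = c(-1, 1),
                           z_margin = 20,
                           max_iter = 200) {
  structure(list(n_z_starts = n_z_starts, w_starts = w_starts,
                 b_starts = b_starts, w_bounds = w_bounds,
                 a_bounds = a_bounds, b_bounds = b_bounds,
                 z_margin = z_margin, max_iter = max_iter),
            class = "rn_fit_control")
}

rn_start_grid <- function(temp, rate, control) {
  zs <- seq(min(temp), max(temp), length.out = control$n_z_starts)
  g <- expand.grid(z = zs, w = control$w_starts, b = control$b_starts,
                   KEEP.OUT.ATTRS = FALSE)
  peak <- max(rate, 0.05)  # floor so all-zero data still gets a usable scale
  g$a <- pmin(pmax(peak / exp(g$b * g$z), 1e-4), 9)
  g[, c("z", "w", "a", "b")]
}

rn_fit_one_start <- function(start, temp, rate, lower, upper, max_iter) {
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper,
      fn = rn_resid, jac = rn_jac, temp = temp, rate = rate,
      control = minpack.lm::nls.lm.control(maxiter = max_iter))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  converged <- fit$info %in% 1:3
  list(par = fit$par, sse = sum(fit$fvec^2), converged = converged,
       info = fit$info)
}

#' Fit the thermal reaction norm to one replicate by maximum likelihood
#'
#' Maximizes the Gaussian likelihood of the observed growth rates — which,
#' with a constant error variance, is nonlinear least squares in
#' (z, w, a, b) — using Levenberg-Marquardt with an analytic Jacobian,
#' restarted from a fixed multi-start grid. The residual scale `sigma` is
#' set to its maximum-likelihood value `sqrt(SSE / n)`. Among converged
#' starts the best sum of squares wins; exact ties go to the smallest
#' parameter-vector norm so the result is deterministic.
#'
#' Censored records (see [censor_no_growth()]) are excluded; uncensored
#' zero rates are retained as genuine observations of no growth.
#'
#' @param data A validated assay tibble for a single replicate (or any data
#'   frame with `assay_temp` and `growth_rate`; a `censored` column is
#'   honoured if present), or a numeric vector of temperatures when `rate`
#'   is given.
#' @param rate Optional numeric vector of growth rates, paired with a
#'   numeric `data`.
#' @param control An [rn_fit_control()] object.
#' @param start Optional extra starting value (an [rn_params()] or numeric
#'   `c(z, w, a, b)`) tried before the grid; used to warm-start bootstrap
#'   refits.
#' @param grid If `FALSE`, only `start` is tried (internal fast path).
#' @return An object of class `rn_fit`: a list with elements `params`
#'   ([rn_params()]), `fitted_values`, `residuals`, `log_likelihood`,
#'   `converged`, `n_obs`, `start_points_tried`, and the data used
#'   (`temp`, `rate`).
#' @export
fit_reaction_norm <- function(data, rate = NULL, control = rn_fit_control(),
                              start = NULL, grid = TRUE) {
  if (is.data.frame(data)) {
    keep <- if ("censored" %in% names(data)) !data$censored else TRUE
    temp <- data$assay_temp[keep]
    y <- data$growth_rate[keep]
  } else {
    temp <- as.numeric(data)
    y <- as.numeric(rate)
  }
  if (length(temp) != length(y) || anyNA(temp) || anyNA(y)) {
    abort("temperatures and rates must be equal-length and complete.",
          class = "thermnorm_invalid_input")
  }
  if (length(y) < 5) {
    abort(sprintf(
      "need at least 5 observations to fit 4 curve parameters plus noise; got %d",
      length(y)), class = "thermnorm_insufficient_data")
  }
  if (length(unique(temp)) < 4) {
    abort("need at least 4 distinct assay temperatures.",
          class = "thermnorm_insufficient_data")
  }

  lower <- c(min(temp) - control$z_margin, control$w_bounds[1],
             control$a_bounds[1], control$b_bounds[1])
  upper <- c(max(temp) + control$z_margin, control$w_bounds[2],
             control$a_bounds[2], control$b_bounds[2])

  starts <- list()
  if (!is.null(start)) {
    s <- as_rn_params(start)
    starts[[1]] <- pmin(pmax(c(s$z, s$w, s$a, s$b), lower), upper)
  }
  if (grid || length(starts) == 0) {
    g <- rn_start_grid(temp, y, control)
    starts <- c(starts, lapply(seq_len(nrow(g)), function(i) unlist(g[i, ])))
  }

  best <- NULL
  n_tried <- 0L
  for (s in starts) {
    n_tried <- n_tried + 1L
    res <- rn_fit_one_start(s, temp, y, lower, upper, control$max_iter)
    if (is.null(res) || !res$converged) next
    if (is.null(best) ||
        res$sse < best$sse - 1e-12 ||
        (abs(res$sse - best$sse) <= 1e-12 &&
         sum(res$par^2) < sum(best$par^2))) {
      best <- res
    }
  }
  if (is.null(best)) {
    abort(sprintf("no starting point converged (%d tried)", n_tried),
          class = "thermnorm_nonconvergence")
  }

  par <- unname(best$par)
  n <- length(y)
  sigma <- sqrt(best$sse / n)
  fitted <- rn_curve(temp, par[1], par[2], par[3], par[4])
  resid <- y - fitted
  loglik <- if (sigma > 0) {
    -n / 2 * (log(2 * pi * sigma^2) + 1)
  } else {
    Inf  # degenerate perfect fit
  }
  structure(list(
    params = rn_params(par[1], par[2], par[3], par[4], sigma),
    fitted_values = fitted,
    residuals = resid,
    log_likelihood = loglik,
    converged = TRUE,
    n_obs = n,
    start_points_tried = n_tried,
    temp = temp,
    rate = y
  ), class = "rn_fit")
}

#' @export
print.rn_fit <- function(x, ...) {
  cat(sprintf("Reaction-norm fit (%d observations, %d starts tried)\n",
              x$n_obs, x$start_points_tried))
  print(x$params)
  cat(sprintf("  logLik = %.4f, T_opt = %.3f °C, T_max = %.3f °C\n",
              x$log_likelihood, derive_topt(x$params), derive_tmax(x$params)))
  invisible(x)
}

# closed-form stationary point: b*u^2 + (4/w)*u - b = 0 with
# u = (T - z)/(w/2); the root inside (-1, 1) is the optimum. Rationalized
# form is stable as b -> 0 and correct for either sign of b.
topt_closed_form <- function(z, w, b) {
  u <- 2 * b / (4 / w + sqrt((4 / w)^2 + 4 * b^2))
  z + (w / 2) * u
}

#' Optimal growth temperature from fitted parameters
#'
#' Finds the temperature maximizing the reaction norm by bounded scalar
#' optimization over the positive-growth interval `[z - w/2, z + w/2]`,
#' and asserts the result against the closed-form stationarity condition
#' `b(1 - u^2) - (4/w)u = 0` before returning it.
#'
#' @param params An [rn_params()] object.
#' @param tolerance Numerical tolerance, degrees C.
#' @return T_opt in degrees C. Greater than `z` whenever `b > 0` (the
#'   left-skewed case).
#' @export
derive_topt <- function(params, tolerance = 1e-6) {
  p <- as_rn_params(params)
  lo <- p$z - p$w / 2
  hi <- p$z + p$w / 2
  opt <- optimize(function(t) rn_curve(t, p$z, p$w, p$a, p$b),
                  lower = lo, upper = hi, maximum = TRUE,
                  tol = min(tolerance, 1e-8))
  t_num <- opt$maximum
  t_cf <- topt_closed_form(p$z, p$w, p$b)
  if (abs(t_num - t_cf) > 1e-4) {
    abort(sprintf(
      "numerical T_opt %.6f °C fails the stationarity check (closed form %.6f °C)",
      t_num, t_cf), class = "thermnorm_numerical_check")
  }
  t_num
}

#' Maximum persistence temperature from fitted parameters
#'
#' Finds the upper zero crossing of the reaction norm — the temperature
#' above which growth becomes negative — by bracketed root finding on
#' `(T_opt, z + w/2 + eps]`, and asserts it against the analytic zero
#' `z + w/2` before returning it.
#'
#' @inheritParams derive_topt
#' @param t_opt Optional precomputed T_opt (saves re-deriving it when both
#'   traits are needed, as in the bootstrap loop).
#' @return T_max in degrees C.
#' @export
derive_tmax <- function(params, tolerance = 1e-6, t_opt = NULL) {
  p <- as_rn_params(params)
  t_opt <- if (is.null(t_opt)) derive_topt(p, tolerance) else t_opt
  hi <- p$z + p$w / 2
  root <- uniroot(function(t) rn_curve(t, p$z, p$w, p$a, p$b),
                  lower = t_opt, upper = hi + 1e-3,
                  tol = min(tolerance, 1e-9) / 10)$root
  if (abs(root - hi) > 1e-4) {
    abort(sprintf(
      "numerical T_max %.6f °C disagrees with the analytic zero %.6f °C",
      root, hi), class = "thermnorm_numerical_check")
  }
  root
}

#' Highest measured growth rate of a replicate
#'
#' The maximum growth rate trait is taken from the measurements themselves
#' rather than the fitted curve. Censored records are excluded. Ties are
#' broken toward the lowest qualifying assay temperature.
#'
#' @inheritParams fit_reaction_norm
#' @return A list with `mu_max` (per day) and `temp` (degrees C of the
#'   maximizing assay).
#' @export
observed_mu_max <- function(data, rate = NULL) {
  if (is.data.frame(data)) {
    keep <- if ("censored" %in% names(data)) !data$censored else TRUE
    temp <- data$assay_temp[keep]
    y <- data$growth_rate[keep]
  } else {
    temp <- as.numeric(data)
    y <- as.numeric(rate)
  }
  if (length(y) == 0) {
    abort("no uncensored records to take a maximum over.",
          class = "thermnorm_invalid_input")
  }
  m <- max(y)
  list(mu_max = m, temp = min(temp[y == m]))
}

#' Derive all three thermal traits for one fitted replicate
#'
#' @param fit An `rn_fit` object.
#' @return A one-row tibble with `t_opt`, `t_max`, `mu_max`, `mu_max_temp`.
#' @export
thermal_traits <- function(fit) {
  stopifnot(inherits(fit, "rn_fit"))
  mm <- observed_mu_max(fit$temp, fit$rate)
  tibble::tibble(
    t_opt = derive_topt(fit$params),
    t_max = derive_tmax(fit$params),
    mu_max = mm$mu_max,
    mu_max_temp = mm$temp
  )
}
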