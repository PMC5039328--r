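#' Residual bootstrap of a fitted thermal reaction norm
#'
#' Quantifies the sampling uncertainty of the fitted curve and of the
#' derived traits T_opt and T_max. In each iteration the fit's residuals
#' are randomly reassigned across the predicted values (each prediction
#' corresponds to one growth-rate measurement) and added to them; the
#' slightly different pseudo reaction norm is refitted and the traits are
#' re-derived. The default reassignment is a permutation of the residuals
#' without replacement; `mode = "resample"` draws them with replacement
#' (classic residual resampling). Refits are warm-started at the original
#' estimates and fall back to the full multi-start grid if the warm start
#' does not converge; iterations whose refit still fails are dropped and
#' counted in `n_failed`, never retried with fresh randomness.
#'
#' Because the residuals of a 4-parameter curve fitted to a handful of
#' points underestimate the observation noise (their variance is about
#' `(n - p)/n` of the error variance), the reassigned residuals are by
#' default rescaled by `sqrt(n / (n - 4))` so the pseudo-data carry the
#' noise level the fit implies; set `inflate = FALSE` for raw
#' reassignment.
#'
#' Randomness is seeded per (replicate, iteration) from `seed` and
#' `unit_index`, so draws are reproducible and independent of execution
#' order across replicates.
#'
#' @param fit A converged `rn_fit` object.
#' @param n_iter Number of bootstrap iterations (default 1000).
#' @param seed Master integer seed.
#' @param mode `"permute"` (default) or `"resample"`.
#' @param inflate Rescale residuals by `sqrt(n/(n - 4))` before
#'   reassignment (default `TRUE`).
#' @param control [rn_fit_control()] used for grid fallbacks.
#' @param replicate_id Label carried into the output.
#' @param unit_index Integer index of this replicate in the experiment,
#'   used to decorrelate the per-iteration seeds between replicates.
#' @return An object of class `rn_boot`: a list with `draws` (tibble with
#'   columns `iteration`, `z`, `w`, `a`, `b`, `t_opt`, `t_max`), counts
#'   `n_iter`/`n_failed`, the `seed`, the `mode`, and `unreliable = TRUE`
#'   when more than 5% of iterations failed.
#' @export
residual_bootstrap <- function(fit, n_iter = 1000, seed = 1,
                               mode = c("permute", "resample"),
                               inflate = TRUE,
                               control = rn_fit_control(),
                               replicate_id = NA_character_,
                               unit_index = 0L) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "rn_fit"))
  if (!isTRUE(fit$converged)) {
    abort("cannot bootstrap a non-converged fit.",
          class = "thermnorm_invalid_input")
  }
  if (!is.numeric(n_iter) || n_iter < 1) {
    abort("`n_iter` must be at least 1.", class = "thermnorm_invalid_input")
  }
  n_iter <- as.integer(n_iter)
  n <- fit$n_obs
  p0 <- fit$params
  res <- fit$residuals
  if (inflate && n > 4) res <- res * sqrt(n / (n - 4))

  rows <- vector("list", n_iter)
  n_failed <- 0L
  for (k in seq_len(n_iter)) {
    set.seed(boot_seed(seed, unit_index, k))
    idx <- if (mode == "permute") sample.int(n) else
      sample.int(n, replace = TRUE)
    pseudo <- fit$fitted_values + res[idx]
    refit <- tryCatch({
      f <- tryCatch(
        fit_reaction_norm(fit$temp, pseudo, control = control,
                          start = p0, grid = FALSE),
        error = function(e) fit_reaction_norm(fit$temp, pseudo,
                                              control = control,
                                              start = p0, grid = TRUE))
      p <- f$params
      to <- derive_topt(p)
      list(z = p$z, w = p$w, a = p$a, b = p$b,
           t_opt = to, t_max = derive_tmax(p, t_opt = to))
    }, error = function(e) NULL)
    if (is.null(refit)) {
      n_failed <- n_failed + 1L
    } else {
      rows[[k]] <- c(iteration = k, unlist(refit))
    }
  }
  draws <- tibble::as_tibble(do.call(rbind, rows[!vapply(rows, is.null, logical(1))]))
  if (nrow(draws) == 0) {
    draws <- tibble::tibble(iteration = integer(), z = numeric(),
                            w = numeric(), a = numeric(), b = numeric(),
                            t_opt = numeric(), t_max = numeric())
  }
  unreliable <- n_failed / n_iter > 0.05
  if (unreliable) {
    warn(sprintf("replicate %s: %d of %d bootstrap refits failed (> 5%%); distribution flagged unreliable",
                 replicate_id, n_failed, n_iter))
  }
  structure(list(replicate_id = replicate_id, draws = draws,
                 n_iter = n_iter, n_failed = n_failed, seed = seed,
                 mode = mode, inflate = inflate, unreliable = unreliable,
                 point = list(t_opt = derive_topt(p0),
                              t_max = derive_tmax(p0))),
            class = "rn_boot")
}

# deterministic per-(unit, iteration) seed below 2^31
boot_seed <- function(seed, unit_index, iteration) {
  as.integer((as.numeric(seed) + 999983 * as.numeric(unit_index) +
                7919 * as.numeric(iteration)) %% 2147483629)
}

#' @export
print.rn_boot <- function(x, ...) {
  ci_t_opt <- trait_ci(x$draws$t_opt)
  ci_t_max <- trait_ci(x$draws$t_max)
  cat(sprintf(
    "Residual bootstrap (%s mode): %d iterations, %d failed%s\n  T_opt %.3f °C [%.3f, %.3f]\n  T_max %.3f °C [%.3f, %.3f]\n",
    x$mode, x$n_iter, x$n_failed,
    if (x$unreliable) " (UNRELIABLE)" else "",
    x$point$t_opt, ci_t_opt[1], ci_t_opt[2],
    x$point$t_max, ci_t_max[1], ci_t_max[2]))
  invisible(x)
}

#' Percentile confidence interval from bootstrap draws
#'
#' Equal-tailed percentile interval using linear interpolation between
#' order statistics (quantile type 7), the definition used throughout the
#' package.
#'
#' @param draws Numeric vector of bootstrap draws (at least 20).
#' @param level Coverage level in (0, 1); default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
trait_ci <- function(draws, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must lie strictly between 0 and 1.",
          class = "thermnorm_invalid_input")
  }
  if (length(draws) < 20) {
    abort(sprintf("need at least 20 draws for a percentile interval; got %d",
                  length(draws)), class = "thermnorm_invalid_input")
  }
  alpha <- (1 - level) / 2
  unname(quantile(draws, c(alpha, 1 - alpha), type = 7, names = FALSE))
}
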