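#' Standardize pCO2 levels by two standard deviations
#'
#' Centers the per-unit pCO2 values and divides by twice their sample
#' standard deviation, so the resulting predictor has mean 0 and SD 0.5 and
#' its regression coefficient is directly comparable to that of a binary
#' treatment indicator.
#'
#' @param x Numeric vector of pCO2 levels (micro-atm), one per experimental
#'   unit; must contain at least two distinct values.
#' @return Unitless standardized vector of the same length.
#' @export
standardize_pco2 <- function(x) {
  if (!is.numeric(x) || length(x) < 2) {
    abort("`x` must be a numeric vector with at least 2 elements.",
          class = "thermnorm_invalid_input")
  }
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("pCO2 levels are constant; cannot standardize (zero SD).",
          class = "thermnorm_invalid_input")
  }
  (x - mean(x)) / (2 * s)
}

#' Build the treatment design table for trait models
#'
#' One row per experimental unit with the selection-temperature indicator
#' (1 for the high selection temperature, 0 for the low, which is the
#' reference level) and the two-SD-standardized pCO2.
#'
#' @param x A validated assay tibble, or any data frame with columns
#'   `replicate_id`, `selection_temp`, `pco2` (one row per unit or per
#'   record).
#' @return A tibble with columns `replicate_id`, `selection_temp`, `pco2`,
#'   `temp_high`, `pco2_std`.
#' @export
trait_design <- function(x) {
  d <- dplyr::distinct(tibble::as_tibble(x)[, c("replicate_id",
                                                "selection_temp", "pco2")])
  temps <- sort(unique(d$selection_temp))
  if (length(temps) != 2) {
    abort(sprintf("need exactly 2 selection temperatures; found %d",
                  length(temps)), class = "thermnorm_invalid_input")
  }
  d$temp_high <- as.integer(d$selection_temp == temps[2])
  d$pco2_std <- standardize_pco2(d$pco2)
  d
}

trait_model_matrix <- function(design) {
  X <- cbind(intercept = 1, temp_effect = design$temp_high,
             pco2_effect = design$pco2_std,
             interaction = design$temp_high * design$pco2_std)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("design is rank deficient; collinear column(s): %s",
                  paste(bad, collapse = ", ")),
          class = "thermnorm_invalid_input")
  }
  X
}

#' Fit the trait linear model for one set of trait values
#'
#' Ordinary least squares of a thermal trait on the selection-temperature
#' indicator, the standardized pCO2 level and their interaction:
#' `trait ~ temp_high + pco2_std + temp_high:pco2_std`.
#'
#' @param design A [trait_design()] tibble.
#' @param trait_value Numeric vector of trait values aligned with the
#'   design rows.
#' @return A list with `coefficients` (named numeric: `intercept`,
#'   `temp_effect`, `pco2_effect`, `interaction`), `adjusted_r2`, and the
#'   underlying `lm` fit.
#' @export
fit_trait_lm <- function(design, trait_value) {
  if (nrow(design) < 5) {
    abort("need at least 5 experimental units.",
          class = "thermnorm_insufficient_data")
  }
  if (length(unique(design$temp_high)) < 2) {
    abort("both selection temperatures must be present.",
          class = "thermnorm_invalid_input")
  }
  if (length(trait_value) != nrow(design) || anyNA(trait_value)) {
    abort("`trait_value` must be complete and aligned with the design.",
          class = "thermnorm_invalid_input")
  }
  trait_model_matrix(design)  # rank check
  fit <- lm(trait_value ~ temp_high * pco2_std, data = design)
  cf <- setNames(unname(coef(fit)),
                 c("intercept", "temp_effect", "pco2_effect", "interaction"))
  # suppress the "essentially perfect fit" note on noiseless input
  sm <- suppressWarnings(summary(fit))
  list(coefficients = cf,
       adjusted_r2 = sm$adj.r.squared,
       fit = fit)
}

new_trait_effects <- function(trait_name, coef_tbl, adjusted_r2,
                              n_bootstrap, level, n_skipped = 0L,
                              method = "bootstrap-percentile") {
  interaction_sig <- coef_tbl$significant[coef_tbl$term == "interaction"]
  coef_tbl$interpretable <- TRUE
  if (isTRUE(interaction_sig)) {
    coef_tbl$interpretable[coef_tbl$term %in%
                             c("temp_effect", "pco2_effect")] <- FALSE
  }
  structure(list(trait_name = trait_name, coefficients = coef_tbl,
                 adjusted_r2 = adjusted_r2,
                 interaction_masks_main_effects = isTRUE(interaction_sig),
                 n_bootstrap = n_bootstrap, n_skipped = n_skipped,
                 level = level, method = method),
            class = "trait_effects")
}

#' @export
print.trait_effects <- function(x, ...) {
  cat(sprintf("Trait effects for %s (%s, level %.2f, adj. R^2 = %.3f)\n",
              x$trait_name, x$method, x$level, x$adjusted_r2))
  print(as.data.frame(x$coefficients), row.names = FALSE)
  if (x$interaction_masks_main_effects) {
    cat("Interaction is significant: main-effect significance not interpreted.\n")
  }
  invisible(x)
}

#' Propagate bootstrap trait uncertainty into treatment-effect inference
#'
#' For each bootstrap iteration, assembles the trait draws of all
#' experimental units, fits the trait linear model, and collects the
#' coefficient estimates. Coefficient confidence intervals are equal-tailed
#' percentile intervals of those per-iteration estimates; a coefficient is
#' flagged significant when its interval excludes zero. When the
#' interaction is significant, the main effects are reported but flagged
#' not interpretable. Iterations in which any unit's refit failed are
#' skipped listwise so that every fitted model sees the complete design.
#'
#' @param boots A list of `rn_boot` objects, one per experimental unit, in
#'   the same order as `design` and all run with the same number of
#'   iterations.
#' @param design A [trait_design()] tibble aligned with `boots`.
#' @param trait `"t_opt"` or `"t_max"`.
#' @param level Confidence level (default 0.95).
#' @return A `trait_effects` object. `adjusted_r2` comes from the model on
#'   the point-estimate traits, not from the bootstrap.
#' @export
bootstrap_trait_inference <- function(boots, design,
                                      trait = c("t_opt", "t_max"),
                                      level = 0.95) {
  trait <- match.arg(trait)
  if (length(boots) != nrow(design)) {
    abort("`boots` and `design` must have one entry per unit.",
          class = "thermnorm_invalid_input")
  }
  n_iters <- vapply(boots, function(b) b$n_iter, integer(1))
  if (length(unique(n_iters)) != 1) {
    abort("all units must be bootstrapped with the same number of iterations.",
          class = "thermnorm_invalid_input")
  }
  n_iter <- n_iters[1]

  # units x iterations matrix of draws, NA where an iteration failed
  Y <- matrix(NA_real_, nrow = length(boots), ncol = n_iter)
  for (i in seq_along(boots)) {
    d <- boots[[i]]$draws
    Y[i, d$iteration] <- d[[trait]]
  }
  ok <- colSums(is.na(Y)) == 0
  n_skipped <- sum(!ok)
  if (sum(ok) < 20) {
    abort("fewer than 20 complete bootstrap iterations across all units.",
          class = "thermnorm_insufficient_data")
  }
  X <- trait_model_matrix(design)
  coef_draws <- qr.coef(qr(X), Y[, ok, drop = FALSE])  # 4 x n_ok
  rownames(coef_draws) <- colnames(X)

  point <- vapply(boots, function(b) b$point[[trait]], numeric(1))
  point_fit <- fit_trait_lm(design, point)

  terms <- colnames(X)
  ci <- t(apply(coef_draws, 1, trait_ci, level = level))
  coef_tbl <- tibble::tibble(
    term = terms,
    estimate = unname(point_fit$coefficients[terms]),
    ci_lo = ci[, 1],
    ci_hi = ci[, 2],
    significant = ci[, 1] > 0 | ci[, 2] < 0
  )
  out <- new_trait_effects(trait, coef_tbl, point_fit$adjusted_r2,
                           n_bootstrap = sum(ok), level = level,
                           n_skipped = n_skipped)
  out$coef_draws <- coef_draws
  out
}

#' Treatment-effect inference for the maximum growth rate
#'
#' The maximum growth rate trait is the highest *measured* rate per unit,
#' so no bootstrap distribution exists for it; the trait linear model is
#' fitted once and coefficient confidence intervals come from normal
#' theory (t distribution on the residual degrees of freedom). The same
#' CI-excludes-zero significance rule and interaction-precedence rule
#' apply.
#'
#' @param design A [trait_design()] tibble.
#' @param mu_max Numeric vector of observed maximum growth rates aligned
#'   with the design.
#' @param level Confidence level (default 0.95).
#' @return A `trait_effects` object.
#' @export
mu_max_inference <- function(design, mu_max, level = 0.95) {
  res <- fit_trait_lm(design, mu_max)
  ci <- confint(res$fit, level = level)
  coef_tbl <- tibble::tibble(
    term = c("intercept", "temp_effect", "pco2_effect", "interaction"),
    estimate = unname(res$coefficients),
    ci_lo = unname(ci[, 1]),
    ci_hi = unname(ci[, 2]),
    significant = ci[, 1] > 0 | ci[, 2] < 0
  )
  new_trait_effects("mu_max", coef_tbl, res$adjusted_r2,
                    n_bootstrap = 0L, level = level,
                    method = "normal-theory")
}

#' Treatment-cell trait means with confidence intervals
#'
#' Per (selection temperature x pCO2) cell: the mean trait across the
#' replicate populations. For T_opt and T_max the interval is a percentile
#' interval of the per-iteration cell means over the residual bootstraps;
#' for mu_max it is a normal-theory interval across the replicates.
#'
#' @param design A [trait_design()] tibble.
#' @param traits A tibble of point traits per unit (columns `t_opt`,
#'   `t_max`, `mu_max`) aligned with `design`.
#' @param boots List of `rn_boot` objects aligned with `design`.
#' @param level Confidence level (default 0.95).
#' @return A tidy tibble: `selection_temp`, `pco2`, `trait`, `mean`,
#'   `ci_lo`, `ci_hi`, `n`.
#' @export
summarize_traits_by_treatment <- function(design, traits, boots,
                                          level = 0.95) {
  stopifnot(nrow(design) == nrow(traits), length(boots) == nrow(design))
  cells <- dplyr::distinct(design[, c("selection_temp", "pco2")])
  cells <- dplyr::arrange(cells, .data$selection_temp, .data$pco2)
  out <- list()
  for (i in seq_len(nrow(cells))) {
    in_cell <- design$selection_temp == cells$selection_temp[i] &
      design$pco2 == cells$pco2[i]
    n <- sum(in_cell)
    if (n == 0) {
      abort(sprintf("empty treatment cell: %g °C x %g µatm",
                    cells$selection_temp[i], cells$pco2[i]),
            class = "thermnorm_invalid_input")
    }
    for (tr in c("t_opt", "t_max")) {
      cell_boots <- boots[in_cell]
      n_iter <- cell_boots[[1]]$n_iter
      Y <- matrix(NA_real_, nrow = n, ncol = n_iter)
      for (j in seq_along(cell_boots)) {
        d <- cell_boots[[j]]$draws
        Y[j, d$iteration] <- d[[tr]]
      }
      cell_means <- colMeans(Y)
      cell_means <- cell_means[!is.na(cell_means)]
      ci <- trait_ci(cell_means, level = level)
      out[[length(out) + 1]] <- tibble::tibble(
        selection_temp = cells$selection_temp[i], pco2 = cells$pco2[i],
        trait = tr, mean = mean(traits[[tr]][in_cell]),
        ci_lo = ci[1], ci_hi = ci[2], n = n)
    }
    mu <- traits$mu_max[in_cell]
    m <- mean(mu)
    if (n > 1) {
      half <- qt(1 - (1 - level) / 2, df = n - 1) * sd(mu) / sqrt(n)
    } else {
      half <- 0
    }
    out[[length(out) + 1]] <- tibble::tibble(
      selection_temp = cells$selection_temp[i], pco2 = cells$pco2[i],
      trait = "mu_max", mean = m, ci_lo = m - half, ci_hi = m + half, n = n)
  }
  dplyr::bind_rows(out)
}
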