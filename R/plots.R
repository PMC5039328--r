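#' Plot fitted reaction norms over the assay data
#'
#' Per-replicate fitted curves drawn over the growth-rate measurements,
#' panelled by selection temperature and coloured by pCO2 level.
#'
#' @param data A validated assay tibble.
#' @param fits Named list of `rn_fit` objects, one per replicate.
#' @param temp_range Temperature range for the curves, degrees C.
#' @return A ggplot object.
#' @export
plot_reaction_norms <- function(data, fits,
                                temp_range = range(data$assay_temp)) {
  grid <- seq(temp_range[1], temp_range[2], length.out = 200)
  meta <- dplyr::distinct(data[, c("replicate_id", "selection_temp", "pco2")])
  curves <- dplyr::bind_rows(lapply(names(fits), function(id) {
    tibble::tibble(replicate_id = id, assay_temp = grid,
                   growth_rate = eval_reaction_norm(fits[[id]]$params, grid))
  }))
  curves <- dplyr::left_join(curves, meta, by = "replicate_id")
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$assay_temp, y = .data$growth_rate,
                               group = .data$replicate_id,
                               colour = factor(.data$pco2))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(data = data, ggplot2::aes(group = .data$replicate_id),
                        size = 1, alpha = 0.6) +
    ggplot2::facet_wrap(~selection_temp,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Assay temperature (°C)",
                  y = "Growth rate (per day)", colour = "pCO2 (µatm)") +
    ggplot2::coord_cartesian(ylim = c(0, NA)) +
    ggplot2::theme_bw()
}

#' Plot standardized treatment-effect coefficients with intervals
#'
#' @param effects Named list of `trait_effects` objects (as produced by
#'   [run_full_pipeline()]).
#' @return A ggplot object.
#' @export
plot_trait_effects <- function(effects) {
  tb <- coefficients_table(effects)
  tb <- tb[tb$term != "intercept", ]
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lo,
                                          xmax = .data$ci_hi,
                                          colour = .data$significant)) +
    ggplot2::facet_wrap(~trait, scales = "free_x") +
    ggplot2::labs(x = "Standardized coefficient", y = NULL) +
    ggplot2::theme_bw()
}
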