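# Diagnostic plots. ggplot2 throughout; every result type gets an autoplot
# or plot_* companion.

#' Plot depletion series
#'
#' Concentration against time per ion, faceted by chamber.
#'
#' @param conc Long concentration tibble (`chamber_id`, `time_h`, `ion`,
#'   `conc_uM`).
#' @param chambers Optional subset of chamber ids.
#' @return A ggplot.
#' @export
plot_depletion <- function(conc, chambers = NULL) {
  if (!is.null(chambers)) conc <- conc[conc$chamber_id %in% chambers, ]
  ggplot2::ggplot(conc, ggplot2::aes(.data$time_h, .data$conc_uM,
                                     colour = .data$ion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~chamber_id, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration (µM)", colour = "ion") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_depletion Plot observed points and the fitted depletion
#'   (or rate) curve.
#' @param object An `mm_fit`.
#' @param ... Unused.
#' @method autoplot mm_fit
#' @export
autoplot.mm_fit <- function(object, ...) {
  if (object$method == "depletion") {
    grid <- tibble(time_h = seq(min(object$data$time_h),
                                max(object$data$time_h), length.out = 200))
    grid$fit <- predict(object, grid)
    ggplot2::ggplot(object$data, ggplot2::aes(.data$time_h, .data$conc_uM)) +
      ggplot2::geom_point() +
      ggplot2::geom_line(data = grid, ggplot2::aes(.data$time_h, .data$fit),
                         colour = "steelblue") +
      ggplot2::labs(x = "time (h)", y = "concentration (µM)") +
      ggplot2::theme_minimal()
  } else {
    grid <- tibble(conc_uM = seq(0, max(object$data$conc_uM), length.out = 200))
    grid$fit <- predict(object, grid)
    ggplot2::ggplot(object$data, ggplot2::aes(.data$conc_uM, .data$rate)) +
      ggplot2::geom_point() +
      ggplot2::geom_line(data = grid, ggplot2::aes(.data$conc_uM, .data$fit),
                         colour = "steelblue") +
      ggplot2::labs(x = "concentration (µM)",
                    y = "specific uptake rate (µmol cm⁻¹ h⁻¹)") +
      ggplot2::theme_minimal()
  }
}

#' Correlation heat map
#'
#' @param object A `trait_cor` from [correlation_matrix()].
#' @param ... Unused.
#' @return A ggplot tile map of pairwise correlations.
#' @method autoplot trait_cor
#' @export
autoplot.trait_cor <- function(object, ...) {
  both <- bind_rows(
    as_tibble(object),
    as_tibble(object) %>% rename(trait_a = "trait_b", trait_b = "trait_a")
  )
  ggplot2::ggplot(both, ggplot2::aes(.data$trait_a, .data$trait_b,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname pca_summary
#' @param object A `pca_summary`.
#' @method autoplot pca_summary
#' @export
autoplot.pca_summary <- function(object, ...) {
  sc <- object$scores
  ve <- object$variance$prop_variance
  ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ve[2])) +
    ggplot2::theme_minimal()
}
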