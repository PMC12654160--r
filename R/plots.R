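# ggplot2 autoplot methods for the main result types.

#' @export
autoplot.soilpem_duncan <- function(object, ...) {
  d <- object$groups
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$group, levels = .data$group),
                                  y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(y = .data$mean + .data$se,
                                    label = .data$letter), vjust = -0.6) +
    ggplot2::labs(x = NULL, y = "mean ± SE",
                  subtitle = sprintf("Duncan letters, alpha = %g", object$alpha)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.soilpem_vector_summary <- function(object, ...) {
  d <- object$per_sample
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length, y = .data$angle,
                                  colour = .data$treatment)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm",
                         formula = y ~ x, se = FALSE, colour = "grey40",
                         linewidth = 0.5) +
    ggplot2::geom_hline(yintercept = 45, linetype = "dashed") +
    ggplot2::labs(x = "vector length (C limitation)",
                  y = "vector angle (°; >45 P-, <45 N-limited)") +
    ggplot2::theme_minimal()
}

#' Plot an NMDS ordination, optionally coloured by treatment
#'
#' @param object a [nmds()] result
#' @param metadata optional [sample_metadata()] for colouring
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.soilpem_nmds <- function(object, metadata = NULL, ...) {
  d <- object$coordinates
  if (!is.null(metadata)) d <- left_join(d, metadata, by = "sample_id")
  aes <- if (!is.null(metadata)) {
    ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2, colour = .data$treatment)
  } else {
    ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(subtitle = sprintf("stress = %.3f", object$stress)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.soilpem_panel <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$col, y = .data$row,
                                       fill = .data$coefficient)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Zi-Pi plot of node topological roles
#'
#' @param object a `soilpem_network` with modules assigned
#' @param ... unused
#' @return a ggplot with the Zi = 2.5 and Pi = 0.62 threshold lines
#' @export
autoplot.soilpem_network <- function(object, ...) {
  d <- zi_pi(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pi, y = .data$zi,
                                  colour = .data$role, shape = .data$domain)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 2.5, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0.62, linetype = "dashed") +
    ggplot2::labs(x = "among-module connectivity (Pi)",
                  y = "within-module degree (Zi)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.soilpem_rf <- function(object, ...) {
  d <- mutate(object, predictor = factor(.data$predictor,
                                         levels = rev(.data$predictor)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$inc_mse, y = .data$predictor)) +
    ggplot2::geom_col(fill = "darkolivegreen4") +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), hjust = -0.3) +
    ggplot2::labs(x = "%IncMSE", y = NULL) +
    ggplot2::theme_minimal()
}
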