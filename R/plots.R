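#' Tile plot of delta-log2E across variants and targets
#'
#' @param tbl Enrichment tibble with `delta_log2E`.
#' @return A ggplot.
#' @export
plot_enrichment_tiles <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$target, y = .data$variant,
                                    fill = .data$delta_log2E)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Δlog2E") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Dose-response curve with data points
#'
#' @param object An [fit_ll3()] object.
#' @param ... Unused.
#' @return A ggplot on a log10 dose axis.
#' @export
autoplot.ll3_fit <- function(object, ...) {
  if (!object$converged) abort("cannot plot an unconverged fit")
  cf <- object$coefficients
  data <- object$data
  y <- if (".response_used" %in% names(data)) data$.response_used else
    data$response
  grid <- tibble(dose = exp(seq(log(min(data$dose)), log(max(data$dose)),
                                length.out = 200)))
  grid <- mutate(grid,
                 response = ll3_curve(.data$dose, cf["b"], cf["c"],
                                      cf["d"], cf["e"]))
  ggplot2::ggplot(mutate(data, .y = y),
                  ggplot2::aes(x = .data$dose, y = .data$.y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$response), colour = "#2166ac") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose [M]",
                  y = if (object$mode == "EC") "response (%)" else
                    "response") +
    ggplot2::theme_minimal()
}

#' Bar chart of bond counts per class
#'
#' @param summary Output of [summarize_bonds()].
#' @return A ggplot.
#' @export
plot_bond_counts <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::labs(x = "bond class", y = "residue-pair interactions") +
    ggplot2::theme_minimal()
}

#' Stacked bar chart of binding-site occlusion
#'
#' @param occ Occlusion tibble (rows from [occlusion()] bound together,
#'   optionally with an identifying `label` column).
#' @return A ggplot with blocked and unblocked site-residue counts stacked.
#' @export
plot_occlusion <- function(occ) {
  occ <- as_tibble(occ)
  if (!"label" %in% names(occ)) {
    occ <- mutate(occ, label = paste0("complex_", row_number()))
  }
  long <- tidyr::pivot_longer(
    mutate(occ, unblocked = .data$total - .data$blocked),
    cols = c("blocked", "unblocked"),
    names_to = "state", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$n,
                                     fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(blocked = "#b2182b",
                                          unblocked = "#d9d9d9")) +
    ggplot2::labs(x = NULL, y = "binding-site residues", fill = NULL) +
    ggplot2::theme_minimal()
}
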