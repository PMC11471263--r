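#' Plot a contact matrix as a heatmap
#'
#' @param object A `contact_matrix`.
#' @param what `"contact"` (binary map) or `"distance"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contact_matrix <- function(object, what = c("contact", "distance"), ...) {
  what <- match.arg(what)
  d <- tidy(object)
  d$label_a <- factor(d$label_a, levels = object$row_labels)
  d$label_b <- factor(d$label_b, levels = object$col_labels)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$label_b, y = .data$label_a))
  if (what == "contact") {
    p <- p + ggplot2::geom_tile(ggplot2::aes(fill = .data$contact)) +
      ggplot2::scale_fill_manual(values = c(`TRUE` = "grey15", `FALSE` = "white"),
                                 na.value = "grey80", name = "contact")
  } else {
    p <- p + ggplot2::geom_tile(ggplot2::aes(fill = .data$distance)) +
      ggplot2::scale_fill_viridis_c(name = "CA-CA (A)", direction = -1)
  }
  p + ggplot2::labs(x = "CL position (IMGT-style)", y = "CH1 position (IMGT-style)") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text = ggplot2::element_text(size = 5))
}

#' Volcano-style plot of an isotype-sensitivity result
#'
#' Signed per-position effect against the BH-adjusted significance, the
#' standard way to spot isotype-sensitive hot spots.
#'
#' @param object A `sensitivity_result`.
#' @param q_cutoff Highlight positions with `q_value` below this
#'   (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sensitivity_result <- function(object, q_cutoff = 0.05, ...) {
  d <- as_tibble(object)
  d$significant <- d$q_value < q_cutoff
  ggplot2::ggplot(d, ggplot2::aes(x = .data$effect, y = -log10(.data$q_value))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 1.4) +
    ggplot2::geom_hline(yintercept = -log10(q_cutoff), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey55"),
                                 name = sprintf("q < %.2g", q_cutoff)) +
    ggplot2::labs(x = "effect (signed log2 fold difference; negative = first isotype favourable)",
                  y = "-log10(q)") +
    ggplot2::theme_minimal()
}

#' Per-residue buried-surface profile of an H-L interface
#'
#' @param object An `hl_interface`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hl_interface <- function(object, ...) {
  d <- object$per_residue
  ggplot2::ggplot(d, ggplot2::aes(x = .data$seqres_index, y = .data$delta_sasa,
                                  fill = .data$interface)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~chain_id, ncol = 1, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue", `FALSE` = "grey70"),
                               name = "interface") +
    ggplot2::labs(x = "residue", y = expression(Delta*SASA~(ring(A)^2)) ) +
    ggplot2::theme_minimal()
}
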