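# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.dcm_landscape <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$n_nat, y = .data$n_hb,
                               fill = .data$free_energy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "G (kcal/mol)") +
    ggplot2::labs(x = "native torsions N_nat", y = "hydrogen bonds N_hb",
                  title = sprintf("free-energy landscape, T = %.1f K",
                                  object$temperature)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dcm_cp <- function(object, ...) {
  ggplot2::ggplot(object$cp, ggplot2::aes(x = .data$T_K, y = .data$cp)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$tm, linetype = "dashed") +
    ggplot2::labs(x = "T (K)", y = "Cp (kcal/(mol K))",
                  title = sprintf("heat capacity, Tm = %.1f K", object$tm)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dcm_qsfr <- function(object, level = c("auto", "residue", "bond"),
                              ...) {
  level <- match.arg(level)
  if (level == "auto") {
    level <- if (!is.null(object$fi_residue)) "residue" else "bond"
  }
  if (level == "residue") {
    ggplot2::ggplot(object$fi_residue,
                    ggplot2::aes(x = .data$residue_index, y = .data$fi)) +
      ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
      ggplot2::geom_line() +
      ggplot2::labs(x = "residue", y = "flexibility index",
                    title = "FI profile (positive = flexible)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$fi_bond,
                    ggplot2::aes(x = .data$bond_id, y = .data$fi)) +
      ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
      ggplot2::geom_col() +
      ggplot2::labs(x = "rotatable bond", y = "flexibility index") +
      ggplot2::theme_minimal()
  }
}

#' Plot a cooperativity-correlation (or delta-CC) matrix
#'
#' Red marks correlated flexibility, blue co-rigidity, white no coupling.
#'
#' @param cc Square matrix.
#' @param limit Colour saturation limit.
#' @return A ggplot object.
#' @export
plot_cc_matrix <- function(cc, limit = 1) {
  df <- tidyr::expand_grid(i = seq_len(nrow(cc)), j = seq_len(ncol(cc)))
  df$value <- as.vector(cc[cbind(df$i, df$j)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-limit, limit),
                                  oob = scales_squish) +
    ggplot2::labs(x = "residue", y = "residue", fill = "CC") +
    ggplot2::theme_minimal()
}

# minimal squish (avoids a scales dependency)
scales_squish <- function(x, range = c(-1, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' Plot a five-bin response histogram next to the Gaussian null
#'
#' @param bins Factor from [classify_bins()] (or named counts).
#' @return A ggplot object.
#' @export
plot_response_histogram <- function(bins) {
  counts <- if (is.factor(bins)) table(bins) else bins
  df <- tibble::tibble(
    bin = factor(rep(.BIN_LEVELS, 2), levels = .BIN_LEVELS),
    source = rep(c("observed", "null"), each = 5),
    fraction = c(as.numeric(counts) / sum(counts), null_expectation()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$fraction,
                                   fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(observed = "#d95f02",
                                          null = "grey60")) +
    ggplot2::labs(x = NULL, y = "fraction of positions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
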