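#' Plot the cascade stage attrition
#'
#' Bar chart of the number of variants removed at each cascade stage plus
#' the survivors, in pipeline order.
#'
#' @param object A `cascade_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cascade_result
#' @export
autoplot.cascade_result <- function(object, ...) {
  s <- object$summary[object$summary$stage != "input", ]
  s$stage <- factor(s$stage, levels = s$stage)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$stage, y = .data$n_variants)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "variants",
                  title = "Family cascade: variants per removal stage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a burden scan
#'
#' -log10 association p-value per gene (and category), with the Bonferroni
#' significance threshold drawn as a dashed line.
#'
#' @param object A `burden_scan` from [run_burden()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot burden_scan
#' @export
autoplot.burden_scan <- function(object, ...) {
  thr <- attr(object, "threshold")
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$p_value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = -log10(.data$p_value),
                                   fill = .data$category)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ p),
                  title = "Rare-variant burden (SKAT-O)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
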