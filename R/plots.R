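#' Manhattan plot of an association scan
#'
#' @param results a `gwas_result` from [glm_scan()].
#' @param threshold significance line (default `1e-3`).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, threshold = 1e-3) {
  md <- manhattan_data(results)
  ggplot2::ggplot(md, ggplot2::aes(x = .data$coord, y = .data$neg_log10_p,
                                   colour = factor(.data$parity))) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c("grey35", "steelblue")) +
    ggplot2::labs(x = "genome position", y = expression(-log[10](p)),
                  title = attr(results, "trait")) +
    ggplot2::theme_minimal()
}

#' QQ plot of an association scan
#'
#' @inheritParams plot_manhattan
#' @return A ggplot object.
#' @export
plot_qq <- function(results) {
  qd <- qq_data(results)
  ggplot2::ggplot(qd, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_point(size = 0.8, colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "red") +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' LD decay curve plot
#'
#' @param decay a tibble from [ld_decay()].
#' @return A ggplot object.
#' @export
plot_ld_decay <- function(decay) {
  ggplot2::ggplot(decay, ggplot2::aes(x = .data$midpoint / 1000,
                                      y = .data$mean_r2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot geno_pca
autoplot.geno_pca <- function(object, ...) {
  lab <- sprintf("PC%d (%.2f%%)", 1:2, object$explained[1:2])
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot trait_pca
autoplot.trait_pca <- function(object, ...) {
  lab <- sprintf("PC%d (%.2f%%)", 1:2, object$explained[1:2])
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot evanno
autoplot.evanno <- function(object, ...) {
  ggplot2::ggplot(object[!is.na(object$delta_K), ],
                  ggplot2::aes(x = .data$K, y = .data$delta_K)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(y = expression(Delta * K)) +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
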