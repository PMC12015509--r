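# Plotting helpers (ggplot2, suggested dependency).

#' Plot a reduced latent landscape
#'
#' Scatter of the first two PCA scores, colored by the ground-truth
#' conformational coordinate when available.
#'
#' @param table A `latent_table` from [embed_dataset()].
#' @param pca Result of [pca_reduce()] (computed from `table` if NULL).
#' @return A ggplot object.
#' @export
plot_landscape <- function(table, pca = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  if (is.null(pca)) pca <- pca_reduce(table, k = 2)
  df <- data.frame(pc1 = pca$scores[, 1], pc2 = pca$scores[, 2])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2))
  if ("t" %in% names(table)) {
    df$t <- table$t
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                          color = .data$t))
  }
  p + ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::labs(x = "PC 1", y = "PC 2", color = "t") +
    ggplot2::theme_minimal()
}

#' Plot per-term training losses
#'
#' @param log Training log data.frame from [train()].
#' @param terms Which loss columns to show.
#' @return A ggplot object.
#' @export
plot_loss <- function(log, terms = c("data", "total")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  terms <- intersect(terms, names(log))
  df <- do.call(rbind, lapply(terms, function(tm)
    data.frame(step = log$step, term = tm, value = log[[tm]])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value,
                                   color = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "step", y = "loss") +
    ggplot2::theme_minimal()
}
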