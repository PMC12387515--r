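#' Scatter plot of the embedding with cluster confidence ellipses
#'
#' Mirrors the standard presentation of a clustered 2-D embedding: points
#' coloured by cluster, sized by fatigue severity, with a 95% confidence
#' ellipse per cluster. Purely presentational; nothing downstream depends
#' on it.
#'
#' @param coords n x 2 embedding coordinates.
#' @param assignments Cluster labels.
#' @param fss Fatigue scores used for point size (optional).
#' @param file Output file (png/svg/pdf inferred from the extension).
#' @param level Ellipse coverage level.
#' @return The file path, invisibly.
#' @export
plot_embedding_clusters <- function(coords, assignments, fss = NULL,
                                    file, level = 0.95) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
  df <- data.frame(
    tsne1 = coords[, 1], tsne2 = coords[, 2],
    cluster = factor(assignments),
    fss = if (is.null(fss)) 1 else fss
  )
  ell <- do.call(rbind, lapply(levels(df$cluster), function(cl) {
    pts <- as.matrix(df[df$cluster == cl, c("tsne1", "tsne2")])
    if (nrow(pts) < 3) {
      return(NULL)
    }
    path <- ellipse_path(confidence_ellipse(pts, level))
    data.frame(tsne1 = path[, 1], tsne2 = path[, 2], cluster = cl)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$tsne1, y = .data$tsne2, colour = .data$cluster
  )) +
    ggplot2::geom_point(ggplot2::aes(size = .data$fss), alpha = 0.8) +
    ggplot2::geom_path(
      data = ell,
      ggplot2::aes(group = .data$cluster), linewidth = 0.4
    ) +
    ggplot2::scale_size_continuous(range = c(1, 4), name = "FSS") +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = "Cluster") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file, p, width = 6, height = 5, dpi = 150)
  invisible(file)
}

#' Line plot of mean silhouette versus sample size
#'
#' One line per k, with a ribbon spanning the 5th-95th percentile of the
#' per-rep silhouettes.
#'
#' @param grid A [run_grid()] result.
#' @param file Output file.
#' @return The file path, invisibly.
#' @export
plot_samplesize_grid <- function(grid, file) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
  df <- as.data.frame(grid)
  df$k <- factor(df$k)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$n, y = .data$mean, colour = .data$k, fill = .data$k
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$q05, ymax = .data$q95),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "sample size", y = "mean silhouette", colour = "k", fill = "k"
    ) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file, p, width = 6, height = 4, dpi = 150)
  invisible(file)
}
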