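#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Compositional biplot of a PCA fit
#'
#' Scores as points, clr-variable rays as arrows (covariance scaling by
#' default), on the first two components.
#'
#' @param object a [coda_pca()] fit.
#' @param kind biplot scaling, see [biplot_elements()].
#' @param ray_scale visual stretch applied to rays only.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.coda_pca <- function(object, kind = "covariance", ray_scale = 1, ...) {
  be <- biplot_elements(object, kind)
  sc <- tibble::as_tibble(be$scores, rownames = "site_id")
  names(sc)[2:3] <- c("pc1", "pc2")
  ev <- round(100 * object$explained_variance[1:2], 1)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey85") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey85") +
    ggplot2::geom_point(colour = "grey40", alpha = 0.7) +
    ggplot2::geom_segment(data = be$rays,
                          ggplot2::aes(x = 0, y = 0, xend = ray_scale * .data$pc1,
                                       yend = ray_scale * .data$pc2),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "firebrick") +
    ggplot2::geom_text(data = be$rays,
                       ggplot2::aes(x = ray_scale * .data$pc1 * 1.07,
                                    y = ray_scale * .data$pc2 * 1.07,
                                    label = .data$part),
                       colour = "firebrick", size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ev[1]),
                  y = sprintf("PC2 (%.1f%%)", ev[2]),
                  title = "Compositional biplot") +
    ggplot2::theme_minimal()
}

#' Ordination scatter of a PCoA
#'
#' @param object a [coda_pcoa()] fit.
#' @param labels optional vector (e.g. cluster labels) colouring points.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.coda_pcoa <- function(object, labels = NULL, ...) {
  df <- tibble::as_tibble(object$coordinates[, 1:2, drop = FALSE],
                          rownames = "site_id")
  names(df)[2:3] <- c("pco1", "pco2")
  rel <- 100 * object$eigenvalues / sum(object$eigenvalues)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pco1, y = .data$pco2))
  if (!is.null(labels)) {
    df$label <- factor(labels)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pco1, y = .data$pco2,
                                          colour = .data$label))
  }
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", rel[1]),
                  y = sprintf("PCo2 (%.1f%%)", rel[2]),
                  colour = "cluster",
                  title = "Principal coordinates (Aitchison distance)") +
    ggplot2::theme_minimal()
}

#' Membership profile of a fuzzy clustering
#'
#' Stacked membership bars per site, ordered by hard label.
#'
#' @param object a [coda_fcm()] fit.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.coda_fcm <- function(object, ...) {
  df <- tidy.coda_fcm(object)
  ord <- names(sort(object$hard_labels))
  df$site_id <- factor(df$site_id, levels = unique(ord))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site_id, y = .data$membership,
                                   fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "membership", title = "Fuzzy c-means memberships") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Ternary diagram of a 3-part (sub)composition
#'
#' Plots closed 3-part compositions in the reference triangle; pass
#' centered data (see [center_composition()]) to avoid the collapse of
#' dominated raw compositions onto a vertex.
#'
#' @param x 3-part composition matrix/tibble (rows).
#' @param labels optional point colouring (e.g. cluster labels).
#' @param highlight optional logical vector; `TRUE` points are circled
#'   (e.g. sites whose hazard index exceeds 1).
#' @return a ggplot.
#' @export
plot_ternary <- function(x, labels = NULL, highlight = NULL) {
  m <- closure(as_comp_matrix(x))
  uv <- ternary_coords(m)
  if (!"site_id" %in% names(uv)) uv$site_id <- as.character(seq_len(nrow(m)))
  if (!is.null(labels)) uv$label <- factor(labels)
  tri <- tibble::tibble(u = c(0, 1, 0.5, 0), v = c(0, 0, sqrt(3) / 2, 0))
  vert <- tibble::tibble(u = c(0, 1, 0.5), v = c(0, 0, sqrt(3) / 2),
                         part = colnames(m))
  p <- ggplot2::ggplot(uv, ggplot2::aes(x = .data$u, y = .data$v)) +
    ggplot2::geom_path(data = tri, colour = "grey30") +
    ggplot2::geom_text(data = vert, ggplot2::aes(label = .data$part),
                       nudge_y = c(-0.04, -0.04, 0.04), size = 3.5)
  p <- if (is.null(labels)) {
    p + ggplot2::geom_point(alpha = 0.8, colour = "grey40")
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.8)
  }
  if (!is.null(highlight) && any(highlight)) {
    p <- p + ggplot2::geom_point(data = uv[highlight, , drop = FALSE],
                                 shape = 21, size = 4, stroke = 0.9,
                                 colour = "goldenrod")
  }
  p + ggplot2::coord_equal() + ggplot2::theme_void() +
    ggplot2::labs(colour = "cluster")
}
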