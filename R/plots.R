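#' Plot a fitted cumulative germination curve
#'
#' Draws the NPMLE cumulative germination probability as a step function.
#' Within each Turnbull support interval the curve is not identified; those
#' regions are shaded, in the manner of the uncertainty bands customary for
#' interval-censored germination curves.
#'
#' @param object An [fit_npmle()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot npmle_fit
#' @export
autoplot.npmle_fit <- function(object, ...) {
  tb <- object$intervals %>% filter(is.finite(.data$right))
  cum0 <- c(0, head(tb$cdf, -1))
  steps <- tibble(t = c(0, tb$right), cdf = c(0, tb$cdf))
  rects <- tb %>%
    mutate(ymin = cum0, ymax = .data$cdf) %>%
    filter(.data$mass > 0)
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = rects,
      ggplot2::aes(xmin = .data$left, xmax = .data$right,
                   ymin = .data$ymin, ymax = .data$ymax),
      fill = "grey70", alpha = 0.5
    ) +
    ggplot2::geom_step(data = steps,
                       ggplot2::aes(x = .data$t, y = .data$cdf)) +
    ggplot2::labs(x = "Days after sowing",
                  y = "Cumulative germination probability") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Score plot for an STI principal component analysis
#'
#' @param object An [pca_sti()] object.
#' @param components Which two components to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sti_pca
#' @export
autoplot.sti_pca <- function(object, components = c(1, 2), ...) {
  pcs <- paste0("PC", components)
  ve <- round(100 * object$var_explained[components], 1)
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]])) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = paste0(pcs[1], " (", ve[1], "%)"),
                  y = paste0(pcs[2], " (", ve[2], "%)")) +
    ggplot2::theme_minimal()
}

#' Cluster plot for a hierarchical k-means fit
#'
#' Projects the (standardized) clustering features onto their first two
#' principal components and colors points by cluster.
#'
#' @param object A [hkmeans()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot germ_hkmeans
#' @export
autoplot.germ_hkmeans <- function(object, ...) {
  pc <- prcomp(object$features)
  ve <- round(100 * pc$sdev[1:2]^2 / sum(pc$sdev^2), 1)
  df <- tibble(
    PC1 = pc$x[, 1], PC2 = pc$x[, 2],
    cluster = factor(object$clusters$cluster)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$cluster)) +
    ggplot2::geom_point() +
    ggplot2::stat_ellipse(level = 0.9, linetype = 2, na.rm = TRUE) +
    ggplot2::labs(x = paste0("PC1 (", ve[1], "%)"),
                  y = paste0("PC2 (", ve[2], "%)"), colour = "Cluster") +
    ggplot2::theme_minimal()
}
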