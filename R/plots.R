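#' Cluster signature heatmap
#'
#' Clusters x markers heatmap of scaled mean expression, diverging colormap
#' centred at 0.
#'
#' @param signatures matrix from [cluster_signatures()].
#' @param path output file (PNG); `NULL` draws to the active device.
#' @param annotation optional named vector mapping cluster id to display
#'   name.
#' @return `path` (or the pheatmap object when `path` is `NULL`),
#'   invisibly.
#' @export
plot_signature_heatmap <- function(signatures, path = NULL,
                                   annotation = NULL) {
  m <- signatures
  if (!is.null(annotation)) {
    hit <- rownames(m) %in% names(annotation)
    rownames(m)[hit] <- annotation[rownames(m)[hit]]
  }
  lim <- max(abs(m), 1e-9)
  cols <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  brk <- seq(-lim, lim, length.out = 102)
  ph <- pheatmap::pheatmap(m, color = cols, breaks = brk,
                           cluster_rows = nrow(m) > 1,
                           cluster_cols = ncol(m) > 1,
                           silent = TRUE)
  if (is.null(path)) return(invisible(ph))
  grDevices::png(path, width = 1400, height = 200 + 60 * nrow(m), res = 150)
  grid::grid.newpage()
  grid::grid.draw(ph$gtable)
  grDevices::dev.off()
  invisible(path)
}

#' PDR heatmap
#'
#' Symmetric phenotype x phenotype heatmap of the pairwise distance rank;
#' colormap runs yellow (0, closest pair) to black (1, furthest pair);
#' missing entries are grey.
#'
#' @param pdr_mat matrix from [pdr()].
#' @param path output PNG path; `NULL` draws to the active device.
#' @return `path` (or the pheatmap object), invisibly.
#' @export
plot_pdr_heatmap <- function(pdr_mat, path = NULL) {
  cols <- grDevices::colorRampPalette(c("#FFFF00", "#000000"))(101)
  m <- pdr_mat
  diag(m) <- NA
  ph <- pheatmap::pheatmap(m, color = cols, breaks = seq(0, 1, length.out = 102),
                           na_col = "#BBBBBB",
                           cluster_rows = nrow(m) > 2, cluster_cols = ncol(m) > 2,
                           silent = TRUE)
  if (is.null(path)) return(invisible(ph))
  grDevices::png(path, width = 1000, height = 900, res = 150)
  grid::grid.newpage()
  grid::grid.draw(ph$gtable)
  grDevices::dev.off()
  invisible(path)
}

#' PDR feature-map figure
#'
#' Scatter of the 2-D embedding from [pdr_feature_map()]: node size =
#' phenotype frequency, node colour = row-mean PDR, edge opacity =
#' `1 - PDR`.
#'
#' @param fmap list from [pdr_feature_map()].
#' @param path output PNG path; `NULL` returns the ggplot object.
#' @return `path` or the plot object, invisibly.
#' @export
plot_feature_map <- function(fmap, path = NULL) {
  nodes <- fmap$nodes
  ed <- fmap$edges
  seg <- merge(merge(ed, stats::setNames(nodes[, c("phenotype", "x", "y")],
                                         c("a", "xa", "ya")), by = "a"),
               stats::setNames(nodes[, c("phenotype", "x", "y")],
                               c("b", "xb", "yb")), by = "b")
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb,
                                       alpha = .data$weight),
                          linewidth = 0.8, colour = "grey30") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$size,
                                     colour = .data$mean_pdr)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$phenotype),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_colour_gradient(low = "#FFD700", high = "#1A1A1A",
                                   limits = c(0, 1)) +
    ggplot2::scale_size_area(max_size = 14) +
    ggplot2::scale_alpha(range = c(0.05, 0.9)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, colour = "mean PDR",
                  size = "frequency", alpha = "1 - PDR")
  if (is.null(path)) return(invisible(p))
  grDevices::png(path, width = 1200, height = 1000, res = 150)
  print(p)
  grDevices::dev.off()
  invisible(path)
}

#' Render an interaction-zone image
#'
#' Rasterises the per-cell RGB triples of one ROI: every cell is drawn as a
#' disk of its area in its RGB zone colour on black background, written as
#' PNG.
#'
#' @param zones data.frame from [interaction_zones()] (one ROI).
#' @param cells matching cell table rows (for `area_um2`).
#' @param path output PNG path.
#' @param pixel_size micrometres per pixel.
#' @return `path` invisibly.
#' @export
plot_zone_image <- function(zones, cells, path, pixel_size = 1) {
  cells <- as.data.frame(cells)
  radius <- sqrt(cells$area_um2 / pi)
  W <- as.integer(ceiling(max(zones$x_um + radius) / pixel_size))
  H <- as.integer(ceiling(max(zones$y_um + radius) / pixel_size))
  img <- array(0, dim = c(H, W, 3))
  for (i in seq_len(nrow(zones))) {
    r_px <- radius[i] / pixel_size
    cx <- zones$x_um[i] / pixel_size
    cy <- zones$y_um[i] / pixel_size
    cols <- max(1L, floor(cx - r_px) + 1L):min(W, ceiling(cx + r_px) + 1L)
    rows <- max(1L, floor(cy - r_px) + 1L):min(H, ceiling(cy + r_px) + 1L)
    for (rr in rows) {
      dy <- (rr - 1) - cy
      dx <- (cols - 1) - cx
      hit <- cols[dx * dx + dy * dy <= r_px * r_px]
      if (length(hit)) {
        img[rr, hit, 1] <- zones$R[i]
        img[rr, hit, 2] <- zones$G[i]
        img[rr, hit, 3] <- zones$B[i]
      }
    }
  }
  png::writePNG(img, path)
  invisible(path)
}
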