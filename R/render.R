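#' Render a cell table as a segmentation label mask and channel stack
#'
#' Draws every cell as a disk of its declared area centred at its centroid;
#' a pixel belongs to a cell when the pixel centre lies within the disk
#' radius. Later cells overwrite earlier ones at overlapping pixels. The
#' channel stack holds, at each labelled pixel, the owning cell's marker
#' vector plus optional zero-mean Gaussian pixel noise (truncated at zero).
#' Background is label 0. Pixel (1,1) of the returned matrices has its
#' centre at (0, 0) micrometres; x runs along columns, y along rows.
#'
#' @param cells a cell table (needs `x_um`, `y_um`, `area_um2` and marker
#'   columns).
#' @param panel a [marker_panel()] naming the channel columns and order.
#' @param pixel_size micrometres per pixel (> 0); IMC ablates at 1 um.
#' @param width_um,height_um image extent; defaults to covering all cells.
#' @param noise_sd pixel noise standard deviation (0 = none).
#' @param seed seed for the pixel noise stream.
#' @return list with `mask` (integer matrix, rows = y, cols = x) and
#'   `stack` (array height x width x markers).
#' @export
render_mask <- function(cells, panel, pixel_size = 1,
                        width_um = NULL, height_um = NULL,
                        noise_sd = 0, seed = 1L) {
  if (pixel_size <= 0) stop_fmt("pixel_size must be positive")
  cells <- as.data.frame(cells)
  markers <- panel$marker
  radius <- sqrt(cells$area_um2 / pi)
  width_um <- width_um %||% max(cells$x_um + radius)
  height_um <- height_um %||% max(cells$y_um + radius)
  W <- max(1L, as.integer(ceiling(width_um / pixel_size)))
  H <- max(1L, as.integer(ceiling(height_um / pixel_size)))
  mask <- matrix(0L, H, W)
  n <- nrow(cells)
  for (i in seq_len(n)) {
    r_px <- radius[i] / pixel_size
    cx <- cells$x_um[i] / pixel_size  # in pixel units; pixel centre j-1
    cy <- cells$y_um[i] / pixel_size
    cols <- max(1L, floor(cx - r_px) + 1L):min(W, ceiling(cx + r_px) + 1L)
    rows <- max(1L, floor(cy - r_px) + 1L):min(H, ceiling(cy + r_px) + 1L)
    for (rr in rows) {
      dy <- (rr - 1) - cy
      dx <- (cols - 1) - cx
      hit <- cols[dx * dx + dy * dy <= r_px * r_px]
      if (length(hit)) mask[rr, hit] <- i
    }
  }
  stack <- array(0, dim = c(H, W, length(markers)))
  lab_px <- which(mask > 0)
  if (length(lab_px)) {
    owner <- mask[lab_px]
    set.seed(derive_seed(seed, stage = 201L))
    for (m in seq_along(markers)) {
      v <- cells[[markers[m]]][owner]
      if (noise_sd > 0) v <- pmax(v + stats::rnorm(length(v), 0, noise_sd), 0)
      plane <- stack[, , m]
      plane[lab_px] <- v
      stack[, , m] <- plane
    }
  }
  dimnames(stack) <- list(NULL, NULL, markers)
  list(mask = mask, stack = stack)
}

#' Read and write label masks and channel stacks as TIFF
#'
#' Masks are written as single-page 16-bit unsigned TIFF (labels up to
#' 65535); stacks as multi-page 32-bit float TIFF, one page per marker in
#' panel order.
#'
#' @param mask integer label matrix.
#' @param stack numeric array height x width x channels.
#' @param path file path.
#' @return readers return the matrix/array; writers return `path`
#'   invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  if (max(mask) > 65535L) stop_fmt("more than 65535 labels; 16-bit overflow")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
}

#' @rdname write_mask_tiff
#' @param scale fixed power-of-two factor dividing intensities before the
#'   float32 write (the TIFF stores values in `[0, 1]`); division and
#'   re-multiplication by a power of two are exact in binary floating
#'   point, so the round trip loses only float32 precision. The same scale
#'   must be passed to the reader.
#' @export
write_stack_tiff <- function(stack, path, scale = 4096) {
  if (max(stack) > scale) {
    stop_fmt("stack intensities exceed scale %g; pass a larger power of two",
             scale)
  }
  pages <- lapply(seq_len(dim(stack)[3]), function(m) stack[, , m] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE,
                  compression = "none")
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_stack_tiff <- function(path, scale = 4096) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (m in seq_along(pages)) out[, , m] <- pages[[m]] * scale
  out
}
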