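#' Write and read the per-cell feature table as CSV
#'
#' The cell table is the pipeline's universal currency: one row per
#' segmented cell with ROI id, condition, centroid in micrometres, area,
#' per-marker mean intensities, and optional phenotype columns. CSV dialect:
#' comma separator, UTF-8, '.' decimal point.
#'
#' @param cells a cell table (`data.frame`/`data.table`).
#' @param path file path.
#' @return `read_cell_table` returns a validated `data.table`;
#'   `write_cell_table` returns `path` invisibly.
#' @export
write_cell_table <- function(cells, path) {
  data.table::fwrite(data.table::as.data.table(cells), path)
  invisible(path)
}

#' @rdname write_cell_table
#' @param panel a [marker_panel()]; required columns are checked against it.
#' @export
read_cell_table <- function(path, panel) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  dt <- data.table::fread(path)
  required <- c("cell_id", "roi_id", "condition", "x_um", "y_um", "area_um2",
                panel$marker)
  missing <- setdiff(required, names(dt))
  if (length(missing)) {
    stop_fmt("cell table %s lacks required column(s): %s", path,
             paste(missing, collapse = ", "))
  }
  # an all-NA integer column (e.g. parent_id with no attractions) is read
  # back as logical; restore the integer type
  for (cn in names(dt)) {
    if (is.logical(dt[[cn]]) && all(is.na(dt[[cn]]))) {
      data.table::set(dt, j = cn, value = as.integer(dt[[cn]]))
    }
  }
  validate_cell_table(dt, panel)
}

#' Validate a cell table against a panel
#'
#' Checks uniqueness of `(roi_id, cell_id)`, numeric non-negative
#' intensities and positive areas. Extra columns are retained untouched.
#'
#' @param cells candidate table.
#' @param panel a [marker_panel()].
#' @return the table as `data.table`, row order preserved.
#' @export
validate_cell_table <- function(cells, panel) {
  dt <- data.table::as.data.table(cells)
  if (nrow(dt)) {
    key <- paste(dt$roi_id, dt$cell_id)
    if (anyDuplicated(key)) stop_fmt("duplicate (roi_id, cell_id) pairs")
    for (m in panel$marker) {
      v <- dt[[m]]
      if (!is.numeric(v)) stop_fmt("non-numeric intensity column '%s'", m)
      if (anyNA(v) || any(v < 0)) stop_fmt("negative or missing intensity in '%s'", m)
    }
    if (any(dt$area_um2 <= 0)) stop_fmt("non-positive cell area")
    if (!is.numeric(dt$x_um) || !is.numeric(dt$y_um) ||
        anyNA(dt$x_um) || anyNA(dt$y_um)) {
      stop_fmt("non-numeric centroid coordinates")
    }
  }
  dt
}

#' Extract per-cell features from a label mask and channel stack
#'
#' Converts a segmentation label mask plus a registered multichannel
#' intensity stack into a cell table: one row per distinct positive label,
#' with the unweighted centroid of the member pixel centres (scaled by
#' `pixel_size`), area = pixel count x `pixel_size`^2, and per-marker mean
#' intensity over member pixels. Labels with zero pixels are absent. Pixel
#' (1,1)'s centre is (0, 0) micrometres; x runs along columns, y along
#' rows.
#'
#' @param mask integer label matrix (0 = background).
#' @param stack numeric array height x width x channels, same grid as
#'   `mask`.
#' @param panel a [marker_panel()]; length must equal the channel count.
#' @param pixel_size micrometres per pixel.
#' @param roi_id,condition labels stamped on the output rows.
#' @return a `data.table` cell table ordered by label.
#' @export
featurize_mask <- function(mask, stack, panel, pixel_size = 1,
                           roi_id = "roi_1", condition = "unknown") {
  if (pixel_size <= 0) stop_fmt("pixel_size must be positive")
  d <- dim(stack)
  if (d[1] != nrow(mask) || d[2] != ncol(mask)) {
    stop_fmt("mask (%d x %d) and stack (%d x %d) grids differ",
             nrow(mask), ncol(mask), d[1], d[2])
  }
  if (d[3] != nrow(panel)) {
    stop_fmt("stack has %d channels but panel has %d markers", d[3], nrow(panel))
  }
  px <- which(mask > 0)
  if (!length(px)) {
    out <- data.table::data.table(cell_id = integer(), roi_id = character(),
                                  condition = character(), x_um = numeric(),
                                  y_um = numeric(), area_um2 = numeric())
    for (m in panel$marker) out[[m]] <- numeric()
    return(out)
  }
  lab <- mask[px]
  row_i <- ((px - 1L) %% nrow(mask)) + 1L
  col_i <- ((px - 1L) %/% nrow(mask)) + 1L
  f <- factor(lab)
  npix <- as.vector(table(f))
  cx <- tapply((col_i - 1) * pixel_size, f, mean)
  cy <- tapply((row_i - 1) * pixel_size, f, mean)
  out <- data.table::data.table(
    cell_id = as.integer(levels(f)), roi_id = roi_id, condition = condition,
    x_um = as.numeric(cx), y_um = as.numeric(cy),
    area_um2 = npix * pixel_size^2)
  for (m in seq_len(d[3])) {
    plane <- stack[, , m]
    out[[panel$marker[m]]] <- as.numeric(tapply(plane[px], f, mean))
  }
  out
}
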