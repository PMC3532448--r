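# RGC mosaics: jittered lattices of identical cells tiling the retinal plane.

#' Build a jittered RGC mosaic
#'
#' Places copies of a template cell on a rows x cols lattice and jitters each
#' cell's planar position with i.i.d. Gaussian noise (the study conditions
#' use a 5 um standard deviation for large-field cells and 1 um for midget
#' cells).  Cells are electrically independent; the mosaic records per-cell
#' planar offsets only.
#'
#' @param template `rgc_morphology` shared by all cells
#' @param rows,cols lattice dimensions
#' @param spacing lattice spacing, um
#' @param jitter_sd Gaussian jitter standard deviation, um
#' @param seed RNG seed
#' @param n_cells optional cell count <= rows*cols; the lattice is filled
#'   row-major and truncated (e.g. 19 cells on a 4 x 5 lattice)
#' @return object of class `rgc_mosaic` with elements `template`, `cells`
#'   (data.frame: id, x, y), `spacing` and `extent` (tiled area, um^2)
#' @export
build_mosaic <- function(template, rows, cols, spacing, jitter_sd = 5,
                         seed = 1, n_cells = rows * cols) {
  stopifnot(inherits(template, "rgc_morphology"))
  if (spacing <= 0) stop("spacing must be positive")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (n_cells < 1 || n_cells > rows * cols)
    stop("n_cells must be in [1, rows*cols]")
  grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  grid <- grid[seq_len(n_cells), ]
  x0 <- (grid$col - (cols + 1) / 2) * spacing
  y0 <- (grid$row - (rows + 1) / 2) * spacing
  jit <- with_seed(seed, matrix(stats::rnorm(2 * n_cells, 0, jitter_sd),
                                ncol = 2))
  cells <- data.frame(id = seq_len(n_cells),
                      x = x0 + jit[, 1], y = y0 + jit[, 2])
  structure(list(template = template, cells = cells, spacing = spacing,
                 extent = n_cells * spacing^2),
            class = "rgc_mosaic")
}

#' @export
print.rgc_mosaic <- function(x, ...) {
  cat("RGC mosaic:", nrow(x$cells), "cells, spacing", x$spacing,
      "um, extent", signif(x$extent, 5), "um^2\n")
  cat("  coverage factor:", signif(coverage_factor(x), 4), "\n")
  invisible(x)
}

#' Coverage factor of a mosaic
#'
#' Dimensionless coverage factor in Rodieck's sense: cell density times the
#' mean dendritic-field area, with the field area taken as the circle of the
#' mean field diameter.  Values below 1 indicate incomplete tiling; 1-3
#' indicates some overlap.
#' @param mos `rgc_mosaic`
#' @return dimensionless coverage factor
#' @export
coverage_factor <- function(mos) {
  stopifnot(inherits(mos, "rgc_mosaic"))
  if (mos$extent <= 0) stop("mosaic planar extent must be positive")
  n <- nrow(mos$cells)
  if (n == 0) return(0)
  fd <- dendritic_field_diameter(mos$template)
  (n / mos$extent) * pi * (fd / 2)^2
}

#' Lattice spacing achieving a target coverage factor
#'
#' With extent = n * spacing^2 the coverage factor is independent of n:
#' CF = pi (d/2)^2 / spacing^2.
#' @param template morphology (for its field diameter)
#' @param coverage target coverage factor
#' @return spacing in um
#' @export
spacing_for_coverage <- function(template, coverage) {
  fd <- dendritic_field_diameter(template)
  sqrt(pi * (fd / 2)^2 / coverage)
}

# Axon polylines of every cell, in mosaic coordinates.  Returns a list of
# matrices (x, y), one per cell, ordered along the axon from the soma.
axon_polylines <- function(mos) {
  nd <- mos$template$nodes
  ax <- which(nd$region %in% c("hillock", "ais", "axon"))
  # order axon nodes by path distance (the axon is an unbranched path here;
  # for branched axons each branch contributes its root-to-tip segments)
  segs <- cbind(nd$x[nd$parent[ax]], nd$y[nd$parent[ax]],
                nd$x[ax], nd$y[ax])
  lapply(seq_len(nrow(mos$cells)), function(i) {
    dx <- mos$cells$x[i]; dy <- mos$cells$y[i]
    segs + cbind(dx, dy, dx, dy)[rep(1, nrow(segs)), , drop = FALSE]
  })
}

#' Distance from a point to the nearest axon in a mosaic
#'
#' Minimum in-plane (x-y) point-to-segment distance over the axon polylines
#' of all cells.
#' @param point numeric (x, y) in um
#' @param mos `rgc_mosaic`
#' @return distance in um
#' @export
nearest_axon_distance <- function(point, mos) {
  stopifnot(length(point) >= 2)
  best <- Inf
  for (segs in axon_polylines(mos)) {
    d <- point_segment_distance(point[1], point[2],
                                segs[, 1], segs[, 2], segs[, 3], segs[, 4])
    best <- min(best, d)
  }
  best
}

# vectorized 2-D point-to-segment distance
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx^2 + dy^2
  t <- ifelse(L2 > 0, ((px - x1) * dx + (py - y1) * dy) / L2, 0)
  t <- pmin(pmax(t, 0), 1)
  min(sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2))
}

#' Write / read a mosaic manifest
#'
#' The manifest is a CSV (cell-id, x-offset, y-offset, swc-path) plus the
#' template cell written as SWC, so a mosaic can be shared as plain text.
#' @param mos `rgc_mosaic`
#' @param dir output directory (created if needed)
#' @return manifest path, invisibly
#' @export
write_mosaic_manifest <- function(mos, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  swc <- file.path(dir, "template.swc")
  write_swc(mos$template, swc)
  man <- data.frame(cell_id = mos$cells$id, x_offset = mos$cells$x,
                    y_offset = mos$cells$y, swc_path = "template.swc")
  path <- file.path(dir, "mosaic.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mosaic_manifest
#' @param path manifest CSV path
#' @param spacing,extent lattice metadata to restore (the CSV stores
#'   positions only); defaults reconstruct spacing from the median nearest-
#'   neighbour distance
#' @export
read_mosaic_manifest <- function(path, spacing = NULL, extent = NULL) {
  man <- utils::read.csv(path)
  template <- read_swc(file.path(dirname(path), man$swc_path[1]))
  cells <- data.frame(id = man$cell_id, x = man$x_offset, y = man$y_offset)
  if (is.null(spacing)) {
    d <- as.matrix(stats::dist(cells[, c("x", "y")]))
    diag(d) <- Inf
    spacing <- if (nrow(cells) > 1) stats::median(apply(d, 1, min)) else 1
  }
  structure(list(template = template, cells = cells, spacing = spacing,
                 extent = extent %||% (nrow(cells) * spacing^2)),
            class = "rgc_mosaic")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
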