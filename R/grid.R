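#' Voxel grid of a scaffold geometry
#'
#' A `voxel_grid` is a binary 3D image with physical voxel spacing: each voxel
#' is either solid (trabecular matrix) or fluid (pore space). It is the common
#' container consumed by the morphometry routines and the pore-scale flow
#' solver.
#'
#' @param labels 3D array (integer, numeric or logical). Non-zero / `TRUE`
#'   values are solid, zero / `FALSE` values are fluid.
#' @param spacing isotropic voxel edge length in micrometres (> 0).
#' @param flow_axis axis index (1, 2 or 3) of the perfusion direction.
#'   Default 3 (z).
#' @return An object of class `voxel_grid` with elements `labels` (integer
#'   array, 1 = solid, 0 = fluid), `spacing` (µm), `dims`, `flow_axis`.
#' @examples
#' g <- voxel_grid(array(0L, c(8, 8, 8)), spacing = 40)
#' porosity(g)
#' @export
voxel_grid <- function(labels, spacing, flow_axis = 3) {
  if (length(dim(labels)) != 3)
    stop("`labels` must be a 3D array")
  if (!is.numeric(spacing) || length(spacing) != 1 || !is.finite(spacing) ||
      spacing <= 0)
    stop("`spacing` must be a single positive number (micrometres)")
  if (!flow_axis %in% 1:3)
    stop("`flow_axis` must be 1, 2 or 3")
  lab <- labels
  storage.mode(lab) <- "integer"
  if (anyNA(lab)) stop("`labels` must not contain NA")
  lab[lab != 0L] <- 1L
  structure(
    list(labels = lab, spacing = as.numeric(spacing),
         dims = dim(lab), flow_axis = as.integer(flow_axis)),
    class = "voxel_grid")
}

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

stopifnot_grid <- function(grid) {
  if (!is_voxel_grid(grid)) stop("expected a `voxel_grid` object")
  invisible(grid)
}

#' Fluid volume fraction of a voxel grid
#'
#' @param grid a [voxel_grid()].
#' @return Porosity (fluid voxels / total voxels), in `[0, 1]`.
#' @export
porosity <- function(grid) {
  stopifnot_grid(grid)
  1 - mean(grid$labels)
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- x$dims
  cat(sprintf("<voxel_grid> %d x %d x %d voxels @ %.4g um (%.3g x %.3g x %.3g mm)\n",
              d[1], d[2], d[3],
              x$spacing,
              d[1] * x$spacing / 1000, d[2] * x$spacing / 1000,
              d[3] * x$spacing / 1000))
  cat(sprintf("  porosity %.3f | flow axis %s\n",
              porosity(x), c("x", "y", "z")[x$flow_axis]))
  invisible(x)
}

# permute so the flow axis becomes the third array index
permute_flow_last <- function(grid) {
  if (grid$flow_axis == 3) return(grid)
  perm <- switch(grid$flow_axis, `1` = c(2, 3, 1), `2` = c(1, 3, 2))
  g <- voxel_grid(aperm(grid$labels, perm), grid$spacing, flow_axis = 3)
  attr(g, "scaffold_spec") <- attr(grid, "scaffold_spec")
  g
}

# labels of the two faces perpendicular to the flow axis
axis_faces <- function(labels, axis) {
  n <- dim(labels)[axis]
  idx <- function(k) switch(axis,
    `1` = labels[k, , ], `2` = labels[, k, ], `3` = labels[, , k])
  list(inlet = idx(1), outlet = idx(n))
}

#' Does the fluid phase percolate along the flow axis?
#'
#' Checks whether a single 6-connected fluid component joins the inlet face to
#' the outlet face.
#'
#' @param grid a [voxel_grid()].
#' @return `TRUE` or `FALSE`.
#' @export
percolates <- function(grid) {
  stopifnot_grid(grid)
  fluid <- 1L - grid$labels
  if (!any(fluid == 1L)) return(FALSE)
  lab <- cpp_label(as.integer(fluid), dim(fluid), 6L)
  dim(lab) <- dim(fluid)
  f <- axis_faces(lab, grid$flow_axis)
  inlab <- unique(f$inlet[f$inlet > 0])
  outlab <- unique(f$outlet[f$outlet > 0])
  length(intersect(inlab, outlab)) > 0
}

#' Solid-fluid interface area
#'
#' Total area of voxel faces separating solid from fluid voxels inside the
#' grid (domain boundary faces are not counted).
#'
#' @param grid a [voxel_grid()].
#' @return Area in µm².
#' @export
interface_area <- function(grid) {
  stopifnot_grid(grid)
  L <- grid$labels
  d <- dim(L)
  nf <- sum(L[-d[1], , ] != L[-1, , ]) +
        sum(L[, -d[2], ] != L[, -1, ]) +
        sum(L[, , -d[3]] != L[, , -1])
  nf * grid$spacing^2
}

#' Read a voxel grid from a multi-page TIFF stack
#'
#' Slices are stacked along the third array axis. Non-binary (8/16-bit) input
#' is thresholded: sample values greater than or equal to `threshold` (on the
#' native integer scale of the file) are labeled solid.
#'
#' @param path path to a multi-page TIFF file.
#' @param spacing isotropic voxel edge length in µm (required; TIFF files do
#'   not carry it reliably).
#' @param threshold threshold on the native sample scale (e.g. 128 for 8-bit
#'   data). The default 1 treats any non-zero value as solid, which is the
#'   lossless inverse of [write_grid()].
#' @param flow_axis perfusion axis of the returned grid.
#' @return A [voxel_grid()].
#' @export
read_image_stack <- function(path, spacing, threshold = 1, flow_axis = 3) {
  if (missing(spacing)) stop("`spacing` (um) must be given")
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("cannot read TIFF: ",
                                             conditionMessage(e)))
  if (length(pages) == 0) stop("empty TIFF stack: ", path)
  shapes <- vapply(pages, function(p) paste(dim(p)[1:2], collapse = "x"), "")
  if (length(unique(shapes)) != 1)
    stop("ragged TIFF stack: slice shapes differ (", paste(unique(shapes),
         collapse = ", "), ")")
  arr <- simplify2array(lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # first channel
    p
  }))
  voxel_grid(arr >= threshold, spacing, flow_axis)
}

#' Write a voxel grid to disk
#'
#' `tiff` writes a binary multi-page TIFF (solid = 255 on an 8-bit scale) that
#' round-trips losslessly through [read_image_stack()]. `vtk` writes a legacy
#' ASCII VTK structured-points file with the labels as cell data, for 3D
#' viewing.
#'
#' @param grid a [voxel_grid()].
#' @param path output file path.
#' @param format `"tiff"` or `"vtk"`.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, format = c("tiff", "vtk")) {
  stopifnot_grid(grid)
  format <- match.arg(format)
  if (format == "tiff") {
    d <- grid$dims
    pages <- lapply(seq_len(d[3]), function(k) {
      m <- grid$labels[, , k]
      storage.mode(m) <- "double"
      m  # 1.0 = solid; writeTIFF maps [0,1] to the 8-bit scale
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else {
    write_vtk_grid(grid, path)
  }
  invisible(path)
}

write_vtk_grid <- function(grid, path, fields = list()) {
  d <- grid$dims
  h <- grid$spacing
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "trabeflow voxel grid",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1] + 1, d[2] + 1, d[3] + 1),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", h, h, h),
               sprintf("CELL_DATA %d", prod(d)),
               "SCALARS label int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(paste(as.vector(grid$labels), collapse = " "), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(paste(format(as.vector(fields[[nm]]), digits = 7),
                     collapse = " "), con)
  }
  invisible(path)
}
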