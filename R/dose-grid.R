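#' Dose grid on a regular voxel lattice
#'
#' A 3-D scalar field (absorbed dose in Gy, or a signed dose difference) on a
#' regular lattice with world-coordinate geometry. Voxel `(i, j, k)` (1-based)
#' has its centre at `origin + (c(i, j, k) - 1) * spacing` (mm). By default
#' the lattice is centred on the world origin.
#'
#' @param values 3-D numeric array.
#' @param spacing Voxel size, mm, length 1 or 3; must be positive.
#' @param origin World position (mm) of the first voxel centre; default
#'   centres the grid at 0.
#' @param signed Logical; signed fields (delta-dose maps) may be negative,
#'   physical doses may not.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing, origin = NULL, signed = FALSE) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array, got ", length(dim(values)), " dims")
  storage.mode(values) <- "double"
  spacing <- rep_len(as.double(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be positive and finite")
  if (is.null(origin)) origin <- -(dim(values) - 1) / 2 * spacing
  origin <- rep_len(as.double(origin), 3L)
  if (anyNA(values) && any(is.nan(values)))
    stop("dose grid contains NaN values")
  if (!signed && any(values < 0, na.rm = TRUE))
    stop("physical dose grid has negative values; use signed = TRUE for delta-dose maps")
  structure(list(values = values, spacing = spacing, origin = origin,
                 signed = isTRUE(signed)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid%s> %s voxels @ %s mm, origin (%s) mm\n",
              if (x$signed) " (signed)" else "",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin, digits = 4), collapse = ", ")))
  v <- x$values[is.finite(x$values)]
  cat(sprintf("  range [%.3f, %.3f] Gy, %d non-finite voxels\n",
              min(v), max(v), sum(!is.finite(x$values))))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' World coordinates of the lattice along one axis
#' @param grid A `dose_grid`.
#' @param axis Axis index 1..3.
#' @return Numeric vector of voxel-centre coordinates, mm.
#' @export
grid_axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(dim(grid$values)[axis]) - 1) * grid$spacing[axis]
}

#' Read a NIfTI-1 volume as a dose grid or binary mask
#'
#' @param path Path to a 3-D NIfTI-1 file.
#' @param kind `"dose"` (non-negative float field), `"delta"` (signed field)
#'   or `"mask"` (strictly 0/1, returned as a logical array with geometry
#'   attributes).
#' @return A `dose_grid`, or for masks a logical array with `spacing` and
#'   `origin` attributes.
#' @export
read_volume <- function(path, kind = c("dose", "delta", "mask")) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D volume, got ", length(d), "-D payload in ", path)
  vals <- array(as.double(img), dim = d)
  if (any(is.nan(vals)))
    stop("NaN payload in ", path)
  sp <- attr(img, "pixdim")[1:3]
  xf <- RNifti::xform(img)
  orig <- xf[1:3, 4]
  # undo any RAS sign flips RNifti applied to the stored sform
  for (ax in 1:3) {
    if (xf[ax, ax] < 0) orig[ax] <- orig[ax] + xf[ax, ax] * (d[ax] - 1)
  }
  if (kind == "mask") {
    u <- unique(as.vector(vals))
    if (!all(u %in% c(0, 1)))
      stop("mask file ", path, " has values outside {0,1}: ",
           paste(utils::head(setdiff(u, c(0, 1))), collapse = ", "))
    m <- array(vals > 0, dim = d)
    attr(m, "spacing") <- sp
    attr(m, "origin") <- orig
    return(m)
  }
  dose_grid(vals, spacing = sp, origin = orig, signed = (kind == "delta"))
}

#' Write a dose grid or mask volume as NIfTI-1
#'
#' Dose fields are stored as float32, masks as uint8. Values pass through
#' float32 on write, so a write/read round trip is bitwise stable for data
#' already at float32 precision. Use an uncompressed `.nii` suffix for
#' byte-reproducible outputs.
#'
#' @param x A `dose_grid` or a logical/0-1 array with `spacing`/`origin`
#'   attributes (as from [read_volume()]).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "dose_grid")) {
    vals <- x$values
    spacing <- x$spacing
    origin <- x$origin
    dt <- "float"
  } else {
    vals <- array(as.integer(x != 0), dim = dim(x))
    spacing <- attr(x, "spacing")
    origin <- attr(x, "origin")
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    if (is.null(origin)) origin <- -(dim(vals) - 1) / 2 * spacing
    dt <- "uint8"
  }
  xf <- diag(4)
  diag(xf)[1:3] <- spacing
  xf[1:3, 4] <- origin
  attr(vals, "pixdim") <- spacing
  img <- RNifti::asNifti(vals, datatype = dt)
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
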