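#' Shift a dose distribution relative to the patient
#'
#' Under the shift-invariance approximation, a rigid patient displacement
#' `shift` (mm) leaves the dose distribution fixed in room coordinates, so
#' the anatomy point at planning position `x` receives `D(x + shift)`.
#' Sampling is trilinear; points sampling outside the grid receive 0 Gy.
#'
#' @param dose A `dose_grid`.
#' @param shift Displacement 3-vector, mm.
#' @return A `dose_grid` on the same lattice.
#' @export
shift_dose <- function(dose, shift) {
  stopifnot(inherits(dose, "dose_grid"))
  shift <- rep_len(as.double(shift), 3L)
  if (any(!is.finite(shift))) stop("`shift` must be finite")
  vals <- accumulate_cpp(as.vector(dose$values), dim(dose$values),
                         dose$spacing, matrix(shift, 1L, 3L))
  dose_grid(array(vals, dim(dose$values)), dose$spacing, dose$origin,
            signed = dose$signed)
}

#' Accumulate delivered dose over a course of fractions
#'
#' Each fraction delivers `1/n` of the planned distribution, shifted by that
#' fraction's residual setup error; the estimated delivered (accumulated)
#' dose is the sum of the per-fraction contributions, i.e. the mean of the
#' shifted grids scaled to the full course.
#'
#' @param planned A `dose_grid` of the planned full-course dose.
#' @param residuals n-by-3 matrix of per-fraction residual errors, mm
#'   (ordered; ordering does not affect the result).
#' @return A `dose_grid`: the accumulated full-course dose.
#' @export
accumulate_dose <- function(planned, residuals) {
  stopifnot(inherits(planned, "dose_grid"))
  residuals <- as.matrix(residuals)
  if (nrow(residuals) < 1L) stop("at least one fraction residual is required")
  if (ncol(residuals) != 3L || any(!is.finite(residuals)))
    stop("`residuals` must be a finite n-by-3 matrix (mm)")
  vals <- accumulate_cpp(as.vector(planned$values), dim(planned$values),
                         planned$spacing, residuals)
  dose_grid(array(vals, dim(planned$values)), planned$spacing, planned$origin)
}

#' Voxel-wise dose difference map
#'
#' `delta = accumulated - planned`: positive values indicate a higher
#' delivered dose than planned.
#'
#' @param accumulated,planned `dose_grid`s on an identical lattice.
#' @return A signed `dose_grid` (delta-dose map).
#' @export
delta_dose <- function(accumulated, planned) {
  stopifnot(inherits(accumulated, "dose_grid"), inherits(planned, "dose_grid"))
  if (!same_geometry(accumulated, planned))
    stop("accumulated and planned grids have different geometry")
  dose_grid(accumulated$values - planned$values, planned$spacing,
            planned$origin, signed = TRUE)
}
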