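#' IGRT imaging and correction protocol
#'
#' Describes an image-guided radiotherapy verification protocol: which
#' fractions are imaged, the couch-correction action threshold, and whether
#' the threshold is evaluated per translation axis or on the 3-D vector norm.
#' The default imaging schedule is the clinical standard for a 20-fraction
#' course: daily imaging for the first 3 fractions, then weekly
#' (fractions 1, 2, 3, 8, 13, 18 at 5 fractions per week).
#'
#' @param action_threshold Correction threshold, mm (> 0). Measured errors at
#'   or below the threshold are left uncorrected.
#' @param imaging_fractions Integer fraction indices that are imaged.
#' @param threshold_rule `"per_axis"` (correct if any axis exceeds the
#'   threshold) or `"vector_norm"` (correct if the 3-D shift length does).
#' @param n_fractions Course length used to build the default schedule.
#' @return An object of class `igrt_protocol`.
#' @export
igrt_protocol <- function(action_threshold = 5,
                          imaging_fractions = default_imaging_fractions(n_fractions),
                          threshold_rule = c("per_axis", "vector_norm"),
                          n_fractions = 20L) {
  threshold_rule <- match.arg(threshold_rule)
  if (!is.finite(action_threshold) || action_threshold <= 0)
    stop("`action_threshold` must be positive (mm)")
  imaging_fractions <- sort(unique(as.integer(imaging_fractions)))
  if (any(imaging_fractions < 1L))
    stop("imaging fractions must be >= 1")
  structure(list(action_threshold = action_threshold,
                 imaging_fractions = imaging_fractions,
                 threshold_rule = threshold_rule),
            class = "igrt_protocol")
}

#' Default imaging schedule: first three fractions, then weekly
#' @param n_fractions Number of fractions in the course.
#' @param per_week Fractions delivered per week.
#' @return Sorted integer vector of imaged fraction indices.
#' @export
default_imaging_fractions <- function(n_fractions = 20L, per_week = 5L) {
  f <- c(1:3, seq.int(3L + per_week, n_fractions, by = per_week))
  sort(unique(f[f <= n_fractions]))
}

#' Sample per-fraction setup errors
#'
#' Standard systematic-plus-random error model: each patient draws one
#' systematic displacement `Sigma ~ N(0, systematic_sd^2)` per axis, and each
#' fraction adds an independent random component `delta_f ~ N(0, random_sd^2)`
#' per axis, so the fraction-f setup error is `Sigma + delta_f` (mm,
#' patient displacement from the planned position).
#'
#' @param systematic_sd,random_sd Per-axis standard deviations, mm (length 1
#'   or 3, >= 0).
#' @param n_fractions Number of fractions (>= 1).
#' @param seed Optional integer seed.
#' @return A data frame with columns `fraction`, `ex_mm`, `ey_mm`, `ez_mm`.
#' @export
sample_fraction_errors <- function(systematic_sd, random_sd, n_fractions,
                                   seed = NULL) {
  systematic_sd <- rep_len(as.double(systematic_sd), 3L)
  random_sd <- rep_len(as.double(random_sd), 3L)
  if (any(systematic_sd < 0) || any(random_sd < 0))
    stop("error SDs must be >= 0")
  n_fractions <- as.integer(n_fractions)
  if (n_fractions < 1L) stop("`n_fractions` must be >= 1")
  with_seed(seed, {
    sys <- rnorm(3L, 0, systematic_sd)
    err <- matrix(rnorm(3L * n_fractions, 0, rep(random_sd, each = n_fractions)),
                  nrow = n_fractions)
    err <- sweep(err, 2L, sys, "+")
    data.frame(fraction = seq_len(n_fractions),
               ex_mm = err[, 1], ey_mm = err[, 2], ez_mm = err[, 3])
  })
}

#' Apply an IGRT action-threshold protocol to a course of setup errors
#'
#' At imaged fractions the measured shift is compared with the action
#' threshold under the protocol's rule; if it exceeds the threshold an online
#' correction is performed and the residual error is exactly zero, otherwise
#' the residual equals the setup error. Non-imaged fractions are delivered
#' with the uncorrected setup error as residual (corrections are purely
#' online and do not carry over).
#'
#' @param records Data frame from [sample_fraction_errors()], ordered by
#'   `fraction`.
#' @param protocol An [igrt_protocol()].
#' @return `records` with added columns `imaged`, `corrected`, `rx_mm`,
#'   `ry_mm`, `rz_mm`.
#' @export
apply_igrt_protocol <- function(records, protocol) {
  stopifnot(inherits(protocol, "igrt_protocol"))
  if (is.unsorted(records$fraction, strictly = TRUE))
    stop("`records` must be ordered by fraction_index")
  if (any(protocol$imaging_fractions > max(records$fraction)))
    stop("imaging fraction index out of range: ",
         paste(setdiff(protocol$imaging_fractions, records$fraction),
               collapse = ", "))
  e <- as.matrix(records[, c("ex_mm", "ey_mm", "ez_mm")])
  imaged <- records$fraction %in% protocol$imaging_fractions
  exceeds <- switch(protocol$threshold_rule,
    per_axis = apply(abs(e), 1L, max) > protocol$action_threshold,
    vector_norm = sqrt(rowSums(e^2)) > protocol$action_threshold)
  corrected <- imaged & exceeds
  r <- e
  r[corrected, ] <- 0
  records$imaged <- imaged
  records$corrected <- corrected
  records$rx_mm <- r[, 1]
  records$ry_mm <- r[, 2]
  records$rz_mm <- r[, 3]
  records
}

#' Residual-error series used for dose accumulation
#'
#' `"asis"` returns the true per-fraction residuals. `"locf"` mirrors what is
#' clinically observable under sparse imaging: at non-imaged fractions the
#' residual is estimated by carrying forward the residual of the most recent
#' imaged fraction (zero before the first imaged fraction).
#'
#' @param records Output of [apply_igrt_protocol()].
#' @param mode `"asis"` or `"locf"`.
#' @return Numeric matrix, one row per fraction, columns x/y/z mm.
#' @export
residual_series <- function(records, mode = c("asis", "locf")) {
  mode <- match.arg(mode)
  r <- as.matrix(records[, c("rx_mm", "ry_mm", "rz_mm")])
  dimnames(r) <- NULL
  if (mode == "asis") return(r)
  out <- matrix(0, nrow(r), 3L)
  last <- c(0, 0, 0)
  for (i in seq_len(nrow(r))) {
    if (records$imaged[i]) last <- r[i, ]
    out[i, ] <- last
  }
  out
}

#' Signed heart shift induced by a residual setup error
#'
#' Change in the distance between the target and heart centres of mass when
#' the residual displacement is applied to the anatomy:
#' `|heart + residual - target| - |heart - target|`. Negative values mean the
#' residual error moves the heart towards the target's high-dose region.
#'
#' @param target_com,heart_com World coordinates, mm (length 3); must differ.
#' @param residual Residual error 3-vector (mm), or an n-by-3 matrix.
#' @return Signed shift(s), mm.
#' @export
heart_shift_metric <- function(target_com, heart_com, residual) {
  base <- sqrt(sum((heart_com - target_com)^2))
  if (base == 0) stop("target and heart centres of mass coincide")
  if (is.null(dim(residual))) residual <- matrix(residual, nrow = 1L)
  d <- sweep(residual, 2L, heart_com - target_com, "+")
  sqrt(rowSums(d^2)) - base
}

#' Summarise residual errors over a treatment course
#'
#' @param records Output of [apply_igrt_protocol()] (>= 1 row).
#' @param target_com,heart_com Centres of mass, world mm; may also be given
#'   via `anatomy` (an object with `gtv_com` and `heart_com`).
#' @param anatomy Optional anatomy model supplying the centres of mass.
#' @return A list of class `course_summary` with `mean_residual` (3-vector
#'   mm) and `mean_heart_shift` (signed mm, mean over all fractions).
#' @export
summarise_course <- function(records, target_com = anatomy$gtv_com,
                             heart_com = anatomy$heart_com, anatomy = NULL) {
  if (nrow(records) < 1L) stop("no fraction records to summarise")
  r <- as.matrix(records[, c("rx_mm", "ry_mm", "rz_mm")])
  structure(list(
    mean_residual = setNames(colMeans(r), c("x", "y", "z")),
    mean_heart_shift = mean(heart_shift_metric(target_com, heart_com, r)),
    n_fractions = nrow(records)
  ), class = "course_summary")
}

#' @export
print.course_summary <- function(x, ...) {
  cat(sprintf("<course_summary> %d fractions; mean residual (%.2f, %.2f, %.2f) mm; mean heart shift %+.3f mm\n",
              x$n_fractions, x$mean_residual[1], x$mean_residual[2],
              x$mean_residual[3], x$mean_heart_shift))
  invisible(x)
}
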