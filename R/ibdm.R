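#' Patient-to-reference spatial transform
#'
#' Affine map from patient world coordinates to reference world coordinates,
#' `x_ref = A x_pat + t`. In this pipeline the transforms are known exactly
#' (the cohort generator creates the anatomy from them), standing in for a
#' deformable spatial normalisation whose output would otherwise need visual
#' QA.
#'
#' @param A Invertible 3x3 matrix.
#' @param t Translation 3-vector, mm.
#' @return An object of class `reference_transform`.
#' @export
reference_transform <- function(A, t = c(0, 0, 0)) {
  A <- matrix(as.double(A), 3L, 3L)
  if (!is.finite(det(A)) || abs(det(A)) < 1e-12)
    stop("transform matrix is singular")
  structure(list(A = A, t = rep_len(as.double(t), 3L)),
            class = "reference_transform")
}

#' QA check for a spatial-normalisation transform
#'
#' Mirrors the visual registration QA of image-based data-mining studies:
#' a patient passes if the transform maps their heart centre of mass to
#' within `tolerance` mm of the reference heart centre of mass.
#'
#' @param transform A [reference_transform()].
#' @param patient_heart_com,reference_heart_com World coordinates, mm.
#' @param tolerance QA tolerance, mm.
#' @return List with `heart_com_deviation` (mm) and `qa_passed`.
#' @export
qa_transform <- function(transform, patient_heart_com, reference_heart_com,
                         tolerance = 10) {
  mapped <- as.vector(transform$A %*% patient_heart_com + transform$t)
  dev <- sqrt(sum((mapped - reference_heart_com)^2))
  list(heart_com_deviation = dev, qa_passed = dev <= tolerance)
}

#' Resample a patient map onto the reference lattice
#'
#' Each reference voxel is pulled back to patient coordinates through the
#' inverse transform and sampled trilinearly from the patient map. Voxels
#' whose pre-image falls outside the patient grid are flagged invalid (`NA`).
#'
#' @param map A `dose_grid` in patient coordinates.
#' @param transform A [reference_transform()] (patient to reference).
#' @param ref_geometry List with `dim`, `spacing`, `origin` of the reference
#'   lattice; defaults to the map's own lattice.
#' @return A signed `dose_grid` on the reference lattice with `NA` at
#'   out-of-field voxels.
#' @export
map_to_reference <- function(map, transform, ref_geometry = NULL) {
  stopifnot(inherits(map, "dose_grid"), inherits(transform, "reference_transform"))
  if (is.null(ref_geometry))
    ref_geometry <- list(dim = dim(map$values), spacing = map$spacing,
                         origin = map$origin)
  Minv <- solve(transform$A)
  b <- -as.vector(Minv %*% transform$t)
  vals <- resample_affine_cpp(as.vector(map$values), dim(map$values),
                              map$spacing, map$origin,
                              as.integer(ref_geometry$dim),
                              ref_geometry$spacing, ref_geometry$origin,
                              Minv, b, NA_real_)
  out <- array(vals, ref_geometry$dim)
  out[is.nan(out)] <- NA_real_
  dose_grid(out, ref_geometry$spacing, ref_geometry$origin, signed = TRUE)
}

gaussian_kernels <- function(sigma_mm, spacing) {
  lapply(1:3, function(ax) {
    s_vox <- sigma_mm[ax] / spacing[ax]
    if (s_vox == 0) return(NULL)
    r <- max(1L, ceiling(3 * s_vox))
    k <- dnorm(seq.int(-r, r), sd = s_vox)
    k / sum(k)
  })
}

#' Gaussian blur of a map for registration uncertainty
#'
#' Separable Gaussian convolution with per-axis sigma in mm (converted to
#' voxels), unit-sum kernel, reflecting boundary. Models the residual
#' uncertainty of the spatial normalisation.
#'
#' @param map A `dose_grid`.
#' @param sigma_mm Sigma per axis, mm (length 1 or 3, >= 0; 0 = identity).
#' @return A blurred `dose_grid`.
#' @export
blur_map <- function(map, sigma_mm) {
  stopifnot(inherits(map, "dose_grid"))
  sigma_mm <- rep_len(as.double(sigma_mm), 3L)
  if (any(!is.finite(sigma_mm)) || any(sigma_mm < 0))
    stop("`sigma_mm` must be >= 0")
  ks <- gaussian_kernels(sigma_mm, map$spacing)
  v <- array(blur3_cpp(as.vector(map$values), dim(map$values), ks),
             dim(map$values))
  dose_grid(v, map$spacing, map$origin, signed = map$signed)
}

#' Stack per-patient maps into a voxel-by-patient matrix
#'
#' @param maps List of `dose_grid`s on a common lattice.
#' @return Numeric matrix (voxels x patients) with `dim3`, `spacing`,
#'   `origin` attributes.
#' @export
stack_maps <- function(maps) {
  stopifnot(length(maps) >= 1L)
  g0 <- maps[[1L]]
  for (m in maps) {
    if (!same_geometry(m, g0)) stop("maps are not on a common lattice")
  }
  x <- vapply(maps, function(m) as.vector(m$values),
              numeric(length(g0$values)))
  attr(x, "dim3") <- dim(g0$values)
  attr(x, "spacing") <- g0$spacing
  attr(x, "origin") <- g0$origin
  x
}

#' Analysis mask from per-patient validity
#'
#' Voxels where at least `coverage` of the patients have valid (finite)
#' mapped values.
#'
#' @param maps Voxel-by-patient matrix (see [stack_maps()]).
#' @param coverage Required fraction of valid patients per voxel.
#' @return Logical vector over voxels.
#' @export
analysis_mask <- function(maps, coverage = 0.9) {
  rowMeans(is.finite(maps)) >= coverage
}

#' Voxel-wise permutation test of delta-dose between outcome groups
#'
#' Image-based data-mining statistic: at each voxel the observed difference
#' of group means (`dead` minus `alive`, so positive values mean a higher
#' delta-dose in non-survivors) is scaled by the standard deviation of that
#' difference over random label permutations (group sizes preserved),
#' yielding a t-statistic map. Global inference uses the maxT permutation
#' distribution: `global_p = (1 + #{b: max |t_b| >= max t}) / (n_perm + 1)`,
#' which controls family-wise error and cannot return an exact zero.
#'
#' @param maps Voxel-by-patient matrix ([stack_maps()]) or list of
#'   `dose_grid`s. Patients with indeterminate one-year status must already
#'   be excluded.
#' @param labels Factor/character per patient: `"alive"` or `"dead"` (>= 2
#'   each).
#' @param n_perm Number of permutations (>= 10).
#' @param seed Optional integer seed for the permutation stream.
#' @param mask Optional logical voxel mask (array or vector); voxels invalid
#'   in any patient are dropped automatically.
#' @param chunk Permutations per block (memory control).
#' @return An object of class `tstat_map` with arrays `t`, `diff`, `perm_sd`
#'   (NA outside the analysed voxels), `max_t`, `argmax` (voxel index),
#'   `global_p`, `n_perm`, `perms` (the permutation set), and lattice
#'   geometry.
#' @export
permutation_test <- function(maps, labels, n_perm = 1000L, seed = NULL,
                             mask = NULL, chunk = NULL) {
  if (is.list(maps)) maps <- stack_maps(maps)
  dim3 <- attr(maps, "dim3")
  if (is.null(dim3)) stop("`maps` must carry a dim3 attribute (see stack_maps)")
  n <- ncol(maps)
  labels <- as.character(labels)
  if (!all(labels %in% c("alive", "dead")))
    stop("labels must be 'alive' or 'dead' (exclude indeterminate patients)")
  dead <- labels == "dead"
  n1 <- sum(dead); n2 <- sum(!dead)
  if (n1 < 2L || n2 < 2L)
    stop("each outcome group needs >= 2 patients (dead=", n1, ", alive=", n2, ")")
  n_perm <- as.integer(n_perm)
  if (n_perm < 10L) stop("n_perm must be >= 10")

  vox_ok <- rowSums(!is.finite(maps)) == 0L
  if (!is.null(mask)) vox_ok <- vox_ok & as.vector(mask)
  idx <- which(vox_ok)
  if (length(idx) == 0L) stop("analysis mask is empty")
  X <- maps[idx, , drop = FALSE]

  w0 <- ifelse(dead, 1 / n1, -1 / n2)
  diff_v <- as.vector(X %*% w0)

  perms <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) sample.int(n), integer(n))
  })  # n x n_perm

  if (is.null(chunk)) chunk <- max(1L, min(n_perm, floor(2e7 / length(idx))))
  starts <- seq.int(1L, n_perm, by = chunk)
  # pass 1: moments of the permuted difference at each voxel
  s1 <- s2 <- numeric(length(idx))
  for (st in starts) {
    en <- min(st + chunk - 1L, n_perm)
    W <- matrix(w0[perms[, st:en, drop = FALSE]], nrow = n)
    D <- X %*% W
    s1 <- s1 + rowSums(D)
    s2 <- s2 + rowSums(D^2)
  }
  var_v <- pmax(0, (s2 - s1^2 / n_perm) / (n_perm - 1L))
  perm_sd <- sqrt(var_v)
  # guard against pure floating-point jitter at truly constant voxels
  sd_floor <- 1e-10 * (max(abs(X)) + 1)
  pos <- perm_sd > sd_floor
  t_v <- rep(NA_real_, length(idx))
  t_v[pos] <- diff_v[pos] / perm_sd[pos]

  if (!any(pos)) {
    max_t <- 0
    argmax <- NA_integer_
    n_ge <- n_perm  # nothing can exceed a degenerate observation
  } else {
    max_t <- max(t_v[pos])
    argmax <- idx[which(pos)[which.max(t_v[pos])]]
    # pass 2: maxT null distribution
    n_ge <- 0L
    inv_sd <- 1 / perm_sd[pos]
    for (st in starts) {
      en <- min(st + chunk - 1L, n_perm)
      W <- matrix(w0[perms[, st:en, drop = FALSE]], nrow = n)
      D <- X[pos, , drop = FALSE] %*% W
      pm <- apply(abs(D * inv_sd), 2L, max)
      n_ge <- n_ge + sum(pm >= max_t)
    }
  }
  global_p <- (1 + n_ge) / (n_perm + 1)

  embed <- function(v) {
    full <- rep(NA_real_, prod(dim3))
    full[idx] <- v
    array(full, dim3)
  }
  structure(list(t = embed(t_v), diff = embed(diff_v),
                 perm_sd = embed(perm_sd),
                 max_t = max_t, argmax = argmax, global_p = global_p,
                 n_perm = n_perm, n_dead = n1, n_alive = n2,
                 perms = perms, seed = seed,
                 dim = dim3, spacing = attr(maps, "spacing"),
                 origin = attr(maps, "origin")),
            class = "tstat_map")
}

#' @export
print.tstat_map <- function(x, ...) {
  cat(sprintf("<tstat_map> %s lattice, %d dead vs %d alive, %d permutations\n",
              paste(x$dim, collapse = "x"), x$n_dead, x$n_alive, x$n_perm))
  cat(sprintf("  max t = %.3f, global p = %.4f\n", x$max_t, x$global_p))
  invisible(x)
}

neighbour_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  g
}

# Connected component of `candidate` (logical 3-D array) containing `start`
# (array index), via vectorised breadth-first flood fill.
component_containing <- function(candidate, start, connectivity = 26L) {
  dm <- dim(candidate)
  offs <- neighbour_offsets(connectivity)
  comp <- array(FALSE, dm)
  comp[start] <- TRUE
  frontier <- matrix(arrayInd(start, dm), ncol = 3L)
  while (nrow(frontier) > 0L) {
    nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(o)
      sweep(frontier, 2L, offs[o, ], "+")))
    ok <- nb[, 1] >= 1L & nb[, 1] <= dm[1] &
      nb[, 2] >= 1L & nb[, 2] <= dm[2] &
      nb[, 3] >= 1L & nb[, 3] <= dm[3]
    nb <- nb[ok, , drop = FALSE]
    if (nrow(nb) == 0L) break
    lin <- nb[, 1] + dm[1] * (nb[, 2] - 1L) + dm[1] * dm[2] * (nb[, 3] - 1L)
    keep <- !duplicated(lin)
    nb <- nb[keep, , drop = FALSE]
    lin <- lin[keep]
    new <- candidate[lin] & !comp[lin]
    if (!any(new)) break
    comp[lin[new]] <- TRUE
    frontier <- nb[new, , drop = FALSE]
  }
  comp
}

#' Extract the high-significance region from a t-statistic map
#'
#' The region is the connected component, containing the map's maximum, of
#' voxels with `t >= fraction * max t` (isocontour at a fraction of the peak
#' statistic; default 80%).
#'
#' @param tmap A `tstat_map` with `max_t > 0`.
#' @param fraction Isocontour level as a fraction of the maximum.
#' @param connectivity 6 or 26.
#' @return An object of class `dose_region`: logical `mask` array,
#'   `threshold_t`, `connectivity`, `n_voxels`, geometry.
#' @export
extract_region <- function(tmap, fraction = 0.8, connectivity = 26L) {
  stopifnot(inherits(tmap, "tstat_map"))
  if (!is.finite(tmap$max_t) || tmap$max_t <= 0)
    stop("region extraction needs max_t > 0")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  thr <- fraction * tmap$max_t
  cand <- !is.na(tmap$t) & tmap$t >= thr
  mask <- component_containing(cand, tmap$argmax, connectivity)
  structure(list(mask = mask, threshold_t = thr, connectivity = connectivity,
                 n_voxels = sum(mask), dim = tmap$dim,
                 spacing = tmap$spacing, origin = tmap$origin),
            class = "dose_region")
}

#' @export
print.dose_region <- function(x, ...) {
  cat(sprintf("<dose_region> %d voxels at t >= %.3f (%d-connected)\n",
              x$n_voxels, x$threshold_t, x$connectivity))
  invisible(x)
}

#' Per-patient mean dose inside a region
#'
#' Arithmetic mean of the mapped delta-dose and planned dose over the
#' region's voxels for each patient, using each patient's valid voxels; a
#' patient whose valid field misses the region entirely is an error.
#'
#' @param region A `dose_region`.
#' @param delta_maps,planned_maps Voxel-by-patient matrices on the reference
#'   lattice.
#' @param patient_ids Optional patient identifiers.
#' @return Data frame with `patient_id`, `mean_delta_region_gy`,
#'   `mean_planned_region_gy`.
#' @export
region_dose_summary <- function(region, delta_maps, planned_maps = NULL,
                                patient_ids = NULL) {
  stopifnot(inherits(region, "dose_region"))
  rv <- which(as.vector(region$mask))
  if (length(rv) == 0L) stop("region is empty")
  n <- ncol(delta_maps)
  if (is.null(patient_ids)) patient_ids <- sprintf("P%04d", seq_len(n))
  mean_valid <- function(m, i) {
    v <- m[rv, i]
    v <- v[is.finite(v)]
    if (length(v) == 0L)
      stop("region lies fully outside the valid field of patient ",
           patient_ids[i])
    mean(v)
  }
  out <- data.frame(
    patient_id = patient_ids,
    mean_delta_region_gy = vapply(seq_len(n), function(i)
      mean_valid(delta_maps, i), numeric(1)))
  if (!is.null(planned_maps))
    out$mean_planned_region_gy <- vapply(seq_len(n), function(i)
      mean_valid(planned_maps, i), numeric(1))
  out
}

#' Erode a binary mask
#'
#' Morphological erosion with the 6-connected structuring element, applied
#' `iterations` times: a voxel survives if it and all its face neighbours
#' are inside the mask (boundary voxels are treated as outside).
#'
#' @param mask Logical 3-D array.
#' @param iterations Number of erosion passes (0 = unchanged).
#' @return Logical array of the same shape.
#' @export
erode_mask <- function(mask, iterations = 1L) {
  dm <- dim(mask)
  for (it in seq_len(iterations)) {
    out <- mask
    n <- dm[1]
    out[c(1, n), , ] <- FALSE
    out[, c(1, dm[2]), ] <- FALSE
    out[, , c(1, dm[3])] <- FALSE
    out[2:(n - 1), , ] <- out[2:(n - 1), , ] & mask[1:(n - 2), , ] & mask[3:n, , ]
    m <- dm[2]
    out[, 2:(m - 1), ] <- out[, 2:(m - 1), ] & mask[, 1:(m - 2), ] & mask[, 3:m, ]
    k <- dm[3]
    out[, , 2:(k - 1)] <- out[, , 2:(k - 1)] & mask[, , 1:(k - 2)] & mask[, , 3:k]
    mask <- out
  }
  mask
}

#' Dice overlap of two binary masks
#' @param a,b Logical arrays/vectors of equal length.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0L) return(NA_real_)
  2 * sum(a & b) / denom
}
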