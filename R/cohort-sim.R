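#' Synthetic-cohort simulation configuration
#'
#' Defines the study conditions for a synthetic NSCLC-like IGRT cohort:
#' lattice geometry, prescription and fractionation, setup-error magnitudes,
#' and the proportional-hazards generative model for survival. The planted
#' dose-sensitive subregion sits at the heart base and is identical for all
#' patients in reference coordinates.
#'
#' The survival model is Weibull proportional hazards (default shape 1, i.e.
#' exponential) with linear predictor
#' `beta_delta * delta_region * [planned_region in window] +
#'  beta_planned * planned_region + beta_age * (age - 70) +
#'  beta_ecog[ecog] + beta_lngtv * (ln GTV - ln 30)`,
#' where `delta_region`/`planned_region` are the mean delta-dose and planned
#' dose (Gy) in the planted sensitive region. Gating the delta-dose effect by
#' planned region dose inside `dose_threshold_window` plants a recoverable
#' dose threshold for the octile analysis. Default effect sizes take the
#' hazard ratios of the clinical multivariable model (e.g. 1.216 per Gy
#' delta-dose) as generative truth; the baseline exponential median of 18
#' months is a typical stage III NSCLC figure at this prescription.
#'
#' @param n_patients Cohort size (>= 8 for [generate_cohort()]).
#' @param grid_shape Voxel counts per axis (all >= 8).
#' @param spacing Voxel size, mm.
#' @param prescription_dose Prescribed mean GTV dose, Gy.
#' @param n_fractions Number of fractions.
#' @param systematic_sd,random_sd Per-axis setup-error SDs, mm.
#' @param residual_mode Residual series used for accumulation: `"asis"`
#'   (true residuals) or `"locf"` (clinically observable estimate).
#' @param effect_beta_delta Log-hazard per Gy regional delta-dose.
#' @param effect_beta_planned Log-hazard per Gy regional planned dose.
#' @param beta_age Log-hazard per year of age (centred at 70).
#' @param beta_ecog Log-hazard for ECOG-PS levels 1-4 vs 0.
#' @param beta_lngtv Log-hazard per unit ln(GTV) (centred at ln 30 cm^3).
#' @param dose_threshold_window Gy interval in which the delta-dose effect is
#'   active.
#' @param baseline_median_days Baseline median survival.
#' @param weibull_shape Weibull shape (1 = exponential baseline).
#' @param censor_horizon_days Administrative censoring horizon.
#' @param dropout_rate Random-censoring (dropout) hazard per day.
#' @param gtv_meanlog,gtv_sdlog Log-normal GTV volume parameters (cm^3).
#' @param transform_scale_range,transform_offset_sd Patient-to-reference
#'   affine: isotropic scale range and translation SD (mm).
#' @param beam_field_margin Flat field radius = GTV radius + margin (mm),
#'   emulating a PTV margin.
#' @param beam_penumbra_sigma Gaussian penumbra sigma beyond the flat field
#'   edge, mm (a clinical 80-20% penumbra of 6-8 mm corresponds to roughly
#'   5 mm).
#' @param beam_axial_sigma Axial Gaussian envelope sigma, mm.
#' @param body_dose_floor Fraction of the in-air beam value retained outside
#'   the body.
#' @param master_seed Master integer seed for the whole cohort.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 120L,
                       grid_shape = c(64L, 64L, 48L),
                       spacing = c(4, 4, 4),
                       prescription_dose = 55,
                       n_fractions = 20L,
                       systematic_sd = c(2.5, 2.5, 2.5),
                       random_sd = c(2, 2, 2),
                       residual_mode = c("asis", "locf"),
                       effect_beta_delta = log(1.216),
                       effect_beta_planned = log(1.013),
                       beta_age = log(1.013),
                       beta_ecog = log(c(1.314, 1.769, 1.490, 3.291)),
                       beta_lngtv = log(1.456),
                       dose_threshold_window = c(16, 24),
                       baseline_median_days = 548,
                       weibull_shape = 1,
                       censor_horizon_days = 1826,
                       dropout_rate = 1e-4,
                       gtv_meanlog = log(30),
                       gtv_sdlog = 0.6,
                       transform_scale_range = c(0.95, 1.05),
                       transform_offset_sd = 4,
                       beam_field_margin = 8,
                       beam_penumbra_sigma = 5,
                       beam_axial_sigma = 60,
                       body_dose_floor = 0.02,
                       master_seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              grid_shape = as.integer(rep_len(grid_shape, 3L)),
              spacing = rep_len(as.double(spacing), 3L),
              prescription_dose = prescription_dose,
              n_fractions = as.integer(n_fractions),
              systematic_sd = rep_len(as.double(systematic_sd), 3L),
              random_sd = rep_len(as.double(random_sd), 3L),
              residual_mode = match.arg(residual_mode),
              effect_beta_delta = effect_beta_delta,
              effect_beta_planned = effect_beta_planned,
              beta_age = beta_age,
              beta_ecog = rep_len(as.double(beta_ecog), 4L),
              beta_lngtv = beta_lngtv,
              dose_threshold_window = as.double(dose_threshold_window),
              baseline_median_days = baseline_median_days,
              weibull_shape = weibull_shape,
              censor_horizon_days = censor_horizon_days,
              dropout_rate = dropout_rate,
              gtv_meanlog = gtv_meanlog,
              gtv_sdlog = gtv_sdlog,
              transform_scale_range = as.double(transform_scale_range),
              transform_offset_sd = transform_offset_sd,
              beam_field_margin = beam_field_margin,
              beam_penumbra_sigma = beam_penumbra_sigma,
              beam_axial_sigma = beam_axial_sigma,
              body_dose_floor = body_dose_floor,
              master_seed = as.integer(master_seed))
  if (cfg$prescription_dose <= 0) stop("prescription_dose must be > 0")
  if (cfg$n_fractions < 1L) stop("n_fractions must be >= 1")
  if (any(cfg$systematic_sd < 0) || any(cfg$random_sd < 0))
    stop("setup-error SDs must be >= 0")
  structure(cfg, class = "sim_config")
}

grid_geometry <- function(config) {
  dm <- config$grid_shape
  sp <- config$spacing
  list(dim = dm, spacing = sp, origin = -(dm - 1) / 2 * sp, fov = dm * sp)
}

# Voxel-centre coordinate arrays are identical for every patient on a given
# lattice, so the last geometry's arrays are memoised.
.coord_cache <- new.env(parent = emptyenv())

coord_arrays <- function(geom) {
  key <- paste(c(geom$dim, geom$spacing, geom$origin), collapse = ",")
  hit <- get0("key", envir = .coord_cache)
  if (identical(hit, key)) return(get("val", envir = .coord_cache))
  dm <- geom$dim
  xs <- geom$origin[1] + (seq_len(dm[1]) - 1) * geom$spacing[1]
  ys <- geom$origin[2] + (seq_len(dm[2]) - 1) * geom$spacing[2]
  zs <- geom$origin[3] + (seq_len(dm[3]) - 1) * geom$spacing[3]
  val <- list(x = array(rep(xs, times = dm[2] * dm[3]), dm),
              y = array(rep(rep(ys, each = dm[1]), times = dm[3]), dm),
              z = array(rep(zs, each = dm[1] * dm[2]), dm))
  assign("key", key, envir = .coord_cache)
  assign("val", val, envir = .coord_cache)
  val
}

ellipsoid_mask <- function(geom, centre, semiaxes) {
  array(ellipsoid_mask_cpp(geom$dim, geom$spacing, geom$origin,
                           as.double(centre), as.double(semiaxes)),
        geom$dim)
}

mask_com <- function(mask, geom) {
  co <- coord_arrays(geom)
  n <- sum(mask)
  if (n == 0L) return(c(NA_real_, NA_real_, NA_real_))
  c(sum(co$x[mask]), sum(co$y[mask]), sum(co$z[mask])) / n
}

# Reference-frame anatomy parameters, proportional to the field of view so
# the phantom scales with the configured lattice.
reference_params <- function(config) {
  fov <- grid_geometry(config)$fov
  body_c <- c(0, 0, 0)
  body_a <- 0.44 * fov
  heart_c <- c(-0.10, 0.06, -0.18) * fov
  heart_a <- c(0.16, 0.16, 0.18) * fov
  sens_c <- heart_c + c(0.35, 0, -0.45) * heart_a
  sens_a <- 0.38 * heart_a
  list(body_c = body_c, body_a = body_a, heart_c = heart_c,
       heart_a = heart_a, sens_c = sens_c, sens_a = sens_a)
}

build_masks <- function(params, geom) {
  body <- ellipsoid_mask(geom, params$body_c, params$body_a)
  heart <- ellipsoid_mask(geom, params$heart_c, params$heart_a) & body
  sens <- ellipsoid_mask(geom, params$sens_c, params$sens_a) & heart
  gtv <- NULL
  if (!is.null(params$gtv_c)) {
    gtv <- ellipsoid_mask(geom, params$gtv_c, rep(params$gtv_r, 3L)) & body
  }
  list(body = body, heart = heart, sensitive = sens, gtv = gtv)
}

#' Reference-frame anatomy (common lattice for spatial normalisation)
#'
#' The reference anatomy shared by all patients: body and heart ellipsoids
#' plus the planted dose-sensitive sub-ellipsoid at the heart base, on the
#' configured lattice with an identity patient-to-reference transform.
#'
#' @param config A [sim_config()].
#' @return An object of class `anatomy_model` (no GTV).
#' @export
reference_anatomy <- function(config) {
  geom <- grid_geometry(config)
  params <- reference_params(config)
  m <- build_masks(params, geom)
  structure(list(body_mask = m$body, heart_mask = m$heart,
                 sensitive_mask = m$sensitive, gtv_mask = NULL,
                 spacing = geom$spacing, origin = geom$origin,
                 heart_com = mask_com(m$heart, geom),
                 gtv_com = NULL, gtv_volume = NA_real_,
                 params = params,
                 transform = reference_transform(diag(3), c(0, 0, 0)),
                 patient_index = 0L),
            class = "anatomy_model")
}

#' Generate one patient's anatomy
#'
#' Parametric anatomy on the configured lattice: ellipsoidal body, an
#' ellipsoidal heart offset inferior-left, a spherical GTV at a randomised
#' position whose distance to the heart varies across patients, and the
#' planted sensitive subregion at the heart base (fixed in reference
#' coordinates). Each patient carries a known affine (isotropic scale +
#' translation) patient-to-reference transform, standing in for deformable
#' spatial normalisation and making it exactly invertible.
#'
#' @param config A [sim_config()].
#' @param patient_index Positive integer.
#' @param seed Optional integer seed (defaults to a substream of the
#'   config's master seed).
#' @return An object of class `anatomy_model` with binary masks
#'   (`body_mask`, `heart_mask`, `gtv_mask`, `sensitive_mask`), mask centres
#'   of mass (world mm), the sampled GTV volume (cm^3), analytic shape
#'   parameters, and the reference transform.
#' @export
make_anatomy <- function(config, patient_index,
                         seed = derive_seed(config$master_seed, "anatomy",
                                            patient_index)) {
  geom <- grid_geometry(config)
  if (any(geom$dim < 8L))
    stop("degenerate grid: every axis needs >= 8 voxels")
  ref <- reference_params(config)
  with_seed(seed, {
    s <- runif(1L, config$transform_scale_range[1], config$transform_scale_range[2])
    tr <- rnorm(3L, 0, config$transform_offset_sd)
    # GTV position sampled in reference coords, biased superior-right of the
    # sensitive region so target-heart distance varies across patients
    raw <- c(abs(rnorm(1L)) + 0.3, 0.6 * rnorm(1L), abs(rnorm(1L)) + 0.5)
    dir <- raw / sqrt(sum(raw^2))
    d <- runif(1L, 8, 0.45 * max(geom$fov))
    vol_cm3 <- rlnorm(1L, config$gtv_meanlog, config$gtv_sdlog)
  })
  gtv_r <- (3 * vol_cm3 * 1000 / (4 * pi))^(1 / 3)  # cm^3 -> mm^3 -> mm
  v <- d * dir
  # keep the GTV centre well inside the body ellipsoid (metric <= 0.55)
  u <- (ref$sens_c - ref$body_c) / ref$body_a
  w <- v / ref$body_a
  metric_end <- sum((u + w)^2)
  if (metric_end > 0.55) {
    a <- sum(w^2); b <- 2 * sum(u * w); cc <- sum(u^2) - 0.55
    t_max <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
    v <- v * t_max
  }
  gtv_c_ref <- ref$sens_c + v
  # map reference-frame shapes into patient coordinates: x_ref = s x_pat + t
  to_pat <- function(x) (x - tr) / s
  params <- list(body_c = to_pat(ref$body_c), body_a = ref$body_a / s,
                 heart_c = to_pat(ref$heart_c), heart_a = ref$heart_a / s,
                 sens_c = to_pat(ref$sens_c), sens_a = ref$sens_a / s,
                 gtv_c = to_pat(gtv_c_ref), gtv_r = gtv_r / s)
  m <- build_masks(params, geom)
  if (!any(m$gtv)) stop("GTV mask is empty for patient ", patient_index)
  structure(list(body_mask = m$body, heart_mask = m$heart,
                 gtv_mask = m$gtv, sensitive_mask = m$sensitive,
                 spacing = geom$spacing, origin = geom$origin,
                 heart_com = mask_com(m$heart, geom),
                 gtv_com = mask_com(m$gtv, geom),
                 gtv_volume = vol_cm3,
                 params = params,
                 transform = reference_transform(s * diag(3), tr),
                 patient_index = as.integer(patient_index)),
            class = "anatomy_model")
}

#' Generate a planned dose distribution for one patient
#'
#' Superposition of beams intersecting at the GTV centre. Each beam is flat
#' inside its field radius (GTV radius plus a PTV-style margin) and falls
#' off as a Gaussian of the distance beyond the field edge (the penumbra),
#' under a broad axial Gaussian envelope; a zero flat radius recovers a pure
#' Gaussian pencil profile. Dose is attenuated to near zero outside the body
#' and normalised so the mean dose over the GTV equals the prescription.
#'
#' @param anatomy An `anatomy_model` from [make_anatomy()].
#' @param config A [sim_config()].
#' @param beams Optional list of beams, each a list with `dir` (unit
#'   3-vector) and `weight`, or a bare direction vector (weight 1). The
#'   default is a patient-specific 5-field coplanar arrangement (anterior,
#'   50-degree and 110-degree oblique pairs, each gantry angle jittered by
#'   up to 12 degrees) with relative weights drawn uniformly from 0.6-1.4,
#'   emulating individually optimised conformal lung plans. Without this
#'   per-patient variation the away-from-target dose would be quantized at
#'   multiples of the per-beam dose, which no real planning system produces.
#' @return A `dose_grid`.
#' @export
make_planned_dose <- function(anatomy, config, beams = NULL) {
  if (is.null(beams)) {
    beams <- with_seed(
      derive_seed(config$master_seed, "beams", anatomy$patient_index), {
        th <- (c(0, 50, -50, 110, -110) + runif(5L, -12, 12)) * pi / 180
        w <- runif(5L, 0.6, 1.4)
        lapply(1:5, function(k)
          list(dir = c(sin(th[k]), cos(th[k]), 0), weight = w[k]))
      })
  }
  geom <- list(dim = dim(anatomy$body_mask), spacing = anatomy$spacing,
               origin = anatomy$origin)
  beams <- lapply(beams, function(b) {
    if (!is.list(b)) b <- list(dir = b, weight = 1)
    b$dir <- b$dir / sqrt(sum(b$dir^2))
    b
  })
  dirs <- do.call(rbind, lapply(beams, `[[`, "dir"))
  wts <- vapply(beams, `[[`, numeric(1), "weight")
  vals <- beam_dose_cpp(geom$dim, geom$spacing, geom$origin,
                        anatomy$params$gtv_c,
                        anatomy$params$gtv_r + config$beam_field_margin,
                        config$beam_penumbra_sigma, config$beam_axial_sigma,
                        dirs, wts, anatomy$params$body_c,
                        anatomy$params$body_a, config$body_dose_floor)
  dose <- array(vals, geom$dim)
  if (is.null(anatomy$gtv_mask) || !any(anatomy$gtv_mask))
    stop("cannot normalise: GTV mask is empty")
  dose <- dose * (config$prescription_dose / mean(dose[anatomy$gtv_mask]))
  dose_grid(dose, anatomy$spacing, anatomy$origin)
}

#' Simulate clinical covariates
#'
#' Age, gender, ECOG performance status, overall/T/N stage and histology
#' with marginal distributions typical of a curative-intent NSCLC cohort.
#' GTV volume is attached by [generate_cohort()] from the sampled anatomy.
#'
#' @param config A [sim_config()].
#' @param n Number of patients.
#' @param seed Optional integer seed.
#' @return A data frame of covariates.
#' @export
simulate_covariates <- function(config, n = config$n_patients, seed = NULL) {
  with_seed(seed, {
    data.frame(
      age = round(pmin(pmax(rnorm(n, 70, 8), 40), 92), 1),
      gender = factor(sample(c("male", "female"), n, TRUE, c(0.55, 0.45))),
      ecog_ps = sample(0:4, n, TRUE, c(0.25, 0.45, 0.20, 0.08, 0.02)),
      overall_stage = factor(sample(c("I", "II", "III", "IV"), n, TRUE,
                                    c(0.10, 0.15, 0.60, 0.15)),
                             levels = c("I", "II", "III", "IV")),
      t_stage = factor(sample(1:4, n, TRUE, c(0.15, 0.25, 0.35, 0.25))),
      n_stage = factor(sample(0:3, n, TRUE, c(0.25, 0.15, 0.40, 0.20))),
      histology = factor(sample(c("squamous", "adeno", "other"), n, TRUE,
                                c(0.35, 0.40, 0.25)))
    )
  })
}

#' Simulate survival outcomes under the generative hazard model
#'
#' Weibull (default exponential) proportional-hazards times with the linear
#' predictor described in [sim_config()]; the regional delta-dose effect is
#' active only when the planned region dose lies inside the configured
#' threshold window. Follow-up is censored administratively at the horizon
#' and by random dropout.
#'
#' @param clin Data frame with `age`, `ecog_ps`, `gtv_cm3`.
#' @param planned_region_dose,delta_region_dose Per-patient mean planned and
#'   delta dose in the sensitive region, Gy.
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return Data frame with `surv_days`, `event` (0/1), `one_year_status`
#'   (factor: alive / dead / indeterminate).
#' @export
simulate_survival <- function(clin, planned_region_dose, delta_region_dose,
                              config, seed = NULL) {
  n <- nrow(clin)
  w <- config$dose_threshold_window
  gate <- as.numeric(planned_region_dose >= w[1] & planned_region_dose <= w[2])
  ecog_eff <- c(0, config$beta_ecog)[clin$ecog_ps + 1L]
  lp <- config$effect_beta_delta * delta_region_dose * gate +
    config$effect_beta_planned * planned_region_dose +
    config$beta_age * (clin$age - 70) +
    ecog_eff +
    config$beta_lngtv * (log(clin$gtv_cm3) - log(30))
  if (any(!is.finite(lp)))
    stop("non-finite linear predictor for patient(s) ",
         paste(utils::head(which(!is.finite(lp))), collapse = ", "))
  shape <- config$weibull_shape
  lambda <- log(2)^(1 / shape) / config$baseline_median_days
  with_seed(seed, {
    e <- rexp(n)
    t_event <- (e / exp(lp))^(1 / shape) / lambda
    t_cens <- if (config$dropout_rate > 0) rexp(n, config$dropout_rate) else Inf
    time <- pmin(t_event, t_cens, config$censor_horizon_days)
    event <- as.integer(t_event <= pmin(t_cens, config$censor_horizon_days))
    status <- ifelse(event == 1L & time < 365.25, "dead",
                     ifelse(time >= 365.25, "alive", "indeterminate"))
    data.frame(surv_days = time, event = event,
               one_year_status = factor(status,
                                        levels = c("alive", "dead",
                                                   "indeterminate")))
  })
}

#' Generate a complete synthetic cohort
#'
#' Runs the per-patient chain (anatomy, planned dose, setup errors under the
#' IGRT protocol, shift-invariant accumulation, delta-dose, mapping onto the
#' reference lattice) and simulates covariates and survival whose hazard
#' depends on the accumulated dose inside the planted sensitive heart
#' subregion. Fully deterministic given `config$master_seed`.
#'
#' @param config A [sim_config()].
#' @param protocol An [igrt_protocol()]; defaults to the standard schedule
#'   for the configured course.
#' @param keep_maps Keep per-patient reference-lattice delta and planned
#'   dose stacks (needed for data-mining; drop for survival-only studies).
#' @param keep_planned Also map the planned dose onto the reference lattice
#'   (needed for mined-region planned-dose summaries; delta-only studies can
#'   drop it).
#' @param qa_tolerance Spatial-normalisation QA tolerance, mm: patients whose
#'   mapped heart centre of mass deviates more are flagged `qa_passed = FALSE`.
#' @param write_dir Optional directory: writes per-patient NIfTI volumes,
#'   the clinical and fraction-record CSVs, the reference sensitive mask and
#'   a provenance JSON.
#' @return An object of class `igrt_cohort`: `clinical` (data frame),
#'   `delta_ref`/`planned_ref` (voxel-by-patient matrices on the reference
#'   lattice, `NA` = out of field), `reference` (anatomy), `records`
#'   (fraction records), `transforms`, `config`, `protocol`, `provenance`.
#' @export
generate_cohort <- function(config, protocol = NULL, keep_maps = TRUE,
                            keep_planned = keep_maps, qa_tolerance = 10,
                            write_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  if (n < 8L) stop("n_patients must be >= 8")
  if (is.null(protocol))
    protocol <- igrt_protocol(n_fractions = config$n_fractions)
  geom <- grid_geometry(config)
  ref <- reference_anatomy(config)
  nv <- prod(geom$dim)
  ids <- sprintf("P%04d", seq_len(n))

  covs <- simulate_covariates(config, n,
                              seed = derive_seed(config$master_seed, "covariates"))
  delta_ref <- if (keep_maps) matrix(NA_real_, nv, n) else NULL
  planned_ref <- if (keep_maps && keep_planned) matrix(NA_real_, nv, n) else NULL
  transforms <- vector("list", n)
  rec_list <- vector("list", n)
  gtv_cm3 <- planned_sens <- delta_sens <- heart_shift <- qa_dev <- numeric(n)
  keep_vols <- !is.null(write_dir)
  if (keep_vols) dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)

  for (i in seq_len(n)) {
    anat <- make_anatomy(config, i)
    planned <- make_planned_dose(anat, config)
    rec <- sample_fraction_errors(config$systematic_sd, config$random_sd,
                                  config$n_fractions,
                                  seed = derive_seed(config$master_seed,
                                                     "errors", i))
    rec <- apply_igrt_protocol(rec, protocol)
    res <- residual_series(rec, config$residual_mode)
    acc <- accumulate_dose(planned, res)
    dd <- delta_dose(acc, planned)

    sm <- anat$sensitive_mask
    planned_sens[i] <- mean(planned$values[sm])
    delta_sens[i] <- mean(dd$values[sm])
    gtv_cm3[i] <- anat$gtv_volume
    heart_shift[i] <- summarise_course(rec, anatomy = anat)$mean_heart_shift
    tf <- anat$transform
    mapped_heart <- as.vector(tf$A %*% anat$heart_com + tf$t)
    qa_dev[i] <- sqrt(sum((mapped_heart - ref$heart_com)^2))
    transforms[[i]] <- tf
    rec$patient_id <- ids[i]
    rec_list[[i]] <- rec

    if (keep_maps) {
      delta_ref[, i] <- as.vector(
        map_to_reference(dd, tf, ref_geometry = geom)$values)
      if (!is.null(planned_ref))
        planned_ref[, i] <- as.vector(
          map_to_reference(planned, tf, ref_geometry = geom)$values)
    }
    if (keep_vols) {
      write_volume(planned, file.path(write_dir,
                                      sprintf("planned_%s.nii", ids[i])))
      write_volume(dd, file.path(write_dir, sprintf("delta_%s.nii", ids[i])))
      hm <- anat$heart_mask
      attr(hm, "spacing") <- anat$spacing; attr(hm, "origin") <- anat$origin
      write_volume(hm, file.path(write_dir, sprintf("heart_%s.nii", ids[i])))
    }
  }

  surv <- simulate_survival(
    data.frame(age = covs$age, ecog_ps = covs$ecog_ps, gtv_cm3 = gtv_cm3),
    planned_sens, delta_sens, config,
    seed = derive_seed(config$master_seed, "survival"))

  clinical <- cbind(data.frame(patient_id = ids), covs,
                    data.frame(gtv_cm3 = gtv_cm3,
                               mean_planned_sens_gy = planned_sens,
                               mean_delta_sens_gy = delta_sens,
                               mean_heart_shift_mm = heart_shift,
                               heart_com_deviation_mm = qa_dev,
                               qa_passed = qa_dev <= qa_tolerance),
                    surv)
  records <- do.call(rbind, rec_list)
  provenance <- list(master_seed = config$master_seed,
                     config = unclass(config),
                     effect_sizes = list(
                       beta_delta = config$effect_beta_delta,
                       beta_planned = config$effect_beta_planned,
                       dose_threshold_window = config$dose_threshold_window),
                     sensitive_region_file = "sensitive_reference.nii")
  cohort <- structure(list(clinical = clinical, delta_ref = delta_ref,
                           planned_ref = planned_ref, reference = ref,
                           records = records, transforms = transforms,
                           geometry = geom, config = config,
                           protocol = protocol, provenance = provenance),
                      class = "igrt_cohort")
  if (keep_vols) {
    sm <- ref$sensitive_mask
    attr(sm, "spacing") <- ref$spacing; attr(sm, "origin") <- ref$origin
    write_volume(sm, file.path(write_dir, "sensitive_reference.nii"))
    write.csv(clinical, file.path(write_dir, "clinical.csv"), row.names = FALSE)
    write.csv(records, file.path(write_dir, "fraction_records.csv"),
              row.names = FALSE)
    jsonlite::write_json(provenance, file.path(write_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  cohort
}

#' @export
print.igrt_cohort <- function(x, ...) {
  cat(sprintf("<igrt_cohort> %d patients, %s grid @ %s mm, %d deaths (%d at 1 yr)\n",
              nrow(x$clinical), paste(x$geometry$dim, collapse = "x"),
              paste(format(x$geometry$spacing), collapse = "x"),
              sum(x$clinical$event),
              sum(x$clinical$one_year_status == "dead")))
  invisible(x)
}
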