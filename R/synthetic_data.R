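#' Synthetic cohort, BOLD and qPCR data with known ground truth
#'
#' Generators that emulate a three-group hypertension/cognition study:
#' a demographic cohort table with group imbalance, resting-state BOLD
#' series carrying a shared low-frequency (0.02-0.04 Hz) vasomotor
#' component scaled voxel-wise by a known cerebrovascular reactivity
#' (CVR) field, qPCR Ct panels with planted group shifts, and cognitive
#' outcomes generated under a known mediated causal structure
#' (X -> M -> Y with covariates). Every generator is fully determined by
#' `config$seed`; ground truth is returned alongside the data so that
#' downstream estimators can be tested for parameter recovery.
#'
#' @name synthetic-data
NULL

#' Group labels used throughout the package
#' @export
COHORT_GROUPS <- c("control", "HT-NC", "HT-CI")

# fixed offsets deriving per-purpose sub-streams from one dataset seed
.SEED_OFFSETS <- c(cohort = 101L, vasomotor = 199L, bold = 211L,
                   ct = 307L, mediation = 401L, cvr_field = 503L)

.substream <- function(seed, purpose) {
  off <- .SEED_OFFSETS[[purpose]]
  set.seed((as.integer(seed) + off) %% .Machine$integer.max)
}

#' Simulation configuration
#'
#' Defaults mirror the cohort structure and acquisition parameters of the
#' emulated study: group sizes 37/67/73 (control, HT-NC, HT-CI), TR 2 s,
#' 240 volumes (8 min), 3 mm voxels on a 16 x 16 x 8 grid with an
#' ellipsoidal brain mask, a vasomotor component band-limited to
#' 0.022-0.038 Hz, and qPCR shifts that halve or nearly halve candidate
#' miRNA expression in the affected groups.
#'
#' @param n_per_group integer vector of group sizes, named or in the order
#'   control, HT-NC, HT-CI.
#' @param tr repetition time, seconds.
#' @param n_volumes number of BOLD time points.
#' @param grid_shape 3 voxel dimensions.
#' @param voxel_size voxel edge lengths, mm.
#' @param vasomotor_range frequency range (Hz) the shared vasomotor signal
#'   is drawn from; must lie strictly inside (0.02, 0.04).
#' @param n_vasomotor_components number of sinusoids summed into g(t).
#' @param cvr_field_spec list with `baseline` and `bumps` (each bump a list
#'   with `center_frac`, `sigma_vox`, `amplitude`) describing the true CVR
#'   field in relative units.
#' @param group_cvr_effect per-group additive CVR change (relative units)
#'   applied inside the first bump's region, emulating a focal group deficit.
#' @param noise_sd white-noise SD of the BOLD series (signal units; the
#'   vasomotor component has unit variance).
#' @param mediation_paths named numeric vector `c(a=, b=, c_prime=)`.
#' @param mediation_noise_sd named numeric vector `c(m=, y=)`.
#' @param ct_effects named list: per miRNA, a length-3 numeric vector of
#'   group mean Ct shifts (control, HT-NC, HT-CI). +1 Ct halves expression.
#' @param ct_baseline,ct_sd baseline Ct level and subject-level Ct SD.
#' @param ref_ct_mean,ref_ct_sd spike-in (cel-miR-39) Ct mean and SD.
#' @param seed integer seed; fully determines all outputs.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = c(control = 37L, `HT-NC` = 67L, `HT-CI` = 73L),
                       tr = 2,
                       n_volumes = 240L,
                       grid_shape = c(16L, 16L, 8L),
                       voxel_size = c(3, 3, 3),
                       vasomotor_range = c(0.022, 0.038),
                       n_vasomotor_components = 3L,
                       cvr_field_spec = default_cvr_field_spec(),
                       group_cvr_effect = c(control = 0, `HT-NC` = -0.1, `HT-CI` = -0.4),
                       noise_sd = 0.5,
                       mediation_paths = c(a = 0.5, b = 0.4, c_prime = 0.1),
                       mediation_noise_sd = c(m = 1, y = 1),
                       ct_effects = default_ct_effects(),
                       ct_baseline = 26,
                       ct_sd = 0.8,
                       ref_ct_mean = 20,
                       ref_ct_sd = 0.3,
                       seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  if (length(n_per_group) != 3L || any(n_per_group < 2L))
    stop("sim_config: need three group sizes, each >= 2")
  names(n_per_group) <- COHORT_GROUPS
  if (n_volumes * tr < 2 / 0.02)
    stop("sim_config: n_volumes * tr too short to resolve 0.02 Hz (need >= 100 s)")
  if (vasomotor_range[1] <= 0.02 || vasomotor_range[2] >= 0.04 ||
      vasomotor_range[1] >= vasomotor_range[2])
    stop("sim_config: vasomotor_range must lie strictly inside (0.02, 0.04) Hz")
  if (noise_sd < 0 || any(mediation_noise_sd <= 0) || ct_sd <= 0 || ref_ct_sd <= 0)
    stop("sim_config: noise SDs must be positive (BOLD noise_sd may be 0)")
  if (is.null(names(ct_effects)) || any(!nzchar(names(ct_effects))))
    stop("sim_config: ct_effects must be a named list of per-miRNA group shifts")
  structure(list(
    n_per_group = n_per_group, tr = tr, n_volumes = as.integer(n_volumes),
    grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
    vasomotor_range = vasomotor_range,
    n_vasomotor_components = as.integer(n_vasomotor_components),
    cvr_field_spec = cvr_field_spec, group_cvr_effect = group_cvr_effect,
    noise_sd = noise_sd, mediation_paths = mediation_paths,
    mediation_noise_sd = mediation_noise_sd, ct_effects = ct_effects,
    ct_baseline = ct_baseline, ct_sd = ct_sd,
    ref_ct_mean = ref_ct_mean, ref_ct_sd = ref_ct_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_cvr_field_spec <- function() {
  list(baseline = 1,
       bumps = list(
         list(center_frac = c(0.30, 0.70, 0.50), sigma_vox = 2.5, amplitude = 0.5),
         list(center_frac = c(0.70, 0.30, 0.50), sigma_vox = 2.5, amplitude = -0.4)))
}

#' @rdname sim_config
#' @export
default_ct_effects <- function() {
  # +Ct = lower expression; defaults emulate the validated candidate pattern:
  # mir-330-3p / mir-432-5p / mir-625-3p reduced in HT-CI, mir-6852-3p raised
  # in both hypertensive groups, plus one null miRNA.
  list(mir_330_3p  = c(0, 0, 1.0),
       mir_432_5p  = c(0, 0, 0.6),
       mir_625_3p  = c(0, 0.5, 0.7),
       mir_6852_3p = c(0, -0.6, -0.6),
       mir_null    = c(0, 0, 0))
}

#' Ellipsoidal brain mask for a simulation grid
#'
#' @param grid_shape 3 voxel dimensions.
#' @param radius_frac semi-axis lengths as a fraction of each half-dimension.
#' @return 3D logical array.
#' @export
ellipsoid_mask <- function(grid_shape, radius_frac = 0.9) {
  d <- grid_shape
  cx <- (d + 1) / 2
  r <- d / 2 * radius_frac
  ii <- slice.index(array(0, d), 1)
  jj <- slice.index(array(0, d), 2)
  kk <- slice.index(array(0, d), 3)
  ((ii - cx[1]) / r[1])^2 + ((jj - cx[2]) / r[2])^2 + ((kk - cx[3]) / r[3])^2 <= 1
}

.gaussian_bump <- function(grid_shape, center_frac, sigma_vox) {
  d <- grid_shape
  ctr <- 1 + center_frac * (d - 1)
  ii <- slice.index(array(0, d), 1)
  jj <- slice.index(array(0, d), 2)
  kk <- slice.index(array(0, d), 3)
  exp(-((ii - ctr[1])^2 + (jj - ctr[2])^2 + (kk - ctr[3])^2) / (2 * sigma_vox^2))
}

#' True CVR field from a field spec
#'
#' Baseline plus smooth Gaussian bumps; clamped to a small positive floor so
#' relative CVR stays well defined.
#'
#' @param config a [sim_config()].
#' @param mask optional logical mask; defaults to [ellipsoid_mask()].
#' @return list with `cvr_true` (3D array, NA outside mask), `mask`, and
#'   `region` (logical array marking the first bump's focal region used for
#'   planted group effects).
#' @export
make_cvr_field <- function(config, mask = NULL) {
  spec <- config$cvr_field_spec
  d <- config$grid_shape
  if (is.null(mask)) mask <- ellipsoid_mask(d)
  field <- array(spec$baseline, d)
  region <- array(FALSE, d)
  for (i in seq_along(spec$bumps)) {
    b <- spec$bumps[[i]]
    g <- .gaussian_bump(d, b$center_frac, b$sigma_vox)
    field <- field + b$amplitude * g
    if (i == 1L) region <- g > 0.5 & mask
  }
  field <- pmax(field, 0.05)
  field[!mask] <- NA_real_
  list(cvr_true = field, mask = mask, region = region)
}

#' Shared band-limited vasomotor signal g(t)
#'
#' Sum of `n_vasomotor_components` sinusoids with frequencies drawn
#' uniformly in `vasomotor_range` and random phases, normalized to zero
#' mean and unit variance.
#'
#' @param config a [sim_config()].
#' @param seed optional override of the derived sub-stream seed.
#' @return numeric vector of length `n_volumes`.
#' @export
simulate_vasomotor <- function(config, seed = NULL) {
  if (is.null(seed)) .substream(config$seed, "vasomotor") else set.seed(seed)
  n <- config$n_volumes
  t_s <- (seq_len(n) - 1) * config$tr
  fr <- config$vasomotor_range
  k <- config$n_vasomotor_components
  freqs <- stats::runif(k, fr[1], fr[2])
  phases <- stats::runif(k, 0, 2 * pi)
  g <- rowSums(vapply(seq_len(k),
                      function(i) sin(2 * pi * freqs[i] * t_s + phases[i]),
                      numeric(n)))
  g <- g - mean(g)
  g / stats::sd(g)
}

#' Simulate a 4D BOLD series from a true CVR field
#'
#' Each in-mask voxel time course is `baseline + cvr_true[v] * g(t) + noise`,
#' with `g(t)` shared across voxels and white Gaussian noise of SD
#' `config$noise_sd`. Out-of-mask voxels are zero.
#'
#' @param cvr_true 3D array of per-voxel vasomotor amplitudes (NA outside
#'   mask allowed).
#' @param config a [sim_config()].
#' @param mask logical 3D array; defaults to `!is.na(cvr_true)`.
#' @param g optional externally supplied vasomotor time course.
#' @param baseline additive signal offset (exercises detrending/intercepts).
#' @param seed optional override of the derived sub-stream seed.
#' @return object of class `bold_series`: list with `data` (4D), `tr`,
#'   `mask`, `voxel_size`, `affine`, and the generating signal `g`.
#' @export
simulate_bold <- function(cvr_true, config, mask = NULL, g = NULL,
                          baseline = 1000, seed = NULL) {
  d <- config$grid_shape
  if (!identical(dim(cvr_true), as.integer(d)))
    stop("simulate_bold: cvr_true shape does not match config$grid_shape")
  if (is.null(mask)) mask <- !is.na(cvr_true)
  if (!any(mask)) stop("simulate_bold: empty mask")
  if (is.null(g)) g <- simulate_vasomotor(config)
  if (is.null(seed)) .substream(config$seed, "bold") else set.seed(seed)
  n_t <- config$n_volumes
  nv <- sum(mask)
  amp <- cvr_true[mask]
  sig <- outer(amp, g)                      # voxels x time
  if (config$noise_sd > 0)
    sig <- sig + matrix(stats::rnorm(nv * n_t, sd = config$noise_sd), nv, n_t)
  data <- array(0, c(d, n_t))
  flat <- matrix(data, prod(d), n_t)
  flat[as.vector(mask), ] <- baseline + sig
  data <- array(flat, c(d, n_t))
  affine <- rbind(cbind(diag(config$voxel_size), 0), c(0, 0, 0, 1))
  structure(list(data = data, tr = config$tr, mask = mask,
                 voxel_size = config$voxel_size, affine = affine, g = g),
            class = "bold_series")
}

# group-level generative parameters for the cohort table; means/SDs follow
# the emulated study's demographics, cognitive scores are on natural scales
.COHORT_PARAMS <- list(
  age        = list(mean = c(58.5, 63.9, 66.0), sd = c(7.2, 8.2, 8.2)),
  education  = list(mean = c(13.0, 12.0, 11.1), sd = c(4.5, 3.6, 3.6)),
  p_male     = c(19 / 37, 38 / 67, 37 / 73),
  p_lacunar  = c(0.16, 0.19, 0.36),
  wmh_meanlog = log(c(1.5, 4.4, 5.6)) - 0.5, wmh_sdlog = 1,
  tests = list(
    #            mean    sd   ci_shift  (shift applied to HT-CI only;
    #                                    timed tests: positive = slower)
    mmse     = c(28.0,  1.5,  -3.0),
    moca     = c(27.0,  2.0,  -5.0),
    vr_dr    = c(10.0,  3.0,  -3.0),
    avlt_dr  = c( 8.0,  2.5,  -2.5),
    tmt_a    = c(45.0, 12.0,  15.0),
    tmt_b    = c(100., 25.0,  30.0),
    scwt_a   = c(30.0,  8.0,   8.0),
    stroop_c = c(60.0, 15.0,  15.0),
    cvf      = c(18.0,  4.0,  -4.0),
    bnt      = c(24.0,  3.0,  -3.0),
    vr_copy  = c(13.0,  1.5,  -2.0),
    cdt      = c( 3.5,  0.6,  -1.0)
  ),
  timed = c("tmt_a", "tmt_b", "scwt_a", "stroop_c")
)

#' Generate a synthetic cohort table
#'
#' Subjects in three groups with demographic imbalance (older, less
#' educated, more lacunar strokes in the hypertensive groups), binary
#' lacunar-stroke history, log-normal WMH volumes, and raw
#' neuropsychological scores on their natural scales (timed tests in
#' seconds, higher = slower) with deficits planted in the HT-CI group.
#'
#' @param config a [sim_config()].
#' @param seed optional override of the derived sub-stream seed.
#' @return data.frame with one row per subject; group is a factor with
#'   levels `control`, `HT-NC`, `HT-CI`.
#' @export
generate_cohort <- function(config, seed = NULL) {
  if (!inherits(config, "sim_config")) stop("generate_cohort: need a sim_config")
  if (is.null(seed)) .substream(config$seed, "cohort") else set.seed(seed)
  n <- config$n_per_group
  gidx <- rep(1:3, times = n)
  N <- sum(n)
  p <- .COHORT_PARAMS
  df <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(N)),
    group = factor(COHORT_GROUPS[gidx], levels = COHORT_GROUPS),
    sex = ifelse(stats::runif(N) < p$p_male[gidx], "male", "female"),
    age = round(stats::rnorm(N, p$age$mean[gidx], p$age$sd[gidx]), 1),
    education_years = pmax(0L, round(stats::rnorm(N, p$education$mean[gidx],
                                                  p$education$sd[gidx]))),
    lacunar_stroke = as.integer(stats::runif(N) < p$p_lacunar[gidx]),
    wmh_volume_ml = round(stats::rlnorm(N, p$wmh_meanlog[gidx], p$wmh_sdlog), 2),
    stringsAsFactors = FALSE
  )
  ci <- gidx == 3L
  for (test in names(p$tests)) {
    par <- p$tests[[test]]
    x <- stats::rnorm(N, par[1], par[2]) + ifelse(ci, par[3], 0)
    if (test %in% c("mmse", "moca")) x <- pmin(30, pmax(0, round(x)))
    else if (test == "cdt") x <- pmin(4, pmax(0, round(x * 2) / 2))
    else if (test %in% p$timed) x <- pmax(5, round(x, 1))
    else x <- pmax(0, round(x, 1))
    df[[test]] <- x
  }
  df
}

#' Simulate a qPCR Ct panel
#'
#' Per-subject Ct values for each miRNA named in `config$ct_effects`
#' (baseline + group mean shift + noise) plus the cel-miR-39 spike-in
#' reference column. A +1 Ct shift halves 2^-deltaCt expression.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param config a [sim_config()].
#' @param seed optional override of the derived sub-stream seed.
#' @return data.frame: `subject_id`, `group`, one Ct column per miRNA, and
#'   `cel_mir_39`.
#' @export
simulate_ct_panel <- function(cohort, config, seed = NULL) {
  if (is.null(seed)) .substream(config$seed, "ct") else set.seed(seed)
  gidx <- as.integer(cohort$group)
  N <- nrow(cohort)
  out <- data.frame(subject_id = cohort$subject_id, group = cohort$group,
                    stringsAsFactors = FALSE)
  for (mir in names(config$ct_effects)) {
    shift <- config$ct_effects[[mir]]
    if (length(shift) != 3L)
      stop("simulate_ct_panel: ct_effects[['", mir, "']] must have 3 group shifts")
    out[[mir]] <- round(config$ct_baseline + shift[gidx] +
                          stats::rnorm(N, sd = config$ct_sd), 3)
  }
  out$cel_mir_39 <- round(stats::rnorm(N, config$ref_ct_mean, config$ref_ct_sd), 3)
  out
}

#' Attach mediator and outcome columns with a known causal structure
#'
#' Generates `m = a*x + covariate effects + noise_m` and
#' `y = c_prime*x + b*m + covariate effects + noise_y`, with small fixed
#' age/education covariate effects, so the true indirect effect `a*b` is
#' known exactly.
#'
#' @param cohort data.frame containing `x_col` plus `age` and
#'   `education_years`.
#' @param x_col name of the exposure column.
#' @param m_col,y_col names of the mediator/outcome columns to create.
#' @param config a [sim_config()] (supplies paths, noise SDs and seed).
#' @param covariate_effects named numeric vector of per-unit effects of
#'   `age` and `education_years` on both m and y.
#' @param seed optional override of the derived sub-stream seed.
#' @return the cohort with `m_col` and `y_col` added; attribute
#'   `ground_truth` holds `a`, `b`, `c_prime` and `indirect_true = a*b`.
#' @export
attach_mediation_outcome <- function(cohort, x_col, m_col = "mediator_sim",
                                     y_col = "outcome_sim", config,
                                     covariate_effects = c(age = -0.01,
                                                           education_years = 0.02),
                                     seed = NULL) {
  if (!x_col %in% names(cohort))
    stop("attach_mediation_outcome: missing x column ", x_col)
  if (is.null(seed)) .substream(config$seed, "mediation") else set.seed(seed)
  paths <- config$mediation_paths
  nsd <- config$mediation_noise_sd
  N <- nrow(cohort)
  x <- cohort[[x_col]]
  cov_term <- covariate_effects[["age"]] * cohort$age +
    covariate_effects[["education_years"]] * cohort$education_years
  m <- paths[["a"]] * x + cov_term + stats::rnorm(N, sd = nsd[["m"]])
  y <- paths[["c_prime"]] * x + paths[["b"]] * m + cov_term +
    stats::rnorm(N, sd = nsd[["y"]])
  cohort[[m_col]] <- m
  cohort[[y_col]] <- y
  attr(cohort, "ground_truth") <- list(
    a = unname(paths[["a"]]), b = unname(paths[["b"]]),
    c_prime = unname(paths[["c_prime"]]),
    indirect_true = unname(paths[["a"]] * paths[["b"]]),
    x_col = x_col, m_col = m_col, y_col = y_col)
  cohort
}

#' Write a complete synthetic dataset to disk
#'
#' Produces everything the end-to-end pipeline consumes: per-subject 4D
#' BOLD NIfTI files, the brain mask, the cohort CSV, the Ct panel CSV, and
#' a ground-truth sidecar (YAML + true-CVR NIfTI). Subject CVR fields are
#' the shared true field plus a focal group effect
#' (`config$group_cvr_effect`) inside the first bump region, a
#' miRNA-driven component (path `a` of `config$mediation_paths`, scaled by
#' the subject's centred log2 expression of the first miRNA in
#' `ct_effects`), and smooth subject-level variation. Executive-function
#' raw scores are additionally driven by the subject's true region CVR
#' (path `b`) and the miRNA level (path `c_prime`), planting a mediated
#' X -> M -> Y chain that the full pipeline should recover.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with the paths written and the ground truth.
#' @export
simulate_dataset <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "bold"), showWarnings = FALSE)
  field <- make_cvr_field(config)
  cohort <- generate_cohort(config)
  ct <- simulate_ct_panel(cohort, config)
  x_mir <- names(config$ct_effects)[1]
  x <- -(ct[[x_mir]] - ct$cel_mir_39)            # log2 expression = -deltaCt
  x_std <- as.vector(scale(x))

  .substream(config$seed, "cvr_field")
  N <- nrow(cohort)
  gidx <- as.integer(cohort$group)
  geff <- config$group_cvr_effect[gidx]
  a <- config$mediation_paths[["a"]]
  b <- config$mediation_paths[["b"]]
  c_prime <- config$mediation_paths[["c_prime"]]
  # X -> M: path `a` couples standardized miRNA level to region CVR in
  # relative units (0.3 r.u. per SD at a = 1); subject noise 0.08 r.u.
  subj_dev <- stats::rnorm(N, sd = 0.08)
  region_delta <- geff + 0.3 * a * x_std + subj_dev
  region <- field$region
  mask <- field$mask

  m_true <- numeric(N)
  bold_paths <- character(N)
  d <- config$grid_shape
  for (i in seq_len(N)) {
    cvr_i <- field$cvr_true
    # smooth subject-specific CVR variation across the whole brain (real
    # subjects differ everywhere, not only in the focal region)
    svar <- smooth_volume(array(stats::rnorm(prod(d)), d), 9,
                          config$voxel_size)
    svar <- svar / stats::sd(svar[mask]) * 0.1
    cvr_i[mask] <- pmax(cvr_i[mask] + svar[mask], 0.05)
    cvr_i[region] <- pmax(cvr_i[region] + region_delta[i], 0.05)
    m_true[i] <- mean(cvr_i[region])
    bold <- simulate_bold(cvr_i, config, mask = mask,
                          seed = (config$seed * 1000L + i) %% .Machine$integer.max)
    bold_paths[i] <- file.path(out_dir, "bold",
                               paste0(cohort$subject_id[i], ".nii.gz"))
    write_nifti(bold$data, bold_paths[i], voxel_size = config$voxel_size,
                tr = config$tr)
  }

  # M -> Y: shift executive constituents by b * (true region CVR, in SD
  # units) + c' * x, plus outcome noise; at b = 1 one SD of region CVR
  # moves the executive shift by one SD-equivalent of each raw test
  .substream(config$seed + 7L, "mediation")
  m_dev <- m_true - mean(m_true)
  m_sd <- stats::sd(m_true)
  if (m_sd > 0) m_dev <- m_dev / m_sd
  exec_eff <- b * m_dev + c_prime * x_std +
    stats::rnorm(N, sd = config$mediation_noise_sd[["y"]] * 0.15)
  cohort$cvf <- pmax(0, cohort$cvf + 4 * exec_eff)
  cohort$tmt_a <- pmax(5, cohort$tmt_a - 12 * exec_eff)
  cohort$tmt_b <- pmax(5, cohort$tmt_b - 25 * exec_eff)
  cohort$stroop_c <- pmax(5, cohort$stroop_c - 15 * exec_eff)

  mask_path <- file.path(out_dir, "mask.nii.gz")
  write_nifti(array(as.numeric(mask), dim(mask)), mask_path,
              voxel_size = config$voxel_size)
  truth_cvr_path <- file.path(out_dir, "cvr_true.nii.gz")
  tc <- field$cvr_true; tc[!mask] <- 0
  write_nifti(tc, truth_cvr_path, voxel_size = config$voxel_size)
  region_path <- file.path(out_dir, "region_true.nii.gz")
  write_nifti(array(as.numeric(region), dim(region)), region_path,
              voxel_size = config$voxel_size)
  cohort_path <- file.path(out_dir, "cohort.csv")
  utils::write.csv(cohort, cohort_path, row.names = FALSE)
  ct_path <- file.path(out_dir, "ct_panel.csv")
  utils::write.csv(ct, ct_path, row.names = FALSE)

  truth <- list(
    seed = config$seed,
    cvr_true_mean_in_mask = mean(field$cvr_true[mask]),
    group_cvr_effect = as.list(config$group_cvr_effect),
    mediation = list(a = unname(a), b = unname(b), c_prime = unname(c_prime),
                     indirect_true = unname(a * b),
                     x_mirna = x_mir),
    region_size_voxels = sum(region),
    m_true = m_true)
  yaml::write_yaml(truth, file.path(out_dir, "ground_truth.yaml"))
  invisible(list(dir = out_dir, bold = bold_paths, mask = mask_path,
                 cohort = cohort_path, ct = ct_path, truth = truth,
                 cvr_true = field$cvr_true, region = region, mask_array = mask))
}
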