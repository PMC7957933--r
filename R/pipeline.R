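#' End-to-end pipeline orchestration
#'
#' Runs the full analysis from a configuration: cognitive scoring, CVR
#' mapping per subject, voxel-wise group statistics with cluster
#' inference, ROI extraction, miRNA quantification/validation,
#' covariate-adjusted correlations, and bootstrap mediation. Outputs are
#' plain files (CSV/NIfTI/YAML) in a run directory with a provenance
#' manifest.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param data_dir directory holding `cohort.csv`, `ct_panel.csv`,
#'   `mask.nii.gz` and `bold/<subject_id>.nii.gz` (the layout written by
#'   [simulate_dataset()]).
#' @param out_dir run output directory.
#' @param band band-pass edges, Hz.
#' @param fwhm_mm smoothing FWHM, mm.
#' @param voxel_p,cluster_p,min_cluster_voxels cluster-inference thresholds
#'   (defaults 0.005 / 0.001 / 20 voxels).
#' @param covariates covariate column names for all adjusted analyses.
#' @param n_boot bootstrap resamples for mediation.
#' @param n_perm permutations for cluster inference.
#' @param seed integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir, out_dir,
                            band = c(0.02, 0.04), fwhm_mm = 8,
                            voxel_p = 0.005, cluster_p = 0.001,
                            min_cluster_voxels = 20,
                            covariates = c("age", "education_years",
                                           "lacunar_stroke"),
                            n_boot = 5000, n_perm = 1000, seed = 1) {
  stopifnot(voxel_p > 0, voxel_p < 1, cluster_p > 0, cluster_p < 1)
  structure(list(data_dir = data_dir, out_dir = out_dir, band = band,
                 fwhm_mm = fwhm_mm, voxel_p = voxel_p, cluster_p = cluster_p,
                 min_cluster_voxels = min_cluster_voxels,
                 covariates = covariates, n_boot = n_boot, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, fun, env = parent.frame()) {
  manifest <- get("manifest", envir = env)
  t0 <- Sys.time()
  res <- tryCatch(fun(), error = function(e) e)
  if (inherits(res, "error")) {
    manifest$stages[[name]] <- list(status = "failed",
                                    error = conditionMessage(res))
    assign("manifest", manifest, envir = env)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
         call. = FALSE)
  }
  manifest$stages[[name]] <- list(
    status = "ok",
    seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
  assign("manifest", manifest, envir = env)
  res
}

#' Run the full pipeline
#'
#' Stages, in order: (1) cognitive scoring, (2) per-subject CVR mapping,
#' (3) voxel-wise ANCOVA + permutation cluster inference, (4) ROI mean
#' extraction and post-hoc contrasts, (5) miRNA expression + ANCOVA
#' validation, (6) covariate-adjusted partial correlations (candidate
#' miRNAs and ROI CVR vs domain composites, within the HT-CI group),
#' (7) bootstrap mediation (first validated miRNA -> first ROI ->
#' executive function). A failed stage leaves earlier outputs in place,
#' writes a `FAILED` marker, and raises an error.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the main results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "cvr"), showWarnings = FALSE)
  manifest <- list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("cvrmir")),
                   r_version = R.version.string,
                   config = unclass(config), stages = list())
  on.exit({
    failed <- any(vapply(manifest$stages,
                         function(s) identical(s$status, "failed"), logical(1)))
    if (failed) writeLines("pipeline failed; see manifest",
                           file.path(out, "FAILED"))
    yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  })

  cohort_path <- file.path(config$data_dir, "cohort.csv")
  ct_path <- file.path(config$data_dir, "ct_panel.csv")
  mask_path <- file.path(config$data_dir, "mask.nii.gz")
  for (p in c(cohort_path, ct_path, mask_path))
    if (!file.exists(p)) stop("run_pipeline: missing input ", p)

  cohort <- utils::read.csv(cohort_path, stringsAsFactors = FALSE)
  cohort$group <- factor(cohort$group, levels = COHORT_GROUPS)

  # 1. cognitive scoring ------------------------------------------------
  cohort <- .stage("scoring", function() {
    sc <- score_cohort(cohort)
    utils::write.csv(sc, file.path(out, "scored_cohort.csv"), row.names = FALSE)
    sc
  })

  # 2. CVR mapping ------------------------------------------------------
  mask_img <- read_nifti(mask_path)
  mask <- array(mask_img$data > 0.5, dim(mask_img$data))
  maps <- .stage("cvr_mapping", function() {
    lapply(seq_len(nrow(cohort)), function(i) {
      bp <- file.path(config$data_dir, "bold",
                      paste0(cohort$subject_id[i], ".nii.gz"))
      img <- read_nifti(bp)
      bold <- structure(list(data = img$data, tr = img$tr, mask = mask,
                             voxel_size = img$voxel_size),
                        class = "bold_series")
      cm <- compute_cvr_map(bold, band = config$band,
                            fwhm_mm = config$fwhm_mm,
                            voxel_size = img$voxel_size)
      dat <- cm$data; dat[!mask] <- 0
      write_nifti(dat, file.path(out, "cvr",
                                 paste0(cohort$subject_id[i], ".nii.gz")),
                  voxel_size = img$voxel_size)
      cm
    })
  })
  covs <- cohort[, config$covariates, drop = FALSE]

  # 3. voxel-wise stats + cluster inference ------------------------------
  clus <- .stage("voxel_stats", function() {
    affine <- mask_img$affine
    cl <- cluster_threshold(maps, cohort$group, covs, mask = mask,
                            voxel_p = config$voxel_p,
                            cluster_p = config$cluster_p,
                            min_size = config$min_cluster_voxels,
                            n_perm = config$n_perm, seed = config$seed,
                            affine = affine)
    utils::write.csv(cl$clusters, file.path(out, "clusters.csv"),
                     row.names = FALSE)
    write_nifti(array(as.numeric(cl$labels), dim(cl$labels)),
                file.path(out, "cluster_labels.nii.gz"),
                voxel_size = mask_img$voxel_size)
    cl
  })

  # 4. ROI extraction + post-hoc ----------------------------------------
  roi <- .stage("roi_extraction", function() {
    if (!any(clus$clusters$retained)) {
      utils::write.csv(data.frame(), file.path(out, "roi_means.csv"),
                       row.names = FALSE)
      return(NULL)
    }
    rt <- extract_roi_means(maps, clus, subject_ids = cohort$subject_id)
    utils::write.csv(rt, file.path(out, "roi_means.csv"), row.names = FALSE)
    ph <- posthoc_group_contrasts(rt, cohort$group, covs)
    utils::write.csv(ph, file.path(out, "roi_posthoc.csv"), row.names = FALSE)
    rt
  })

  # 5. miRNA quantification + validation --------------------------------
  val <- .stage("mirna_validation", function() {
    ct <- utils::read.csv(ct_path, stringsAsFactors = FALSE)
    panel <- mirna_panel(ct)
    utils::write.csv(panel$log_expression,
                     file.path(out, "mirna_log_expression.csv"),
                     row.names = FALSE)
    v <- validate_candidates(panel, cohort, covariates = config$covariates)
    utils::write.csv(v$anova, file.path(out, "mirna_ancova.csv"),
                     row.names = FALSE)
    utils::write.csv(v$contrasts, file.path(out, "mirna_posthoc.csv"),
                     row.names = FALSE)
    list(panel = panel, validation = v)
  })

  # 6. correlations within HT-CI ----------------------------------------
  corr <- .stage("correlations", function() {
    ci_idx <- cohort$group == "HT-CI"
    le <- val$panel$log_expression
    le <- le[match(cohort$subject_id, le$subject_id), , drop = FALSE]
    doms <- grep("^domain_", names(cohort), value = TRUE)
    vars_x <- c(val$panel$mirnas,
                if (!is.null(roi)) grep("^cluster_", names(roi), value = TRUE))
    rows <- list()
    for (vx in vars_x) {
      xv <- if (vx %in% val$panel$mirnas) le[[vx]] else roi[[vx]]
      for (dm in doms) {
        pc <- tryCatch(partial_correlation(xv[ci_idx], cohort[[dm]][ci_idx],
                                           covs[ci_idx, , drop = FALSE]),
                       error = function(e) NULL)
        if (!is.null(pc))
          rows[[length(rows) + 1L]] <- data.frame(
            x = vx, y = dm, r = pc$r, p = pc$p, df = pc$df,
            stringsAsFactors = FALSE)
      }
    }
    ctab <- do.call(rbind, rows)
    utils::write.csv(ctab, file.path(out, "correlations.csv"),
                     row.names = FALSE)
    ctab
  })

  # 7. mediation ---------------------------------------------------------
  med <- .stage("mediation", function() {
    if (is.null(roi)) return(NULL)
    x_mir <- val$panel$mirnas[1]
    # mediator ROI: the largest retained cluster (the most reliable focal
    # effect; small satellite clusters are often normalization leakage)
    ret <- clus$clusters[clus$clusters$retained, ]
    roi_col <- paste0("cluster_", ret$cluster_id[which.max(ret$size)])
    le <- val$panel$log_expression
    dat <- cohort
    dat$x_mirna <- le[[x_mir]][match(dat$subject_id, le$subject_id)]
    dat$m_cvr <- roi[[roi_col]][match(dat$subject_id, roi$subject_id)]
    mr <- bootstrap_indirect(dat, "x_mirna", "m_cvr", "domain_executive",
                             covariates = config$covariates,
                             n_boot = config$n_boot, seed = config$seed)
    yaml::write_yaml(list(x = x_mir, m = roi_col, y = "domain_executive",
                          a = mr$a, b = mr$b, c_prime = mr$c_prime, c = mr$c,
                          indirect = mr$indirect, ci_low = mr$ci_low,
                          ci_high = mr$ci_high, mediation = mr$mediation,
                          n = mr$n, n_boot = mr$n_boot, seed = mr$seed),
                    file.path(out, "mediation.yaml"))
    mr
  })

  invisible(list(cohort = cohort, clusters = clus, roi = roi,
                 validation = val$validation, correlations = corr,
                 mediation = med, manifest = manifest, out_dir = out))
}
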