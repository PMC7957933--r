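#' Voxel-wise group statistics and cluster-extent inference
#'
#' CVR maps from all subjects are compared voxel by voxel with a
#' covariate-adjusted ANCOVA F test. Supra-threshold voxels (parametric
#' voxel p below `voxel_p`) are grouped into connected components, and
#' cluster extents are tested against a permutation null distribution of
#' the maximum cluster size (Freedman-Lane residual permutation, exact
#' under exchangeability after covariate adjustment). Retained clusters
#' must satisfy both the corrected cluster p threshold and a minimum size.
#'
#' @name roi-stats
NULL

.stack_maps <- function(cvr_maps) {
  # accepts 4D array (x,y,z,subject), list of cvr_map, or list of 3D arrays
  if (is.list(cvr_maps) && !is.null(cvr_maps[[1]])) {
    arrs <- lapply(cvr_maps, function(m) if (inherits(m, "cvr_map")) m$data else m)
    d <- dim(arrs[[1]])
    if (any(!vapply(arrs, function(a) identical(dim(a), d), logical(1))))
      stop("maps have inconsistent shapes")
    arr <- array(unlist(arrs), c(d, length(arrs)))
  } else arr <- cvr_maps
  arr
}

# vectorized partial-F for value ~ group + covs at every voxel
.voxel_F <- function(Y, X, Z) {
  # Y: subjects x voxels; returns F vector
  qx <- qr(X); qz <- qr(Z)
  rss_full <- colSums(qr.resid(qx, Y)^2)
  rss_red <- colSums(qr.resid(qz, Y)^2)
  df_g <- ncol(X) - ncol(Z)
  df_res <- nrow(Y) - ncol(X)
  f <- ((rss_red - rss_full) / df_g) / (rss_full / df_res)
  # per-voxel degenerate guards, matching ancova()
  tol <- 1e-12 * pmax(colSums(Y^2), .Machine$double.xmin)
  f[rss_full <= tol & rss_red > tol] <- Inf
  f[rss_red <= tol] <- 0
  list(F = f, df = c(df_g, df_res))
}

#' Voxel-wise ANCOVA over a stack of CVR maps
#'
#' Per in-mask voxel, the covariate-adjusted group F statistic (identical
#' to applying [ancova()] voxel by voxel, computed vectorized).
#'
#' @param cvr_maps 4D array `(x, y, z, subject)` or list of `cvr_map`s /
#'   3D arrays.
#' @param groups group label per subject.
#' @param covariates data.frame of numeric covariates or NULL.
#' @param mask logical 3D array; default: voxels finite in all subjects.
#' @return object of class `stat_map`: `F` (3D, NA outside mask), `p`
#'   (parametric), `df`, `mask`.
#' @export
voxelwise_ancova <- function(cvr_maps, groups, covariates = NULL, mask = NULL) {
  arr <- .stack_maps(cvr_maps)
  d <- dim(arr)
  n <- d[4L]
  if (n != length(groups)) stop("voxelwise_ancova: subject count mismatch")
  flat <- t(matrix(arr, prod(d[1:3]), n))       # subjects x voxels
  if (is.null(mask)) mask <- array(colSums(!is.finite(flat)) == 0, d[1:3])
  Yv <- flat[, as.vector(mask), drop = FALSE]
  des <- .design_full_reduced(groups, covariates)
  res <- .voxel_F(Yv, des$X, des$Z)
  Fmap <- array(NA_real_, d[1:3])
  Fmap[mask] <- res$F
  pmap <- array(NA_real_, d[1:3])
  pmap[mask] <- stats::pf(res$F, res$df[1], res$df[2], lower.tail = FALSE)
  structure(list(F = Fmap, p = pmap, df = res$df, mask = mask),
            class = "stat_map")
}

# 3D connected components over a logical array
.neighbor_offsets <- function(connectivity) {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  manh <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  keep <- switch(as.character(connectivity),
                 "6" = manh == 1, "18" = manh <= 2, "26" = rep(TRUE, nrow(offs)),
                 stop("connectivity must be 6, 18 or 26"))
  as.matrix(offs[keep, ])
}

#' Label connected components in a 3D logical array
#'
#' @param supra logical 3D array of supra-threshold voxels.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return integer 3D array of cluster labels (0 = background).
#' @export
label_clusters <- function(supra, connectivity = 26) {
  d <- dim(supra)
  offs <- .neighbor_offsets(connectivity)
  labels <- array(0L, d)
  idx <- which(supra)
  if (!length(idx)) return(labels)
  nlab <- 0L
  for (start in idx) {
    if (labels[start] != 0L) next
    nlab <- nlab + 1L
    queue <- start
    labels[start] <- nlab
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      k0 <- (v - 1L) %/% (d[1L] * d[2L])
      rem <- (v - 1L) %% (d[1L] * d[2L])
      j0 <- rem %/% d[1L]
      i0 <- rem %% d[1L]
      ii <- i0 + 1L + offs[, 1L]
      jj <- j0 + 1L + offs[, 2L]
      kk <- k0 + 1L + offs[, 3L]
      ok <- ii >= 1L & ii <= d[1L] & jj >= 1L & jj <= d[2L] &
            kk >= 1L & kk <= d[3L]
      nb <- (kk[ok] - 1L) * d[1L] * d[2L] + (jj[ok] - 1L) * d[1L] + ii[ok]
      nb <- nb[supra[nb] & labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- nlab
        queue <- c(queue, nb)
      }
    }
  }
  labels
}

.max_cluster_size <- function(supra, connectivity) {
  lab <- label_clusters(supra, connectivity)
  if (!any(lab > 0L)) return(0L)
  max(tabulate(lab[lab > 0L]))
}

#' Cluster-extent inference by permutation
#'
#' Computes the observed voxel-wise ANCOVA F map, thresholds it at the
#' parametric voxel p-value `voxel_p`, labels connected components, and
#' compares each observed cluster's extent with the permutation null
#' distribution of the *maximum* cluster size. The null is built
#' Freedman-Lane style: the maps are residualized on the covariates
#' (reduced model), residuals are permuted over subjects, the reduced-model
#' fit is added back, and the full F map and its max supra-threshold
#' cluster size are recomputed. Corrected cluster p =
#' `(1 + #{perm max size >= observed}) / (n_perm + 1)`. Retained clusters
#' satisfy `p_corr < cluster_p` and `size > min_size`.
#'
#' @param cvr_maps stack as in [voxelwise_ancova()].
#' @param groups,covariates design, as in [voxelwise_ancova()].
#' @param mask logical 3D array or NULL.
#' @param voxel_p voxel-level p threshold (default 0.005).
#' @param cluster_p corrected cluster-level threshold (default 0.001).
#' @param min_size minimum cluster extent in voxels, exclusive
#'   (default 20: clusters must exceed 20 voxels).
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed RNG seed for the permutation stream.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param affine optional 4x4 voxel-to-world matrix for peak coordinates.
#' @return object of class `cluster_result`: `clusters` (data.frame:
#'   cluster_id, size, peak_ijk0 (0-based), peak_x/y/z_mm, peak_F, p_corr,
#'   retained), `labels` (integer 3D array over *retained* clusters),
#'   `all_labels`, `stat_map`, `null_max_sizes`, and the thresholds used.
#' @export
cluster_threshold <- function(cvr_maps, groups, covariates = NULL, mask = NULL,
                              voxel_p = 0.005, cluster_p = 0.001,
                              min_size = 20, n_perm = 1000, seed = 1,
                              connectivity = 26, affine = NULL) {
  if (n_perm < 100) stop("cluster_threshold: n_perm must be >= 100")
  arr <- .stack_maps(cvr_maps)
  d <- dim(arr)
  n <- d[4L]
  flat <- t(matrix(arr, prod(d[1:3]), n))
  if (is.null(mask)) mask <- array(colSums(!is.finite(flat)) == 0, d[1:3])
  Yv <- flat[, as.vector(mask), drop = FALSE]
  des <- .design_full_reduced(groups, covariates)
  obs <- .voxel_F(Yv, des$X, des$Z)
  f_crit <- stats::qf(voxel_p, obs$df[1], obs$df[2], lower.tail = FALSE)

  supra_vec <- obs$F > f_crit
  supra <- array(FALSE, d[1:3]); supra[mask] <- supra_vec
  all_labels <- label_clusters(supra, connectivity)

  # Freedman-Lane permutation null of the max cluster extent
  qz <- qr(des$Z)
  fitted_red <- qr.fitted(qz, Yv)
  resid_red <- Yv - fitted_red
  set.seed(seed)
  null_max <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    Yb <- fitted_red + resid_red[perm, , drop = FALSE]
    fb <- .voxel_F(Yb, des$X, des$Z)$F
    sb <- array(FALSE, d[1:3]); sb[mask] <- fb > f_crit
    null_max[b] <- .max_cluster_size(sb, connectivity)
  }

  ids <- sort(unique(all_labels[all_labels > 0L]))
  if (length(ids)) {
    rows <- lapply(ids, function(id) {
      vox <- which(all_labels == id)
      size <- length(vox)
      fk <- obs$F
      fmap <- array(NA_real_, d[1:3]); fmap[mask] <- fk
      peak <- vox[which.max(fmap[vox])]
      k0 <- (peak - 1L) %/% (d[1L] * d[2L])
      rem <- (peak - 1L) %% (d[1L] * d[2L])
      ijk0 <- c(rem %% d[1L], rem %/% d[1L], k0)
      p_corr <- (1 + sum(null_max >= size)) / (n_perm + 1)
      data.frame(cluster_id = id, size = size,
                 peak_i = ijk0[1], peak_j = ijk0[2], peak_k = ijk0[3],
                 peak_F = fmap[peak], p_corr = p_corr,
                 stringsAsFactors = FALSE)
    })
    ctab <- do.call(rbind, rows)
    ctab$retained <- ctab$p_corr < cluster_p & ctab$size > min_size
  } else {
    ctab <- data.frame(cluster_id = integer(0), size = integer(0),
                       peak_i = integer(0), peak_j = integer(0),
                       peak_k = integer(0), peak_F = numeric(0),
                       p_corr = numeric(0), retained = logical(0))
  }
  if (!is.null(affine) && nrow(ctab)) {
    mm <- voxel_to_world(as.matrix(ctab[, c("peak_i", "peak_j", "peak_k")]),
                         affine)
    ctab$peak_x_mm <- mm[, 1]; ctab$peak_y_mm <- mm[, 2]; ctab$peak_z_mm <- mm[, 3]
  }
  labels <- all_labels
  drop_ids <- ctab$cluster_id[!ctab$retained]
  labels[labels %in% drop_ids] <- 0L
  Fmap <- array(NA_real_, d[1:3]); Fmap[mask] <- obs$F
  stat_map <- structure(list(F = Fmap, df = obs$df, mask = mask),
                        class = "stat_map")
  structure(list(clusters = ctab, labels = labels, all_labels = all_labels,
                 stat_map = stat_map, null_max_sizes = null_max,
                 voxel_p = voxel_p, cluster_p = cluster_p,
                 min_size = min_size, n_perm = n_perm, seed = seed,
                 connectivity = connectivity, f_crit = f_crit),
            class = "cluster_result")
}

#' Per-subject mean CVR inside each retained cluster
#'
#' @param cvr_maps stack as in [voxelwise_ancova()].
#' @param clusters a `cluster_result` (retained clusters are used) or an
#'   integer label volume.
#' @param subject_ids optional subject identifiers for the rows.
#' @return data.frame, one row per subject, one `cluster_<id>` column per
#'   cluster; attribute `peaks` carries the cluster table.
#' @export
extract_roi_means <- function(cvr_maps, clusters, subject_ids = NULL) {
  arr <- .stack_maps(cvr_maps)
  d <- dim(arr)
  labels <- if (inherits(clusters, "cluster_result")) clusters$labels else clusters
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) stop("extract_roi_means: no retained clusters")
  flat <- t(matrix(arr, prod(d[1:3]), d[4L]))   # subjects x voxels
  out <- data.frame(row.names = seq_len(d[4L]))
  if (!is.null(subject_ids)) out$subject_id <- subject_ids
  for (id in ids) {
    vox <- which(labels == id)
    if (!length(vox)) { warning("empty cluster ", id, " skipped"); next }
    out[[paste0("cluster_", id)]] <- rowMeans(flat[, vox, drop = FALSE])
  }
  if (inherits(clusters, "cluster_result"))
    attr(out, "peaks") <- clusters$clusters[clusters$clusters$retained, ]
  out
}

#' Covariate-adjusted pairwise group contrasts per ROI
#'
#' @param roi_table data.frame from [extract_roi_means()] (cluster_*
#'   columns).
#' @param groups group label per subject.
#' @param covariates data.frame of covariates or NULL.
#' @param p_adjust adjustment for the pairwise p-values (default "none").
#' @return tidy data.frame of contrasts per ROI (delegates to [ancova()]).
#' @export
posthoc_group_contrasts <- function(roi_table, groups, covariates = NULL,
                                    p_adjust = "none") {
  rois <- grep("^cluster_", names(roi_table), value = TRUE)
  if (!length(rois)) stop("posthoc_group_contrasts: no cluster_* columns")
  rows <- lapply(rois, function(rc) {
    res <- ancova(roi_table[[rc]], groups, covariates, p_adjust = p_adjust)
    cc <- res$contrasts
    cc$roi <- rc
    cc$F_group <- res$F
    cc$p_group <- res$p
    cc
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
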