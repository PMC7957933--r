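#' Relative CVR mapping from resting-state BOLD
#'
#' The vasodilatory capacity of cerebral vessels modulates the amplitude of
#' slow (0.02-0.04 Hz) BOLD fluctuations. A relative cerebrovascular
#' reactivity (CVR) map is obtained by (1) band-limiting the BOLD series to
#' that range, (2) taking the whole-brain mean time course as a global
#' vasomotor reference, (3) regressing each voxel's time course on the
#' reference (GLM slope), and (4) dividing the slope map by its in-mask
#' mean, yielding relative units ("r.u.") with whole-brain mean 1.
#'
#' @name cvr-mapping
NULL

.as_time_by_series <- function(x) {
  # coerce vector/matrix/4D to a time x series matrix + restorer
  if (is.null(dim(x))) {
    list(mat = matrix(x, ncol = 1L),
         restore = function(m) as.vector(m[, 1L]))
  } else if (length(dim(x)) == 2L) {
    list(mat = x, restore = function(m) m)
  } else if (length(dim(x)) == 4L) {
    d <- dim(x)
    nt <- d[4L]
    flat <- t(matrix(x, prod(d[1:3]), nt))     # time x voxels
    list(mat = flat, restore = function(m) array(t(m), d))
  } else stop("expected a vector, time x series matrix, or 4D array")
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain (FFT) ideal band-pass: Fourier coefficients with
#' frequency magnitude inside `[low, high]` are retained, all others
#' (including DC) are zeroed, and the series is inverse-transformed. The
#' realization is exactly zero-phase, so regression slopes against a
#' filtered reference are not biased by phase distortion. This is the
#' filter realization used by the common resting-state toolboxes.
#'
#' @param x numeric vector, time x series matrix, or 4D array (x,y,z,t).
#' @param tr sampling interval, seconds.
#' @param low,high band edges in Hz; `0 < low < high < 1/(2*tr)`.
#' @return filtered signal, same shape as `x`, zero-mean along time.
#' @export
bandpass_filter <- function(x, tr, low = 0.02, high = 0.04) {
  nyq <- 1 / (2 * tr)
  if (!(low > 0 && low < high && high < nyq))
    stop("bandpass_filter: need 0 < low < high < Nyquist (", nyq, " Hz)")
  conv <- .as_time_by_series(x)
  m <- conv$mat
  n <- nrow(m)
  freqs <- (seq_len(n) - 1) / (n * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)         # two-sided frequency magnitude
  keep <- freqs >= low & freqs <= high
  fm <- stats::mvfft(m)
  fm[!keep, ] <- 0
  out <- Re(stats::mvfft(fm, inverse = TRUE)) / n
  conv$restore(out)
}

#' Remove a per-series linear trend
#'
#' @param x vector, time x series matrix, or 4D array.
#' @return detrended signal (mean and linear slope removed per series).
#' @export
detrend_linear <- function(x) {
  conv <- .as_time_by_series(x)
  m <- conv$mat
  n <- nrow(m)
  t_c <- seq_len(n) - (n + 1) / 2
  means <- colMeans(m)
  slopes <- as.vector(crossprod(m, t_c)) / sum(t_c^2)
  out <- m - rep(means, each = n) - outer(t_c, slopes)
  conv$restore(out)
}

#' Global vasomotor reference signal
#'
#' In-mask spatial mean of the BOLD series at each time point, band-pass
#' filtered and therefore zero-mean.
#'
#' @param bold a `bold_series` (list with `data`, `tr`, `mask`) or 4D array.
#' @param band band edges in Hz.
#' @param mask,tr required when `bold` is a bare array.
#' @param filter apply [bandpass_filter()] to the mean course (default TRUE;
#'   set FALSE if `bold` was already filtered).
#' @return list of class `reference_signal`: `values`, `band`.
#' @export
reference_signal <- function(bold, band = c(0.02, 0.04), mask = NULL,
                             tr = NULL, filter = TRUE) {
  if (inherits(bold, "bold_series")) {
    data <- bold$data; mask <- bold$mask; tr <- bold$tr
  } else data <- bold
  if (is.null(mask) || !any(mask)) stop("reference_signal: empty or missing mask")
  d <- dim(data)
  flat <- matrix(data, prod(d[1:3]), d[4L])
  ref <- colMeans(flat[as.vector(mask), , drop = FALSE])
  if (filter) ref <- bandpass_filter(ref, tr, band[1], band[2])
  else ref <- ref - mean(ref)
  structure(list(values = ref, band = band, tr = tr),
            class = "reference_signal")
}

#' An end-tidal CO2 trace
#'
#' @param values mmHg samples.
#' @param sampling_interval seconds between samples.
#' @param shift applied alignment shift in seconds (0 before alignment).
#' @export
etco2_trace <- function(values, sampling_interval, shift = 0) {
  structure(list(values = as.numeric(values),
                 sampling_interval = sampling_interval, shift = shift),
            class = "etco2_trace")
}

#' Align an EtCO2 trace to the BOLD reference by step-wise lag search
#'
#' The trace is shifted over a lag grid `seq(0, max_lag, step)`; the lag
#' maximizing the Pearson correlation with the reference (ties toward the
#' smaller lag) is applied. This models the lung-to-brain transit delay: at
#' lag L the aligned trace value at scan time t is the CO2 value at t - L.
#'
#' @param etco2 an [etco2_trace()].
#' @param reference a `reference_signal`.
#' @param max_lag,step lag grid, seconds.
#' @param min_corr correlation floor below which the result is flagged
#'   `low_correlation = TRUE`.
#' @return the shifted trace, resampled to the BOLD time grid, with fields
#'   `shift`, `correlation`, `low_correlation`.
#' @export
align_etco2 <- function(etco2, reference, max_lag = 20, step = NULL,
                        min_corr = 0.3) {
  stopifnot(inherits(etco2, "etco2_trace"))
  if (is.null(step)) step <- reference$tr
  if (max_lag < 0 || step <= 0) stop("align_etco2: bad lag grid")
  ref <- reference$values
  n <- length(ref)
  t_bold <- (seq_len(n) - 1) * reference$tr
  t_e <- (seq_along(etco2$values) - 1) * etco2$sampling_interval
  lags <- seq(0, max_lag, by = step)
  best <- c(lag = NA_real_, r = -Inf)
  for (lag in lags) {
    tv <- t_bold - lag
    ok <- tv >= min(t_e) & tv <= max(t_e)
    if (sum(ok) < n / 2)
      stop("align_etco2: trace too short to cover BOLD timing at lag ", lag)
    v <- stats::approx(t_e, etco2$values, xout = tv[ok])$y
    r <- suppressWarnings(stats::cor(v, ref[ok]))
    if (is.na(r)) r <- -Inf
    if (r > best[["r"]] + 1e-12) best <- c(lag = lag, r = r)
  }
  tv <- t_bold - best[["lag"]]
  ok <- tv >= min(t_e) & tv <= max(t_e)
  vals <- rep(NA_real_, n)
  vals[ok] <- stats::approx(t_e, etco2$values, xout = tv[ok])$y
  out <- etco2_trace(vals, reference$tr, shift = best[["lag"]])
  out$correlation <- unname(best[["r"]])
  out$low_correlation <- unname(best[["r"]]) < min_corr
  out
}

#' Voxel-wise GLM slope of BOLD on the reference signal
#'
#' Per in-mask voxel, the least-squares slope (intercept included) of the
#' voxel time course on the reference time course. Because the reference
#' is zero-mean, the slope is `<v, ref> / <ref, ref>` after removing each
#' voxel's mean.
#'
#' @param bold a `bold_series` or 4D array.
#' @param reference a `reference_signal` or numeric vector.
#' @param mask required when `bold` is a bare array.
#' @return 3D beta map; `NA` outside the mask.
#' @export
voxelwise_cvr <- function(bold, reference, mask = NULL) {
  if (inherits(bold, "bold_series")) { data <- bold$data; mask <- bold$mask }
  else data <- bold
  ref <- if (inherits(reference, "reference_signal")) reference$values else reference
  d <- dim(data)
  if (length(ref) != d[4L]) stop("voxelwise_cvr: time lengths differ")
  r0 <- ref - mean(ref)
  denom <- sum(r0^2)
  if (denom <= .Machine$double.eps * length(r0))
    stop("voxelwise_cvr: reference signal has zero variance")
  flat <- matrix(data, prod(d[1:3]), d[4L])
  beta_flat <- as.vector(flat %*% r0) / denom
  beta <- array(NA_real_, d[1:3])
  beta[mask] <- beta_flat[as.vector(mask)]
  beta
}

#' Normalize a beta map to relative CVR units
#'
#' Divides every in-mask voxel by the in-mask mean, so the relative CVR map
#' has whole-brain mean exactly 1. The whole-brain mask is the reference
#' region; any other reference region can be supplied as `mask`.
#'
#' @param beta_map 3D array of GLM slopes.
#' @param mask logical 3D array.
#' @return object of class `cvr_map`: list with `data` (NA outside mask)
#'   and `mask`.
#' @export
normalize_cvr <- function(beta_map, mask) {
  vals <- beta_map[mask]
  m <- mean(vals, na.rm = TRUE)
  if (!is.finite(m) || abs(m) < 1e-12)
    stop("normalize_cvr: in-mask mean beta is zero or non-finite")
  out <- array(NA_real_, dim(beta_map))
  out[mask] <- beta_map[mask] / m
  structure(list(data = out, mask = mask), class = "cvr_map")
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian kernel with `sigma = fwhm / (2*sqrt(2*log(2)))` per
#' axis, specified in mm and converted to voxels via `voxel_size`. Kernel
#' weights are renormalized at the volume edges so constant volumes are
#' preserved. `fwhm = 0` is the identity.
#'
#' When a `mask` is supplied, smoothing is mask-aware: out-of-mask voxels
#' carry zero weight and the kernel is renormalized by the smoothed mask,
#' so in-mask amplitudes near the brain edge are not diluted by the
#' (signal-free) background.
#'
#' @param data 3D or 4D array.
#' @param fwhm_mm full width at half maximum, mm.
#' @param voxel_size length-3 voxel edges, mm.
#' @param mask optional logical 3D array for mask-aware smoothing.
#' @return smoothed array, same shape.
#' @export
smooth_volume <- function(data, fwhm_mm, voxel_size = c(3, 3, 3),
                          mask = NULL) {
  if (fwhm_mm < 0) stop("smooth_volume: fwhm must be >= 0")
  if (fwhm_mm == 0) return(data)
  if (!is.null(mask)) {
    w <- .gauss_smooth(array(as.numeric(mask), dim(mask)), fwhm_mm, voxel_size)
    w[w <= 0] <- 1
    sm <- .gauss_smooth(data * as.vector(mask), fwhm_mm, voxel_size)
    out <- (sm / as.vector(w)) * as.vector(mask)
    return(out)
  }
  .gauss_smooth(data, fwhm_mm, voxel_size)
}

.gauss_smooth <- function(data, fwhm_mm, voxel_size) {
  d <- dim(data)
  nd <- length(d)
  if (!nd %in% c(3L, 4L)) stop("smooth_volume: need a 3D or 4D array")
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  out <- data
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    n <- d[ax]
    # banded convolution matrix, rows renormalized at the edges
    K <- matrix(0, n, n)
    for (off in seq(-r, r)) {
      idx <- seq_len(n)
      j <- idx + off
      ok <- j >= 1L & j <= n
      K[cbind(idx[ok], j[ok])] <- k[off + r + 1L]
    }
    K <- K / rowSums(K)
    # bring axis `ax` first, multiply, restore
    perm <- c(ax, setdiff(seq_len(nd), ax))
    m <- matrix(aperm(out, perm), d[ax])
    m <- K %*% m
    out <- aperm(array(m, d[perm]), order(perm))
  }
  out
}

#' Compute a relative CVR map from a BOLD series
#'
#' Full mapping pipeline: optional Gaussian smoothing of the 4D series,
#' per-voxel linear detrending, band-pass filtering, global reference
#' extraction, voxel-wise GLM, and normalization to relative units.
#'
#' @param bold a `bold_series` (see [simulate_bold()]) or a list with
#'   `data`, `tr`, `mask`.
#' @param band band edges in Hz.
#' @param fwhm_mm smoothing kernel FWHM in mm (0 disables smoothing).
#' @param voxel_size voxel edges in mm.
#' @param detrend remove per-voxel linear trends before filtering.
#' @return a `cvr_map` with attribute `reference` (the reference signal).
#' @export
compute_cvr_map <- function(bold, band = c(0.02, 0.04), fwhm_mm = 8,
                            voxel_size = NULL, detrend = TRUE) {
  data <- bold$data; tr <- bold$tr; mask <- bold$mask
  if (is.null(voxel_size))
    voxel_size <- if (!is.null(bold$voxel_size)) bold$voxel_size else c(3, 3, 3)
  if (anyNA(data[rep(mask, dim(data)[4L])]))
    stop("compute_cvr_map: NA inside mask")
  if (fwhm_mm > 0) data <- smooth_volume(data, fwhm_mm, voxel_size,
                                         mask = mask)
  if (detrend) data <- detrend_linear(data)
  filt <- bandpass_filter(data, tr, band[1], band[2])
  ref <- reference_signal(filt, band = band, mask = mask, tr = tr,
                          filter = FALSE)
  beta <- voxelwise_cvr(filt, ref, mask = mask)
  out <- normalize_cvr(beta, mask)
  attr(out, "reference") <- ref
  out
}
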