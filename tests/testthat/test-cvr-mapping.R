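test_that("bandpass_filter keeps the passband and kills the stopband", {
  tr <- 2; n <- 240
  t_s <- (seq_len(n) - 1) * tr
  inband <- sin(2 * pi * 0.03 * t_s)
  out <- bandpass_filter(inband, tr, 0.02, 0.04)
  expect_gt(sd(out) / sd(inband), 0.95)
  expect_lt(sd(out) / sd(inband), 1.05)
  expect_equal(mean(out), 0, tolerance = 1e-10)

  stopband <- sin(2 * pi * 0.1 * t_s)
  out2 <- bandpass_filter(stopband, tr, 0.02, 0.04)
  expect_lt(sd(out2) / sd(stopband), 0.2)

  set.seed(1)
  noise <- rnorm(n)
  out3 <- bandpass_filter(noise, tr, 0.02, 0.04)
  expect_gte(band_power_fraction(out3, tr), 0.8)

  expect_error(bandpass_filter(noise, tr, 0.02, 0.3), "Nyquist")
  expect_error(bandpass_filter(noise, tr, 0.04, 0.02), "Nyquist|low")
})

test_that("filter and detrend operate per series across shapes", {
  tr <- 2
  set.seed(2)
  m <- matrix(rnorm(120 * 3), 120, 3)
  fm <- bandpass_filter(m, tr, 0.02, 0.04)
  expect_equal(fm[, 2], bandpass_filter(m[, 2], tr, 0.02, 0.04))
  a <- array(rnorm(3 * 3 * 2 * 120), c(3, 3, 2, 120))
  fa <- bandpass_filter(a, tr, 0.02, 0.04)
  expect_equal(fa[2, 3, 1, ], bandpass_filter(a[2, 3, 1, ], tr, 0.02, 0.04))
  x <- 5 + 0.3 * seq_len(100) + rnorm(100)
  dx <- detrend_linear(x)
  expect_equal(mean(dx), 0, tolerance = 1e-10)
  expect_lt(abs(coef(lm(dx ~ seq_along(dx)))[2]), 1e-10)
})

test_that("reference_signal is the filtered in-mask mean", {
  cfg <- tiny_config()
  d <- cfg$grid_shape
  g <- simulate_vasomotor(cfg)
  # constant field: every voxel shares s(t) -> reference == filtered s(t)
  bold <- simulate_bold(array(1, d), cfg, mask = array(TRUE, d),
                        g = g, baseline = 0, seed = 1)
  cfg0 <- tiny_config(noise_sd = 0)
  bold0 <- simulate_bold(array(1, d), cfg0, mask = array(TRUE, d),
                         g = g, baseline = 0)
  ref0 <- reference_signal(bold0)
  expect_equal(ref0$values, bandpass_filter(g, cfg$tr, 0.02, 0.04),
               tolerance = 1e-10)
  # two-voxel mask with u and -u cancels
  arr <- array(0, c(d, cfg$n_volumes))
  arr[1, 1, 1, ] <- g; arr[2, 1, 1, ] <- -g
  mask2 <- array(FALSE, d); mask2[1:2, 1, 1] <- TRUE
  refc <- reference_signal(arr, mask = mask2, tr = cfg$tr)
  expect_lt(max(abs(refc$values)), 1e-10)
  expect_error(reference_signal(arr, mask = array(FALSE, d), tr = cfg$tr),
               "mask")
  # noisy generative data: reference tracks g
  fld <- make_cvr_field(cfg)
  boldn <- simulate_bold(fld$cvr_true, cfg)
  refn <- reference_signal(boldn)
  gf <- bandpass_filter(boldn$g, cfg$tr, 0.02, 0.04)
  expect_gte(cor(refn$values, gf), 0.95)
})

test_that("align_etco2 finds a constructed lag and flags noise", {
  tr <- 2; n <- 200
  t_bold <- (seq_len(n) - 1) * tr
  gfun <- function(t) sin(2 * pi * 0.03 * t) + 0.5 * sin(2 * pi * 0.025 * t + 1)
  ref <- make_reference(gfun(t_bold), tr = tr)
  t_e <- seq(0, max(t_bold) + 30, by = 1)
  lagged <- etco2_trace(gfun(t_e + 6), sampling_interval = 1)
  al <- align_etco2(lagged, ref, max_lag = 20, step = 2)
  expect_equal(al$shift, 6)
  expect_false(al$low_correlation)

  same <- etco2_trace(gfun(t_e), sampling_interval = 1)
  expect_equal(align_etco2(same, ref, max_lag = 20, step = 2)$shift, 0)

  set.seed(3)
  noise <- etco2_trace(rnorm(length(t_e)), sampling_interval = 1)
  aln <- align_etco2(noise, ref, max_lag = 20, step = 2)
  expect_true(aln$low_correlation)
  short <- etco2_trace(gfun(seq(0, 50)), sampling_interval = 1)
  expect_error(align_etco2(short, ref, max_lag = 20, step = 2), "too short")
})

test_that("voxelwise_cvr is an exact per-voxel regression slope", {
  cfg <- tiny_config()
  d <- cfg$grid_shape
  g <- simulate_vasomotor(cfg)
  arr <- array(0, c(d, cfg$n_volumes))
  arr[1, 1, 1, ] <- 2 * g
  orth <- sin(2 * pi * 0.1 * (seq_len(cfg$n_volumes) - 1))
  orth <- orth - mean(orth)
  orth <- orth - g * sum(orth * (g - mean(g))) / sum((g - mean(g))^2)
  arr[2, 1, 1, ] <- orth
  mask <- array(FALSE, d); mask[1:2, 1, 1] <- TRUE
  beta <- voxelwise_cvr(arr, make_reference(g, cfg$tr), mask = mask)
  expect_equal(beta[1, 1, 1], 2, tolerance = 1e-9)
  expect_equal(beta[2, 1, 1], 0, tolerance = 1e-9)
  expect_true(is.na(beta[3, 1, 1]))
  expect_error(voxelwise_cvr(arr, make_reference(rep(0, cfg$n_volumes), cfg$tr),
                             mask = mask), "zero variance")
})

test_that("normalize_cvr yields mean 1 and is scale invariant", {
  d <- c(6, 6, 4)
  mask <- array(TRUE, d)
  uni <- normalize_cvr(array(3, d), mask)
  expect_equal(unique(as.vector(uni$data)), 1)
  set.seed(4)
  beta <- array(rexp(prod(d)) + 0.1, d)
  n1 <- normalize_cvr(beta, mask)
  n2 <- normalize_cvr(2 * beta, mask)
  expect_equal(n1$data, n2$data, tolerance = 1e-12)
  expect_equal(mean(n1$data[mask]), 1, tolerance = 1e-9)
  expect_error(normalize_cvr(array(0, d), mask), "zero")
})

test_that("smooth_volume matches the analytic Gaussian kernel", {
  d <- c(15, 15, 9)
  expect_identical(smooth_volume(array(1, d), 0), array(1, d))
  cons <- smooth_volume(array(5, d), 8, c(3, 3, 3))
  expect_equal(cons, array(5, d), tolerance = 1e-9)
  delta <- array(0, d); delta[8, 8, 5] <- 1
  sm <- smooth_volume(delta, 8, c(3, 3, 3))
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 3
  r <- max(1, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma); k <- k / sum(k)
  expect_equal(sm[8, 8, 5], max(k)^3, tolerance = 1e-9)  # peak attenuation
  expect_equal(sm[9, 8, 5] / sm[8, 8, 5], k[r + 2] / k[r + 1],
               tolerance = 1e-9)
  expect_error(smooth_volume(delta, -1), ">= 0")
})

test_that("relative CVR is invariant to BOLD intensity scaling", {
  cfg <- tiny_config(seed = 9)
  fld <- make_cvr_field(cfg)
  bold <- simulate_bold(fld$cvr_true, cfg)
  cm1 <- compute_cvr_map(bold)
  bold$data <- bold$data * 7.3
  cm2 <- compute_cvr_map(bold)
  expect_equal(cm1$data, cm2$data, tolerance = 1e-9)
})

test_that("zero-noise recovery is exact; default SNR recovery is strong", {
  cfg0 <- tiny_config(noise_sd = 0, seed = 2)
  fld <- make_cvr_field(cfg0)
  cm <- compute_cvr_map(simulate_bold(fld$cvr_true, cfg0), fwhm_mm = 0)
  rel_truth <- fld$cvr_true[fld$mask] / mean(fld$cvr_true[fld$mask])
  expect_lt(max(abs(cm$data[fld$mask] - rel_truth)), 1e-6)
  expect_equal(mean(cm$data[fld$mask]), 1, tolerance = 1e-9)

  rs <- vapply(1:3, function(seed) {
    cfg <- sim_config(n_per_group = c(5, 5, 5), seed = seed)
    fld <- make_cvr_field(cfg)
    cmn <- compute_cvr_map(simulate_bold(fld$cvr_true, cfg))
    cor(cmn$data[fld$mask], fld$cvr_true[fld$mask])
  }, numeric(1))
  expect_gte(median(rs), 0.9)
})
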