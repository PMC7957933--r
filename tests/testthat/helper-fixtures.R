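# small configurations used across tests; sizes chosen to keep the
# default suite fast while leaving the stated defaults untouched
tiny_config <- function(seed = 1, ...) {
  sim_config(n_per_group = c(5, 5, 5), n_volumes = 120, seed = seed, ...)
}

# reference signal object from a bare time course
make_reference <- function(values, tr = 2, band = c(0.02, 0.04)) {
  structure(list(values = values - mean(values), band = band, tr = tr),
            class = "reference_signal")
}

# fraction of periodogram power inside [low, high] (two-sided, DC excluded)
band_power_fraction <- function(x, tr, low = 0.02, high = 0.04) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) / (n * tr)
  f <- pmin(f, 1 / tr - f)
  sum(p[f >= low & f <= high]) / sum(p[-1])
}
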