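#' Covariate-adjusted bootstrap mediation analysis
#'
#' Three-variable mediation (X -> M -> Y) with covariates, in the
#' regression tradition: `a` is the X slope in `M ~ X + Cov`, `b` and
#' `c'` are the M and X slopes in `Y ~ X + M + Cov`, and the total effect
#' `c` is the X slope in `Y ~ X + Cov`. For OLS with identical covariate
#' sets, `c = c' + a*b` exactly. The indirect effect `a*b` is tested with
#' a percentile bootstrap over subject-level resamples: mediation is
#' declared when the CI excludes zero.
#'
#' @name mediation
NULL

.med_designs <- function(data, x_col, m_col, y_col, covariates) {
  cols <- c(x_col, m_col, y_col, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("mediation: columns missing from data: ",
         paste(missing_cols, collapse = ", "))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  x <- as.numeric(d[[x_col]]); m <- as.numeric(d[[m_col]])
  y <- as.numeric(d[[y_col]])
  C <- if (length(covariates))
    as.matrix(as.data.frame(lapply(d[covariates], as.numeric))) else NULL
  list(x = x, m = m, y = y, C = C, n = nrow(d))
}

.fit_paths_num <- function(x, m, y, C) {
  one <- rep(1, length(x))
  Xa <- cbind(one, x, C)
  Xb <- cbind(one, x, m, C)
  fa <- stats::lm.fit(Xa, m)
  fb <- stats::lm.fit(Xb, y)
  fc <- stats::lm.fit(Xa, y)
  if (fa$rank < ncol(Xa) || fb$rank < ncol(Xb)) return(NULL)
  c(a = unname(fa$coefficients[2]),
    b = unname(fb$coefficients[3]),
    c_prime = unname(fb$coefficients[2]),
    c = unname(fc$coefficients[2]))
}

#' Fit the three mediation path regressions
#'
#' @param data data.frame holding all columns.
#' @param x_col,m_col,y_col exposure, mediator, outcome column names.
#' @param covariates covariate column names (may be empty).
#' @param standardize z-standardize x, m and y before fitting, so the
#'   paths are standardized coefficients (default FALSE here; the
#'   bootstrap wrapper defaults to TRUE).
#' @return list: `a`, `b`, `c_prime`, `c`, `n`; `c - (c_prime + a*b)` is
#'   zero to numerical precision.
#' @export
fit_paths <- function(data, x_col, m_col, y_col, covariates = character(0),
                      standardize = FALSE) {
  dd <- .med_designs(data, x_col, m_col, y_col, covariates)
  if (dd$n <= length(covariates) + 3L)
    stop("fit_paths: n too small for the design")
  if (standardize) {
    dd$x <- as.vector(scale(dd$x)); dd$m <- as.vector(scale(dd$m))
    dd$y <- as.vector(scale(dd$y))
  }
  est <- .fit_paths_num(dd$x, dd$m, dd$y, dd$C)
  if (is.null(est)) stop("fit_paths: rank-deficient design")
  as.list(c(est, indirect = unname(est["a"] * est["b"]), n = dd$n))
}

#' Percentile-bootstrap CI for the indirect effect
#'
#' Resamples subjects with replacement (covariates travel with their
#' subjects), refits the `a` and `b` paths per resample, and forms the
#' percentile CI of `a*b` at `ci_level`. Resamples with rank-deficient
#' designs are redrawn (count reported). Fully determined by `seed`.
#'
#' @param data,x_col,m_col,y_col,covariates as in [fit_paths()].
#' @param n_boot bootstrap resamples (>= 1000 recommended; default 5000).
#' @param seed RNG seed.
#' @param ci_level CI level (default 0.95).
#' @param standardize z-standardize x, m, y before fitting (standardized
#'   path coefficients; default TRUE).
#' @return object of class `mediation_result`: point estimates `a`, `b`,
#'   `c_prime`, `c`, `indirect`; `ci_low`, `ci_high`; `mediation`
#'   (CI excludes 0); `boot_indirect` (the bootstrap draws), `n`, `n_boot`,
#'   `n_redrawn`, `seed`, `ci_level`, `covariates`.
#' @export
bootstrap_indirect <- function(data, x_col, m_col, y_col,
                               covariates = character(0), n_boot = 5000,
                               seed = 1, ci_level = 0.95,
                               standardize = TRUE) {
  dd <- .med_designs(data, x_col, m_col, y_col, covariates)
  n <- dd$n
  if (n <= length(covariates) + 3L)
    stop("bootstrap_indirect: n too small for the design")
  if (standardize) {
    dd$x <- as.vector(scale(dd$x)); dd$m <- as.vector(scale(dd$m))
    dd$y <- as.vector(scale(dd$y))
  }
  point <- .fit_paths_num(dd$x, dd$m, dd$y, dd$C)
  if (is.null(point)) stop("bootstrap_indirect: rank-deficient design")

  set.seed(seed)
  boot_ab <- numeric(n_boot)
  n_redrawn <- 0L
  b <- 1L
  while (b <= n_boot) {
    idx <- sample.int(n, n, replace = TRUE)
    est <- .fit_paths_num(dd$x[idx], dd$m[idx], dd$y[idx],
                          if (is.null(dd$C)) NULL else dd$C[idx, , drop = FALSE])
    if (is.null(est)) { n_redrawn <- n_redrawn + 1L; next }
    boot_ab[b] <- est[["a"]] * est[["b"]]
    b <- b + 1L
  }
  alpha <- (1 - ci_level) / 2
  ci <- unname(stats::quantile(boot_ab, c(alpha, 1 - alpha)))
  structure(list(
    a = point[["a"]], b = point[["b"]], c_prime = point[["c_prime"]],
    c = point[["c"]], indirect = point[["a"]] * point[["b"]],
    ci_low = ci[1], ci_high = ci[2],
    mediation = ci[1] > 0 || ci[2] < 0,
    boot_indirect = boot_ab, n = n, n_boot = n_boot,
    n_redrawn = n_redrawn, seed = seed, ci_level = ci_level,
    covariates = covariates, standardize = standardize
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation analysis (percentile bootstrap, n =", x$n,
      ", n_boot =", x$n_boot, ")\n")
  cat(sprintf("  a = %.4f  b = %.4f  c' = %.4f  c = %.4f\n",
              x$a, x$b, x$c_prime, x$c))
  cat(sprintf("  indirect (a*b) = %.4f, %.0f%% CI [%.4f, %.4f]%s\n",
              x$indirect, 100 * x$ci_level, x$ci_low, x$ci_high,
              if (x$mediation) "  *CI excludes 0*" else ""))
  if (length(x$covariates))
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}
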