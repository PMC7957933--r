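#' Cohort-level statistics
#'
#' One-way ANOVA (from raw data or from printed summary statistics),
#' Pearson chi-square without continuity correction, ANCOVA with partial
#' (Type-III-style) group sums of squares, adjusted means, pairwise
#' covariate-adjusted contrasts, and partial correlation. These are the
#' building blocks for demographic tables, the miRNA validation stage,
#' ROI post-hoc tests and the correlation analyses.
#'
#' @name cohort-stats
NULL

#' One-way ANOVA
#'
#' Classical between/within decomposition. A dataset with zero
#' within-group variance yields `F = Inf` with `degenerate = TRUE`.
#'
#' @param values numeric outcome.
#' @param groups factor or character group labels.
#' @return list: `F`, `p`, `df` (between, within), `degenerate`.
#' @export
one_way_anova <- function(values, groups) {
  ok <- stats::complete.cases(values, groups)
  values <- values[ok]; groups <- droplevels(factor(groups[ok]))
  k <- nlevels(groups)
  n <- tabulate(groups)
  if (k < 2L || any(n < 2L))
    stop("one_way_anova: need >= 2 groups with n >= 2 each")
  N <- length(values)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum((values - means[as.integer(groups)])^2)
  df_b <- k - 1L; df_w <- N - k
  if (ssw <= .Machine$double.eps * sum(values^2)) {
    return(list(F = Inf, p = 0, df = c(df_b, df_w), degenerate = TRUE))
  }
  f <- (ssb / df_b) / (ssw / df_w)
  list(F = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE),
       df = c(df_b, df_w), degenerate = FALSE)
}

#' One-way ANOVA from published summary statistics
#'
#' Reconstructs the F test from per-group means, SDs and ns:
#' `SSB = sum n_i (m_i - m)^2`, `SSW = sum (n_i - 1) s_i^2`.
#'
#' @param means,sds,ns per-group summary statistics.
#' @return list: `F`, `p`, `df`.
#' @export
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  stopifnot(length(sds) == k, length(ns) == k)
  if (any(ns < 2) || any(sds < 0)) stop("anova_from_summary: invalid summaries")
  N <- sum(ns)
  df_b <- k - 1L; df_w <- N - k
  if (df_w <= 0) stop("anova_from_summary: insufficient residual df")
  gm <- sum(ns * means) / N
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  if (ssw == 0) return(list(F = if (ssb > 0) Inf else 0, p = if (ssb > 0) 0 else 1,
                            df = c(df_b, df_w)))
  f <- (ssb / df_b) / (ssw / df_w)
  list(F = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE),
       df = c(df_b, df_w))
}

#' Pearson chi-square test (no continuity correction)
#'
#' @param table integer matrix of counts, groups x categories.
#' @return list: `chisq`, `p`, `df`, `expected`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("chi_square: negative counts")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0))
    stop("chi_square: zero margin; expected counts undefined")
  expected <- outer(rs, cs) / sum(table)
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(chisq = stat, p = stats::pchisq(stat, df, lower.tail = FALSE),
       df = df, expected = expected)
}

.design_full_reduced <- function(groups, covariates = NULL) {
  groups <- droplevels(factor(groups))
  k <- nlevels(groups)
  if (k < 2L) stop("need >= 2 groups")
  # sum-to-zero group coding -> partial SS for group is Type-III-style
  G <- stats::model.matrix(~ g, data = data.frame(g = groups),
                           contrasts.arg = list(g = "contr.sum"))
  Z <- G[, 1, drop = FALSE]                       # intercept
  if (!is.null(covariates)) {
    C <- as.matrix(as.data.frame(covariates))
    storage.mode(C) <- "double"
    keep <- apply(C, 2L, function(col) stats::sd(col) > 0)
    C <- C[, keep, drop = FALSE]
    if (ncol(C) > 0) {
      Z <- cbind(Z, C)
      G <- cbind(G, C)
    }
  }
  if (qr(G)$rank < ncol(G))
    stop("design matrix is rank deficient (collinear covariates?)")
  list(X = G, Z = Z, groups = groups, k = k)
}

#' ANCOVA: group comparison adjusted for covariates
#'
#' Fits `value ~ group + covariates` with sum-to-zero group coding. The
#' group F statistic uses the partial (Type-III-style) sum of squares:
#' the RSS increase when the group columns are dropped while the
#' covariates stay. Adjusted group means are model predictions at the
#' covariate means; pairwise contrasts are differences of adjusted means
#' with model-based standard errors and t tests on the residual df.
#'
#' @param values numeric outcome.
#' @param groups factor/character labels.
#' @param covariates data.frame/matrix of numeric covariates, or NULL.
#'   Zero-variance columns are dropped (so the covariate-free call reduces
#'   to one-way ANOVA).
#' @param p_adjust multiplicity adjustment for the pairwise contrasts:
#'   `"none"` (default), `"bonferroni"`, `"BH"`, ... (see
#'   [stats::p.adjust()]).
#' @return list of class `ancova_result`: `F`, `p`, `df`,
#'   `adjusted_means`, `contrasts` (data.frame), `n`, `p_adjust`.
#' @export
ancova <- function(values, groups, covariates = NULL, p_adjust = "none") {
  ok <- stats::complete.cases(values, groups,
                              if (is.null(covariates)) rep(TRUE, length(values))
                              else as.data.frame(covariates))
  values <- values[ok]
  groups <- if (is.factor(groups)) droplevels(groups[ok]) else groups[ok]
  if (!is.null(covariates))
    covariates <- as.data.frame(covariates)[ok, , drop = FALSE]
  des <- .design_full_reduced(groups, covariates)
  X <- des$X; Z <- des$Z; k <- des$k
  n <- length(values)
  fit <- stats::lm.fit(X, values)
  rss_full <- sum(fit$residuals^2)
  df_res <- n - ncol(X)
  if (df_res <= 0) stop("ancova: no residual df")
  fit_red <- stats::lm.fit(Z, values)
  rss_red <- sum(fit_red$residuals^2)
  df_g <- k - 1L
  sigma2 <- rss_full / df_res
  # degenerate perfect fits: a reduced model explaining everything leaves
  # nothing for group (F = 0); a full-only perfect fit separates (F = Inf)
  tol <- 1e-12 * max(sum(values^2), .Machine$double.xmin)
  f <- if (rss_red <= tol) 0
       else if (rss_full <= tol) Inf
       else ((rss_red - rss_full) / df_g) / sigma2
  p <- stats::pf(f, df_g, df_res, lower.tail = FALSE)

  # adjusted means: prediction at covariate means per group
  XtXinv <- chol2inv(chol(crossprod(X)))
  beta <- fit$coefficients
  lv <- levels(des$groups)
  cov_means <- if (ncol(X) > k) colMeans(X[, (k + 1L):ncol(X), drop = FALSE])
               else numeric(0)
  Cmat <- matrix(0, k, ncol(X), dimnames = list(lv, colnames(X)))
  Cmat[, 1L] <- 1
  for (i in seq_len(k)) {
    if (i < k) Cmat[i, 1L + i] <- 1 else Cmat[k, 2L:k] <- -1
  }
  if (length(cov_means)) Cmat[, (k + 1L):ncol(X)] <- rep(cov_means, each = k)
  adj <- as.vector(Cmat %*% beta)
  adj_se <- sqrt(sigma2 * diag(Cmat %*% XtXinv %*% t(Cmat)))
  names(adj) <- names(adj_se) <- lv

  pairs <- utils::combn(k, 2L)
  ctab <- data.frame(
    group1 = lv[pairs[1L, ]], group2 = lv[pairs[2L, ]],
    estimate = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    cvec <- Cmat[pairs[1L, j], ] - Cmat[pairs[2L, j], ]
    est <- sum(cvec * beta)
    se <- sqrt(sigma2 * as.numeric(t(cvec) %*% XtXinv %*% cvec))
    tv <- est / se
    ctab$estimate[j] <- est; ctab$se[j] <- se; ctab$t[j] <- tv
    ctab$p[j] <- 2 * stats::pt(abs(tv), df_res, lower.tail = FALSE)
  }
  ctab$p_adj <- stats::p.adjust(ctab$p, method = p_adjust)

  structure(list(F = f, p = p, df = c(df_g, df_res),
                 adjusted_means = adj, adjusted_se = adj_se,
                 contrasts = ctab, n = n, p_adjust = p_adjust),
            class = "ancova_result")
}

#' Partial correlation
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing
#' each on the covariates (with intercept); the p-value is t-based with
#' `df = n - n_covariates - 2`. With no covariates this is the plain
#' Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame/matrix of numeric covariates, or NULL.
#' @return list: `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  ok <- stats::complete.cases(x, y,
                              if (is.null(covariates)) rep(TRUE, length(x))
                              else as.data.frame(covariates))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  q <- 0L
  if (!is.null(covariates)) {
    C <- as.matrix(as.data.frame(covariates)[ok, , drop = FALSE])
    storage.mode(C) <- "double"
    q <- ncol(C)
    Z <- cbind(1, C)
    x <- stats::lm.fit(Z, x)$residuals
    y <- stats::lm.fit(Z, y)$residuals
  }
  df <- n - q - 2L
  if (df <= 0) stop("partial_correlation: insufficient df (n too small)")
  r <- stats::cor(x, y)
  tv <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(tv), df, lower.tail = FALSE)
  if (abs(r) >= 1) p <- 0
  list(r = r, p = p, df = df, n = n)
}
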