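test_that("one_way_anova agrees with anova_from_summary on its own summaries", {
  set.seed(1)
  for (rep in 1:5) {
    g <- factor(sample(c("a", "b", "c"), 60, replace = TRUE))
    while (any(table(g) < 2)) g <- factor(sample(c("a", "b", "c"), 60, TRUE))
    y <- rnorm(60) + as.integer(g) * rnorm(1)
    raw <- one_way_anova(y, g)
    summ <- anova_from_summary(tapply(y, g, mean), tapply(y, g, sd),
                               as.vector(table(g)))
    expect_equal(raw$F, summ$F, tolerance = 1e-9)
    expect_equal(raw$p, summ$p, tolerance = 1e-9)
  }
  # oracle: stats::oneway.test with equal variances
  g <- factor(rep(c("a", "b", "c"), c(10, 14, 12)))
  y <- rnorm(36) + (g == "c")
  expect_equal(one_way_anova(y, g)$F,
               oneway.test(y ~ g, var.equal = TRUE)$statistic[[1]],
               tolerance = 1e-9)
})

test_that("degenerate ANOVA inputs are flagged or rejected", {
  r <- one_way_anova(c(1, 1, 2, 2), factor(c("a", "a", "b", "b")))
  expect_true(is.infinite(r$F) && r$degenerate)
  expect_error(one_way_anova(1:3, factor(c("a", "a", "b"))), "n >= 2")
  expect_equal(anova_from_summary(c(5, 5), c(1, 1), c(10, 10))$F, 0)
})

test_that("chi_square equals the brute-force oracle and handles edge cases", {
  set.seed(2)
  for (rep in 1:10) {
    tab <- matrix(rpois(6, 20) + 1, 3, 2)
    res <- chi_square(tab)
    # independent brute-force over cells
    expect_equal(res$chisq,
                 sum(vapply(seq_along(tab), function(i) {
                   e <- sum(tab[(i - 1) %% 3 + 1, ]) *
                     sum(tab[, (i - 1) %/% 3 + 1]) / sum(tab)
                   (tab[i] - e)^2 / e
                 }, numeric(1))), tolerance = 1e-9)
    expect_equal(res$chisq,
                 suppressWarnings(chisq.test(tab, correct = FALSE))$statistic[[1]],
                 tolerance = 1e-9)
  }
  prop <- outer(c(10, 20, 30), c(2, 3))     # perfectly proportional
  expect_equal(chi_square(prop)$chisq, 0, tolerance = 1e-9)
  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("ancova reduces, absorbs confounds, and recovers planted effects", {
  set.seed(3)
  n <- 120
  g <- factor(rep(c("a", "b", "c"), each = n / 3))
  y <- rnorm(n) + (g == "b") * 0.5
  # zero-variance covariates dropped -> equals one-way ANOVA
  r0 <- ancova(y, g, data.frame(const = rep(1, n)))
  expect_equal(r0$F, one_way_anova(y, g)$F, tolerance = 1e-9)
  # outcome identical to a covariate -> group F ~ 0
  cov1 <- rnorm(n)
  rc <- ancova(cov1, g, data.frame(cov1 = cov1))
  expect_lt(rc$F, 1e-9)
  # planted adjusted means recovered
  covs <- data.frame(age = rnorm(n, 60, 8))
  mu <- c(a = 1, b = 2, c = 3.5)
  yy <- mu[g] + 0.05 * (covs$age - 60) + rnorm(n, sd = 0.4)
  rr <- ancova(yy, g, covs)
  for (lev in names(mu))
    expect_lt(abs(rr$adjusted_means[[lev]] - mu[[lev]]),
              3 * rr$adjusted_se[[lev]])
  # group F invariant to affine covariate rescaling
  rr2 <- ancova(yy, g, data.frame(age = covs$age * 13 - 100))
  expect_equal(rr$F, rr2$F, tolerance = 1e-9)
  expect_equal(rr$contrasts$p, rr2$contrasts$p, tolerance = 1e-9)
  expect_error(ancova(yy, g, data.frame(a = covs$age, b = covs$age)),
               "rank deficient")
})

test_that("ancova pairwise contrasts match the lm oracle", {
  set.seed(4)
  n <- 90
  g <- factor(rep(c("x", "y", "z"), each = 30))
  cov1 <- rnorm(n)
  y <- rnorm(n) + (g == "z") + 0.3 * cov1
  res <- ancova(y, g, data.frame(cov1 = cov1))
  fit <- lm(y ~ g + cov1)          # treatment coding: coef gy = y - x
  sm <- summary(fit)$coefficients
  xy <- res$contrasts[res$contrasts$group1 == "x" & res$contrasts$group2 == "y", ]
  expect_equal(xy$estimate, -sm["gy", 1], tolerance = 1e-9)
  expect_equal(xy$se, sm["gy", 2], tolerance = 1e-9)
  expect_equal(xy$p, sm["gy", 4], tolerance = 1e-9)
})

test_that("partial_correlation reduces to Pearson and recovers truth", {
  set.seed(5)
  x <- rnorm(50); y <- 0.5 * x + rnorm(50)
  pc <- partial_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc$r, ct$estimate[[1]], tolerance = 1e-12)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-9)
  expect_equal(partial_correlation(x, x)$r, 1)
  # generative partial correlation 0.3 given one covariate, n = 10000
  n <- 10000
  z <- rnorm(n)
  rho <- 0.3
  a <- 0.6 * z + rnorm(n)
  b <- 0.6 * z + rho / sqrt(1 - rho^2) * (a - 0.6 * z) + rnorm(n)
  est <- partial_correlation(a, b, data.frame(z = z))
  expect_lt(abs(est$r - 0.3), 0.02)
  expect_error(partial_correlation(rnorm(3), rnorm(3), data.frame(z = rnorm(3))),
               "df")
})
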