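test_that("2^-deltaCt closed forms and log round trip", {
  expect_equal(delta_ct_expression(25, 25), 1.0)
  expect_equal(delta_ct_expression(26, 25), 0.5)
  expect_equal(delta_ct_expression(20, 25), 32.0)
  expect_warning(delta_ct_expression(NA, 25), "missing")
  expect_error(log_expression(0), "> 0")
  expect_equal(log_expression(1), 0)
  set.seed(1)
  ct <- runif(50, 18, 32); ref <- runif(50, 19, 21)
  # log2 o (2^-dCt) == -dCt exactly
  expect_equal(log_expression(delta_ct_expression(ct, ref), base = 2),
               -(ct - ref), tolerance = 1e-12)
  x <- sort(runif(20, 0.01, 100))
  expect_true(all(diff(log_expression(x)) > 0))   # monotone
})

test_that("mirna_panel computes expression for all non-reference columns", {
  ct <- data.frame(subject_id = c("s1", "s2"), group = c("control", "HT-CI"),
                   mir_a = c(25, 26), cel_mir_39 = c(25, 25))
  p <- mirna_panel(ct)
  expect_equal(p$mirnas, "mir_a")
  expect_equal(p$expression$mir_a, c(1, 0.5))
  expect_error(mirna_panel(ct[, -4]), "reference")
})

test_that("screen_differential recovers planted effects and applies strict thresholds", {
  set.seed(2)
  n <- 60
  groups <- rep(c("control", "HT-NC", "HT-CI"), each = n)
  base <- matrix(2^rnorm(3 * n * 3, sd = 0.2), ncol = 3,
                 dimnames = list(NULL, c("up_mir", "null_mir", "down_mir")))
  base[groups == "HT-CI", "up_mir"] <- base[groups == "HT-CI", "up_mir"] * 4
  base[groups == "HT-CI", "down_mir"] <- base[groups == "HT-CI", "down_mir"] / 4
  sr <- screen_differential(base, groups)
  expect_setequal(sr$candidates$mirna, c("up_mir", "down_mir"))
  expect_equal(sr$candidates$direction[sr$candidates$mirna == "up_mir"], "up")
  expect_equal(sr$candidates$direction[sr$candidates$mirna == "down_mir"], "down")
  expect_false("null_mir" %in% sr$candidates$mirna)

  # fold change exactly at the threshold is excluded (strict inequality)
  a <- rep(c(1, 2), 20); b <- a * 2      # log2FC exactly 1, p ~ 0
  m <- cbind(at_thr = c(b, a, a))
  groups2 <- rep(c("HT-CI", "control", "HT-NC"), each = 40)
  sr2 <- screen_differential(m, groups2, lfc_threshold = 1)
  expect_false("at_thr" %in% sr2$candidates$mirna)
  expect_error(screen_differential(m, rep("control", 120)), "absent")
})

test_that("screen is invariant to subject order and global scaling", {
  set.seed(3)
  n <- 30
  groups <- rep(c("control", "HT-NC", "HT-CI"), each = n)
  expr <- matrix(2^rnorm(3 * n * 2, sd = 0.4), ncol = 2,
                 dimnames = list(NULL, c("m1", "m2")))
  expr[groups == "HT-CI", "m1"] <- expr[groups == "HT-CI", "m1"] * 3
  s1 <- screen_differential(expr, groups)
  perm <- sample(length(groups))
  s2 <- screen_differential(expr[perm, ], groups[perm])
  expect_equal(s1$table$log2fc, s2$table$log2fc, tolerance = 1e-12)
  s3 <- screen_differential(expr * 1000, groups)
  expect_equal(s1$table$log2fc, s3$table$log2fc, tolerance = 1e-9)
  expect_equal(s1$table$p, s3$table$p, tolerance = 1e-9)
})

test_that("validation reduces to one-way ANOVA without covariates and
           recovers a planted HT-CI decrease with them", {
  cfg <- sim_config(n_per_group = c(30, 30, 34), seed = 4,
                    ct_effects = list(mir_down = c(0, 0, 1.2),
                                      mir_flat = c(0, 0, 0)))
  coh <- generate_cohort(cfg)
  panel <- mirna_panel(simulate_ct_panel(coh, cfg))
  v0 <- validate_candidates(panel, coh, covariates = character(0))
  f_oracle <- one_way_anova(panel$log_expression$mir_down, coh$group)$F
  expect_equal(v0$anova$F[v0$anova$mirna == "mir_down"], f_oracle,
               tolerance = 1e-9)
  v <- validate_candidates(panel, coh)
  cc <- v$contrasts[v$contrasts$mirna == "mir_down", ]
  ci_vs_ctl <- cc[cc$group1 == "control" & cc$group2 == "HT-CI", ]
  ci_vs_nc <- cc[cc$group1 == "HT-NC" & cc$group2 == "HT-CI", ]
  expect_gt(ci_vs_ctl$estimate, 0)       # HT-CI below control
  expect_lt(ci_vs_ctl$p, 0.01)
  expect_gt(ci_vs_nc$estimate, 0)        # HT-CI below HT-NC
  expect_lt(ci_vs_nc$p, 0.01)
  expect_error(validate_candidates(panel, coh, covariates = "nope"), "missing")
})

test_that("validation p-values are calibrated under permuted labels", {
  cfg <- sim_config(n_per_group = c(20, 20, 20), seed = 8,
                    ct_effects = list(m = c(0, 0, 0)))
  coh <- generate_cohort(cfg)
  set.seed(8)
  ps <- replicate(60, {
    ct <- simulate_ct_panel(coh, sim_config(n_per_group = c(20, 20, 20),
                                            seed = sample.int(1e6, 1),
                                            ct_effects = list(m = c(0, 0, 0))))
    panel <- mirna_panel(ct)
    grp <- sample(coh$group)
    ancova(panel$log_expression$m, grp, NULL)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
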