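make_map_stack <- function(n, d = c(8, 8, 4), sd = 0.1, mean = 1, seed = 1) {
  set.seed(seed)
  array(rnorm(prod(d) * n, mean, sd), c(d, n))
}

test_that("voxelwise_ancova matches the per-voxel ancova loop exactly", {
  d <- c(4, 4, 2)
  n <- 24
  g <- factor(rep(c("control", "HT-NC", "HT-CI"), each = 8),
              levels = COHORT_GROUPS)
  covs <- data.frame(age = rnorm(n, 60, 5), edu = rnorm(n, 12, 3))
  arr <- make_map_stack(n, d, seed = 2)
  mask <- array(TRUE, d)
  sm <- voxelwise_ancova(arr, g, covs, mask = mask)
  for (vox in list(c(1, 1, 1), c(3, 2, 2), c(4, 4, 1))) {
    y <- arr[vox[1], vox[2], vox[3], ]
    expect_equal(sm$F[vox[1], vox[2], vox[3]], ancova(y, g, covs)$F,
                 tolerance = 1e-9)
  }
  # covariate-free call equals voxel-wise one-way ANOVA
  sm0 <- voxelwise_ancova(arr, g, mask = mask)
  y <- arr[2, 2, 1, ]
  expect_equal(sm0$F[2, 2, 1], one_way_anova(y, g)$F, tolerance = 1e-9)
  # identical maps across subjects -> F = 0 everywhere
  same <- array(rep(as.vector(make_map_stack(1, d, seed = 3)), n), c(d, n))
  smc <- voxelwise_ancova(same, g, mask = mask)
  expect_lt(max(smc$F, na.rm = TRUE), 1e-9)
})

test_that("label_clusters respects the connectivity scheme", {
  d <- c(5, 5, 3)
  supra <- array(FALSE, d)
  supra[1, 1, 1] <- TRUE
  supra[2, 2, 1] <- TRUE      # diagonal in-plane neighbor
  supra[4, 4, 3] <- TRUE      # isolated
  lab26 <- label_clusters(supra, 26)
  expect_equal(max(lab26), 2L)
  expect_equal(lab26[1, 1, 1], lab26[2, 2, 1])
  lab6 <- label_clusters(supra, 6)
  expect_equal(max(lab6), 3L)  # face connectivity splits the diagonal pair
  expect_equal(sum(label_clusters(array(FALSE, d)) > 0), 0L)
})

test_that("cluster inference recovers a planted block and respects min_size", {
  d <- c(16, 16, 8)
  mask <- ellipsoid_mask(d)
  n <- 30
  g <- factor(rep(COHORT_GROUPS, each = 10), levels = COHORT_GROUPS)
  block <- array(FALSE, d); block[5:8, 5:8, 3:4] <- TRUE; block <- block & mask
  set.seed(4)
  maps <- lapply(seq_len(n), function(i) {
    m <- array(rnorm(prod(d), 1, 0.1), d)
    if (g[i] == "HT-CI") m[block] <- m[block] - 0.4
    m[!mask] <- NA
    m
  })
  cl <- cluster_threshold(maps, g, mask = mask, n_perm = 1000, seed = 5)
  ret <- cl$clusters[cl$clusters$retained, ]
  expect_equal(nrow(ret), 1L)
  overlap <- sum(cl$labels > 0 & block) / sum(block)
  expect_gte(overlap, 0.8)
  # peak lies inside its cluster
  peak_idx <- ret$peak_i + 1 + ret$peak_j * d[1] + ret$peak_k * d[1] * d[2]
  expect_equal(cl$labels[peak_idx], ret$cluster_id)
  # permutation null is reproducible under a fixed seed
  cl2 <- cluster_threshold(maps, g, mask = mask, n_perm = 1000, seed = 5)
  expect_identical(cl$null_max_sizes, cl2$null_max_sizes)
  expect_identical(cl$clusters, cl2$clusters)
  # min_size = Inf retains nothing
  cl3 <- cluster_threshold(maps, g, mask = mask, n_perm = 100, seed = 5,
                           min_size = Inf)
  expect_false(any(cl3$clusters$retained))
  expect_error(cluster_threshold(maps, g, mask = mask, n_perm = 50), "100")
})

test_that("cluster labels are invariant to subject ordering", {
  d <- c(10, 10, 4)
  mask <- array(TRUE, d)
  n <- 18
  g <- factor(rep(COHORT_GROUPS, each = 6), levels = COHORT_GROUPS)
  set.seed(6)
  arr <- make_map_stack(n, d, seed = 6)
  arr[3:5, 3:5, 2, g == "HT-CI"] <- arr[3:5, 3:5, 2, g == "HT-CI"] - 0.5
  cl1 <- cluster_threshold(arr, g, mask = mask, n_perm = 100, seed = 7,
                           cluster_p = 0.5, min_size = 2)
  perm <- sample(n)
  cl2 <- cluster_threshold(arr[, , , perm], g[perm], mask = mask,
                           n_perm = 100, seed = 7, cluster_p = 0.5,
                           min_size = 2)
  expect_identical(cl1$all_labels, cl2$all_labels)
})

test_that("ROI means and post-hoc contrasts follow the planted ordering", {
  d <- c(8, 8, 4)
  labels <- array(0L, d)
  labels[2:3, 2:3, 2] <- 1L          # 4-voxel cluster
  labels[6, 6, 3] <- 2L              # singleton
  n <- 15
  arr <- array(2, c(d, n))           # uniform value 2
  rm <- extract_roi_means(arr, labels)
  expect_equal(unique(unlist(rm[paste0("cluster_", 1:2)])), 2)
  arr[6, 6, 3, 4] <- 9
  rm2 <- extract_roi_means(arr, labels)
  expect_equal(rm2$cluster_2[4], 9)  # singleton mean = the voxel itself

  g <- factor(rep(COHORT_GROUPS, each = 5), levels = COHORT_GROUPS)
  set.seed(7)
  roi <- data.frame(cluster_1 = rnorm(n, 1, 0.05) - (g == "HT-CI") * 0.5)
  ph <- posthoc_group_contrasts(roi, g)
  row <- ph[ph$group1 == "control" & ph$group2 == "HT-CI", ]
  expect_gt(row$estimate, 0)
  expect_lt(row$p, 0.001)
  # two-group reduction equals the two-sample ANCOVA contrast oracle
  two <- droplevels(g[g != "HT-NC"])
  r2 <- ancova(roi$cluster_1[g != "HT-NC"], two)
  t2 <- t.test(roi$cluster_1[g == "control"], roi$cluster_1[g == "HT-CI"],
               var.equal = TRUE)
  expect_equal(abs(r2$contrasts$t), abs(t2$statistic[[1]]), tolerance = 1e-9)
  expect_error(extract_roi_means(arr, array(0L, d)), "no retained")
})
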