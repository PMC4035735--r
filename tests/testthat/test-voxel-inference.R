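test_that("slope t equals the closed form r sqrt(n-2)/sqrt(1-r^2) voxelwise", {
  set.seed(41)
  for (n in c(6, 15, 40)) {
    arr <- array(rnorm(5 * 4 * 3 * n), c(5, 4, 3, n))
    z <- rnorm(n)
    tm <- voxelwise_slope_t(arr, z)
    r <- apply(matrix(arr, ncol = n), 1, function(v) cor(v, z))
    t_closed <- r * sqrt(n - 2) / sqrt(1 - r^2)
    expect_equal(as.vector(tm$values), t_closed, tolerance = 1e-10)
    expect_equal(tm$df, n - 2L)
  }
})

test_that("perfect linear fits are capped at the sentinel and flagged", {
  n <- 8
  z <- seq_len(n)
  arr <- array(rnorm(2 * 2 * 2 * n), c(2, 2, 2, n))
  arr[1, 1, 1, ] <- 3 * z + 2        # exact positive fit
  arr[2, 2, 2, ] <- -0.5 * z + 1     # exact negative fit
  tm <- voxelwise_slope_t(arr, z)
  expect_equal(tm$values[1, 1, 1], 1e6)
  expect_equal(tm$values[2, 2, 2], -1e6)
  expect_true(tm$capped[1, 1, 1] && tm$capped[2, 2, 2])
  expect_false(tm$capped[1, 2, 1])
})

test_that("degenerate inputs are rejected or neutralized", {
  arr <- array(rnorm(4^3 * 6), c(4, 4, 4, 6))
  expect_error(voxelwise_slope_t(arr, rep(1, 6)), "zero variance")
  expect_error(voxelwise_slope_t(arr, rnorm(5)), "length")
  expect_error(voxelwise_slope_t(array(rnorm(4^3 * 3), c(4, 4, 4, 3)),
                                 rnorm(3)), "at least 4")
  # voxel constant across subjects -> t = 0, not NaN
  arr[2, 3, 1, ] <- 7
  tm <- voxelwise_slope_t(arr, rnorm(6))
  expect_equal(tm$values[2, 3, 1], 0)
})

test_that("a global shift of all maps is absorbed by the intercept", {
  set.seed(43)
  n <- 12
  arr <- array(rnorm(4^3 * n), c(4, 4, 4, n))
  z <- rnorm(n)
  t0 <- voxelwise_slope_t(arr, z)$values
  expect_equal(voxelwise_slope_t(arr + 5.3, z)$values, t0, tolerance = 1e-8)
  # predictor location/scale changes do not move the t-map either
  expect_equal(voxelwise_slope_t(arr, 10 * z - 2)$values, t0, tolerance = 1e-8)
})

test_that("null t-values follow the t distribution with n-2 df", {
  set.seed(47)
  n <- 30
  arr <- array(rnorm(2000 * n), c(20, 10, 10, n))
  z <- rnorm(n)
  tm <- voxelwise_slope_t(arr, z)
  ks <- suppressWarnings(stats::ks.test(as.vector(tm$values),
                                        function(q) pt(q, df = n - 2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("cluster labeling matches the BFS oracle on random small grids", {
  set.seed(53)
  for (rep in 1:6) {
    dims <- sample(4:12, 3, replace = TRUE)
    tvals <- array(rnorm(prod(dims)), dims)
    for (conn in c(6, 18, 26)) {
      cs <- label_clusters(tvals, t_threshold = 0.8, connectivity = conn)
      ref <- oracle_bfs_label(tvals > 0.8, conn)
      expect_true(same_partition(cs$label_map, ref))
      expect_equal(sort(cs$sizes), sort(tabulate(ref[ref > 0])))
    }
  }
})

test_that("corner-touching blobs merge under 26- but not 6/18-connectivity", {
  tvals <- array(0, c(8, 8, 8))
  tvals[2:3, 2:3, 2:3] <- 5  # blob A
  tvals[4:5, 4:5, 4:5] <- 5  # blob B, touches A only at corner (3,3,3)-(4,4,4)
  expect_equal(length(label_clusters(tvals, 3.5, 26)$sizes), 1L)
  expect_equal(length(label_clusters(tvals, 3.5, 18)$sizes), 2L)
  expect_equal(length(label_clusters(tvals, 3.5, 6)$sizes), 2L)
})

test_that("empty and singleton suprathreshold sets label correctly", {
  tvals <- array(0, c(5, 5, 5))
  expect_equal(length(label_clusters(tvals, 3.5, 26)$sizes), 0L)
  tvals[3, 3, 3] <- 4
  cs <- label_clusters(tvals, 3.5, 26, voxel_size_mm = c(2, 2, 2))
  expect_equal(cs$sizes, 1L)
  expect_equal(cs$volumes_cm3, 8 / 1000)
})

test_that("cluster sizes are invariant to axis relabeling of the grid", {
  set.seed(59)
  tvals <- array(rnorm(10 * 8 * 6), c(10, 8, 6))
  a <- label_clusters(tvals, 1, 26)
  b <- label_clusters(aperm(tvals, c(3, 1, 2)), 1, 26)
  expect_equal(sort(a$sizes), sort(b$sizes))
})

test_that("the permutation null is seeded, deterministic, and degenerate-safe", {
  set.seed(61)
  n <- 10
  arr <- array(rnorm(6^3 * n, sd = 0.02), c(6, 6, 6, n))
  z <- rnorm(n)
  a <- permutation_null(arr, z, n_perm = 120, seed = 5)
  b <- permutation_null(arr, z, n_perm = 120, seed = 5)
  expect_identical(a$max_cluster_sizes, b$max_cluster_sizes)
  expect_identical(a$critical_size, b$critical_size)
  c2 <- permutation_null(arr, z, n_perm = 120, seed = 6)
  expect_false(identical(a$max_cluster_sizes, c2$max_cluster_sizes))

  # identical maps across subjects: no between-subject variance anywhere
  same <- array(rep(rnorm(6^3), n), c(6, 6, 6, n))
  d <- permutation_null(same, z, n_perm = 120, seed = 5)
  expect_true(all(d$max_cluster_sizes == 0))

  expect_error(permutation_null(arr, z, n_perm = 50, seed = 1), ">= 100")
  expect_error(permutation_null(arr, z, n_perm = 120), "seed")
})

test_that("significance calls use the strict critical-size rule and the p floor", {
  set.seed(67)
  n <- 20
  # strong planted signal in a block
  z <- rnorm(n)
  arr <- array(rnorm(8^3 * n, sd = 0.05), c(8, 8, 8, n))
  for (i in seq_len(n)) arr[3:6, 3:6, 3:6, i] <- arr[3:6, 3:6, 3:6, i] + z[i]
  cs <- label_clusters(voxelwise_slope_t(arr, z), 3.5, 26)
  nl <- permutation_null(arr, z, t_threshold = 3.5, n_perm = 199, seed = 3)
  roi <- significant_clusters(cs, nl, alpha = 0.05)
  big <- which.max(cs$sizes)
  expect_true(roi$table$significant[big])
  if (max(cs$sizes) > max(nl$max_cluster_sizes))
    expect_equal(min(roi$table$p_corrected), 1 / (nl$n_perm + 1))

  # observed never beats the null -> empty mask
  null_arr <- array(rnorm(8^3 * n, sd = 0.05), c(8, 8, 8, n))
  cs0 <- label_clusters(voxelwise_slope_t(null_arr, z), 10, 26)
  nl0 <- permutation_null(null_arr, z, t_threshold = 10, n_perm = 199, seed = 3)
  roi0 <- significant_clusters(cs0, nl0)
  expect_false(any(roi0$mask))

  # settings mismatch is a usage error
  nl_wrong <- permutation_null(arr, z, t_threshold = 2, n_perm = 199, seed = 3)
  expect_error(significant_clusters(cs, nl_wrong), "threshold/connectivity")
  expect_error(significant_clusters(cs, nl, alpha = 0.7), "alpha")
})

test_that("corrected p-values are valid under the familywise null", {
  # per-cohort corrected p for the max cluster: P(p <= alpha) <= alpha + margin
  set.seed(71)
  n_rep <- 40
  hits <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    n <- 12
    arr <- array(rnorm(8^3 * n), c(8, 8, 8, n))
    z <- rnorm(n)
    cs <- label_clusters(voxelwise_slope_t(arr, z), 2.5, 26)
    nl <- permutation_null(arr, z, t_threshold = 2.5, n_perm = 120, seed = r)
    roi <- significant_clusters(cs, nl)
    hits[r] <- any(roi$table$significant)
  }
  # binomial(40, 0.05) upper 99.5% is ~7
  expect_lte(sum(hits), 7)
})

test_that("cluster_inference bundles the stages consistently", {
  coh <- generate_cohort(cohort_spec(n_subjects = 16L,
                                     grid_shape = c(10L, 10L, 10L),
                                     planted_region = list(
                                       center = c(5.5, 5.5, 5.5),
                                       radii = c(3, 3, 3)),
                                     effect_beta = 0.05, seed = 2L))
  maps <- lapply(coh$maps, normalize_to_two_years)
  fit <- cluster_inference(maps, coh$subject_table$fornix_fa,
                           n_perm = 150, seed = 9)
  expect_s3_class(fit, "cluster_inference")
  expect_identical(dim(fit$roi$mask), dim(fit$tmap$values))
  # mask is a subset of the suprathreshold set
  expect_true(all(fit$tmap$values[fit$roi$mask] > fit$clusters$t_threshold))
  expect_output(print(fit), "Significant region")
})
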