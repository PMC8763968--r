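test_that("density clustering handles separated groups and all-noise cases", {
  # two groups of 5 points separated by 10x eps
  set.seed(5)
  g1 <- matrix(rnorm(10, 0, 2), ncol = 2)
  g2 <- matrix(rnorm(10, 0, 2), ncol = 2) + 400 # 10 x eps (eps = 40 px)
  lab <- cluster_vesicles(rbind(g1, g2), eps_nm = 200, min_pts = 3,
                          nm_per_px = 5)
  expect_equal(length(unique(lab[lab > 0])), 2)
  expect_true(all(lab[1:5] == lab[1]) && all(lab[6:10] == lab[6]))
  expect_true(lab[1] != lab[6])
  # all points pairwise beyond eps, min_pts 2 -> all noise
  far <- cbind(seq(0, 1000, by = 100), 0)
  expect_true(all(cluster_vesicles(far, 200, 2, 5) == -1L))
})

test_that("density clustering matches brute-force reachability closure", {
  set.seed(17)
  for (k in 1:40) {
    n <- sample(5:30, 1)
    pts <- matrix(runif(2 * n, 0, 60), ncol = 2)
    eps <- runif(1, 5, 20); mp <- sample(2:4, 1)
    a <- cluster_vesicles(pts, eps_nm = eps, min_pts = mp, nm_per_px = 1)
    b <- brute_dbscan(pts, eps, mp)
    expect_true(same_clustering(a, b))
  }
})

test_that("cell profiles: counts, detectability and density", {
  p0 <- cell_profile(matrix(numeric(0), 0, 2), nm_per_px = 5)
  expect_equal(p0$vesicle_count, 0)
  expect_false(p0$detectable)
  expect_true(is.na(p0$density_per_um2))
  # 4 instances at the corners of a 1 um square -> density 4 per um^2
  sq <- cbind(c(0, 200, 200, 0), c(0, 0, 200, 200)) # px at 5 nm/px
  p4 <- cell_profile(sq, min_count = 1, eps_nm = 2000, min_pts = 1,
                     nm_per_px = 5)
  expect_equal(p4$vesicle_count, 4)
  expect_true(p4$detectable)
  expect_equal(p4$density_per_um2, 4)
  # collinear points -> degenerate hull, density undefined, count kept
  col3 <- cbind(c(0, 50, 100), c(0, 50, 100))
  pc <- cell_profile(col3, nm_per_px = 5)
  expect_equal(pc$vesicle_count, 3)
  expect_true(is.na(pc$density_per_um2))
})

test_that("adding a point never decreases the hull area", {
  set.seed(29)
  for (k in 1:50) {
    pts <- matrix(rnorm(2 * 10), ncol = 2)
    a0 <- convex_hull_area(pts)
    a1 <- convex_hull_area(rbind(pts, rnorm(2, sd = 2)))
    expect_gte(a1 + 1e-12, a0)
  }
})

test_that("median recovered density tracks the generator density", {
  # dense cells: the hull-of-cluster denominator is consistent when the
  # point spacing is well under eps and boundary deficits are small
  r <- experiment_density_recovery(density = 80, n_cells = 12, seed = 3)
  expect_lt(abs(r$ratio - 1), 0.25)
})

test_that("doubling the generator density doubles recovered density within 30%", {
  # both densities in the single-cluster regime (spacing well under eps),
  # where the hull denominator is consistent
  r1 <- experiment_density_recovery(density = 80, n_cells = 12, seed = 5)
  r2 <- experiment_density_recovery(density = 160, n_cells = 12, seed = 6)
  ratio <- r2$median_recovered / r1$median_recovered
  expect_gt(ratio, 2 * 0.7)
  expect_lt(ratio, 2 * 1.3)
})
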