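test_that("chi-square 2x2 matches hand computation and symmetry", {
  hom <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(hom$statistic, 0)
  expect_equal(hom$p_value, 1)
  # [[20,5],[5,20]]: all expected counts 12.5, X^2 = 4 * 7.5^2 / 12.5 = 18
  tab <- matrix(c(20, 5, 5, 20), 2, byrow = TRUE)
  r <- chi_square_2x2(tab)
  expect_equal(r$statistic, 18, tolerance = 1e-9)
  expect_equal(r$p_value, pchisq(18, df = 1, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_lt(abs(r$p_value - 2.2e-5), 1e-6)
  # swapping both rows and both columns leaves the statistic unchanged
  set.seed(4)
  for (k in 1:20) {
    t1 <- matrix(rpois(4, 20) + 1, 2)
    s1 <- chi_square_2x2(t1)$statistic
    s2 <- chi_square_2x2(t1[2:1, 2:1])$statistic
    expect_equal(s1, s2, tolerance = 1e-12)
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "margins")
})

test_that("KS test matches trivial cases and exact enumeration at small n", {
  x <- c(1, 2, 3, 4.5)
  r <- ks_two_sample(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(ks_two_sample(1:5, 11:15)$statistic, 1)

  # exact p at nx = ny = 5 equals full permutation enumeration
  ks_stat <- function(x, y) {
    v <- sort(unique(c(x, y)))
    max(abs(ecdf(x)(v) - ecdf(y)(v)))
  }
  set.seed(9)
  for (k in 1:10) {
    z <- round(rnorm(10), 3) # distinct values, no ties
    obs <- ks_stat(z[1:5], z[6:10])
    splits <- combn(10, 5)
    ds <- apply(splits, 2, function(i) ks_stat(z[i], z[-i]))
    p_enum <- mean(ds >= obs - 1e-12)
    expect_equal(ks_two_sample(z[1:5], z[6:10])$p_value, p_enum,
                 tolerance = 1e-6)
  }
})

test_that("t test wrapper reports statistic, p and group sizes", {
  set.seed(2)
  x <- rnorm(12); y <- rnorm(15, 1)
  r <- t_test_groups(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value)
  expect_equal(c(r$n1, r$n2), c(12, 15))
})

test_that("group summaries report mean, SEM and detectable proportions", {
  profs <- data.frame(cell_id = letters[1:5],
                      group = c("a", "a", "a", "b", "b"),
                      vesicle_count = c(4, 5, 6, 1, 7),
                      hull_area_um2 = 1,
                      density_per_um2 = c(1, 2, 3, NA, 4),
                      detectable = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  s <- summarize_groups(profs)
  a <- s[s$group == "a", ]
  expect_equal(a$mean, 2)
  expect_equal(a$sem, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(a$prop_detectable, 1)
  b <- s[s$group == "b", ]
  expect_equal(b$n_value, 1)
  expect_equal(b$sem, 0) # single-value group, flagged
  expect_true(b$single_cell_group)
  expect_equal(b$prop_detectable, 0.5)
})

test_that("SEM agrees with a bootstrap standard error on a large group", {
  set.seed(31)
  v <- rgamma(400, 3, 1)
  profs <- data.frame(cell_id = seq_along(v), group = "g",
                      vesicle_count = 5, hull_area_um2 = 1,
                      density_per_um2 = v, detectable = TRUE)
  s <- summarize_groups(profs)
  boot <- replicate(2000, mean(sample(v, replace = TRUE)))
  expect_lt(abs(s$sem - sd(boot)) / sd(boot), 0.1)
})
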