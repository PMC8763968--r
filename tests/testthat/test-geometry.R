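test_that("shoelace area matches closed forms and a Monte-Carlo oracle", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_area(sq[4:1, ]), 1) # orientation-independent
  tri <- cbind(c(0, 4, 0), c(0, 0, 3))
  expect_equal(polygon_area(tri), 6)

  # random star-shaped simple polygon vs point-in-polygon Monte Carlo
  set.seed(11)
  th <- sort(runif(17, 0, 2 * pi))
  r <- runif(17, 0.5, 1.5)
  poly <- cbind(r * cos(th), r * sin(th))
  a <- polygon_area(poly)
  px <- runif(1e6, -1.5, 1.5); py <- runif(1e6, -1.5, 1.5)
  mc <- mean(point_in_polygon(px, py, poly)) * 9
  expect_lt(abs(mc - a) / a, 0.01)
})

test_that("Feret diameter equals the all-pairs brute force on random polygons", {
  circ <- ellipse_polygon(10, 10, n = 720)
  expect_equal(feret_diameter(circ), 20, tolerance = 1e-3)
  rect <- cbind(c(0, 2, 2, 0), c(0, 0, 1, 1))
  expect_equal(feret_diameter(rect), sqrt(5))
  set.seed(7)
  for (k in 1:100) {
    pts <- matrix(rnorm(2 * sample(5:40, 1)), ncol = 2)
    brute <- sqrt(max(dist(pts)^2))
    expect_equal(feret_diameter(pts), brute, tolerance = 1e-12)
  }
})

test_that("second-moment axis ratio is 1 for circles and squares, a/b for ellipses", {
  expect_equal(ellipse_axis_ratio(ellipse_polygon(5, 5, n = 720)), 1,
               tolerance = 0.01)
  expect_equal(ellipse_axis_ratio(ellipse_polygon(4, 2, n = 720)), 2,
               tolerance = 0.02)
  # square second moments are equal, so the ratio is exactly 1
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(ellipse_axis_ratio(sq), 1, tolerance = 1e-9)
  # rotation leaves the ratio unchanged
  for (ang in c(0.3, 1.1, 2.5))
    expect_equal(ellipse_axis_ratio(ellipse_polygon(4, 2, angle = ang, n = 720)),
                 2, tolerance = 0.02)
})

test_that("convex hull area matches an O(n^3) brute force on >= 100 instances", {
  sq_um <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)) * 200 # 1 um at 5 nm/px
  expect_equal(convex_hull_area(sq_um) * (5 / 1000)^2, 1)
  expect_true(is.na(convex_hull_area(cbind(1:3, 1:3)))) # collinear
  set.seed(23)
  for (k in 1:110) {
    n <- sample(3:14, 1)
    pts <- matrix(round(rnorm(2 * n), 2), ncol = 2)
    a <- convex_hull_area(pts)
    b <- brute_hull_area(unique(pts))
    if (is.na(a) || is.na(b)) expect_equal(is.na(a), is.na(b))
    else expect_lt(abs(a - b) / max(b, 1e-12), 1e-9)
  }
})

test_that("contour validation rejects degenerate and self-intersecting polygons", {
  expect_error(validate_contour(cbind(c(0, 1), c(0, 1))), "at least 3")
  expect_error(validate_contour(cbind(c(0, 1, 2), c(0, 0, 0))), "zero area")
  bow <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(validate_contour(bow), "self-intersecting")
  expect_silent(validate_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))))
})

test_that("distances to a contour are exact for concentric circles", {
  inner <- ellipse_polygon(1, 1, n = 720)
  outer <- ellipse_polygon(1.03, 1.03, n = 720)
  d <- dist_to_contour(inner, outer)
  expect_true(all(abs(d - 0.03) < 1e-4))
})
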