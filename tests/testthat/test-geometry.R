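test_that("rotation checking accepts rotations and rejects everything else", {
  expect_true(check_rotation(diag(3)))
  expect_false(check_rotation(diag(c(1, 1, -1))))   # reflection
  expect_false(check_rotation(2 * diag(3)))         # scaling
  rod <- rotation_about_axis(c(1, 1, 1) / sqrt(3), 0.7)
  expect_true(check_rotation(rod))
  expect_lt(max(abs(t(rod) %*% rod - diag(3))), 1e-12)
  set.seed(9)
  for (i in 1:20) {
    expect_true(check_rotation(rotation_about_axis(runif(3, -1, 1) + 1e-4,
                                                   runif(1, -pi, pi))))
  }
})

test_that("rigid transforms are exact isometries", {
  pts <- matrix(runif(30, -10, 10), ncol = 3)
  expect_equal(transform_points(pts, diag(3)), pts)
  expect_equal(transform_points(matrix(c(0, 0, 0), 1), diag(3),
                                c(1, 2, 3)),
               matrix(c(1, 2, 3), 1))
  set.seed(19)
  for (i in 1:25) {
    cloud <- matrix(runif(60, -50, 50), ncol = 3)
    rot <- rotation_about_axis(runif(3, -1, 1) + 1e-4, runif(1, -pi, pi))
    moved <- transform_points(cloud, rot, runif(3, -10, 10))
    d0 <- dist(cloud)
    d1 <- dist(moved)
    expect_lt(max(abs(d1 - d0) / pmax(d0, 1e-12)), 1e-9)
  }
  expect_error(transform_points(pts, diag(c(1, 1, -1))), "proper rotation")
})

test_that("bounding spheres contain their points within the Ritter bound", {
  one <- bounding_sphere(c(1, 2, 3))
  expect_equal(one$center, c(1, 2, 3))
  expect_equal(one$radius, 0)
  two <- bounding_sphere(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(two$center, c(1, 0, 0))
  expect_equal(two$radius, 1)
  expect_error(bounding_sphere(matrix(numeric(0), ncol = 3)), "empty")
  set.seed(11)
  for (i in 1:10) {
    pts <- matrix(runif(300, -10, 10), ncol = 3)
    got <- bounding_sphere(pts)
    d <- sqrt(colSums((t(pts) - got$center)^2))
    expect_true(all(d <= got$radius * (1 + 1e-9) + 1e-12))
    exact <- min_enclosing_sphere(pts)
    expect_lte(got$radius, exact$radius * 1.1)
  }
})

test_that("focus-derived cameras satisfy the sphere-in-cone closed form", {
  cam <- camera_from_focus(list(center = c(0, 0, 0), radius = 10),
                           direction = c(0, 0, -1), up = c(0, 1, 0),
                           fov_deg = 90)
  expect_equal(sqrt(sum((cam$position - cam$target)^2)), 10 / sin(pi / 4),
               tolerance = 1e-12)
  expect_equal(cam$position, c(0, 0, 10 / sin(pi / 4)))
  expect_equal(cam$up, c(0, 1, 0))
  # radius-0 target: the 0.01-A floor keeps the camera finite
  tiny <- camera_from_focus(list(center = c(1, 1, 1), radius = 0))
  d <- sqrt(sum((tiny$position - tiny$target)^2))
  expect_true(is.finite(d) && d > 0)
  expect_equal(d, 0.01 / sin(22.5 * pi / 180), tolerance = 1e-12)
  expect_error(camera_from_focus(list(center = c(0, 0, 0), radius = 1),
                                 direction = c(0, 0, 0)), "degenerate")
  expect_error(camera_from_focus(list(center = c(0, 0, 0), radius = 1),
                                 direction = c(0, 0, -1), up = c(0, 0, 1)),
               "parallel")
})

test_that("every sphere surface point lies inside the view cone", {
  set.seed(29)
  for (trial in 1:100) {
    sph <- list(center = runif(3, -20, 20), radius = runif(1, 0.1, 15))
    fov <- runif(1, 20, 160)
    dir <- runif(3, -1, 1) + 1e-4
    cam <- camera_from_focus(sph, direction = dir, fov_deg = fov)
    axis <- sph$center - cam$position
    axis <- axis / sqrt(sum(axis^2))
    u <- matrix(rnorm(600), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    surface <- sweep(u * sph$radius, 2, sph$center, "+")
    v <- sweep(surface, 2, cam$position, "-")
    ang <- acos(pmin(1, (v %*% axis) / sqrt(rowSums(v^2))))
    expect_true(all(ang <= fov / 2 * pi / 180 + 1e-9))
  }
})

test_that("distance and angle measurements are exact and well-conditioned", {
  expect_identical(measure_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_identical(measure_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  # collinear triples clamp instead of producing NaN
  expect_identical(measure_angle(c(1, 0, 0), c(0, 0, 0), c(2, 0, 0)), 0)
  expect_identical(measure_angle(c(-1, 0, 0), c(0, 0, 0), c(2, 0, 0)), 180)
  expect_error(measure_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "coincides")
  set.seed(39)
  for (i in 1:50) {
    a <- runif(3, -5, 5); b <- runif(3, -5, 5); c <- runif(3, -5, 5)
    expect_equal(measure_distance(a, b), measure_distance(b, a))
    expect_lte(measure_distance(a, c),
               measure_distance(a, b) + measure_distance(b, c) + 1e-12)
    expect_equal(measure_angle(a, b, c), measure_angle(c, b, a),
                 tolerance = 1e-12)
  }
})

test_that("label templates format measured values to two decimals", {
  expect_identical(render_label_template("{{distance}} A", 14.1421),
                   "14.14 A")
  expect_identical(render_label_template("{{angle}} deg", 90), "90.00 deg")
  expect_identical(render_label_template("fixed text", 123), "fixed text")
  expect_error(render_label_template("{{foo}}", 1), "unknown placeholder")
  expect_error(render_label_template("{{distance}} {{angle}}", 1),
               "more than one")
})
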