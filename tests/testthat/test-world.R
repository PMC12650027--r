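test_that("terrain generation is deterministic and counts triangles", {
  m1 <- generate_terrain(seed = 11, n_objects = 5)
  m2 <- generate_terrain(seed = 11, n_objects = 5)
  expect_identical(as.matrix(m1), as.matrix(m2))
  expect_equal(nrow(m1), 2 + 5 * 8)
  m0 <- generate_terrain(seed = 1, n_objects = 0)
  expect_equal(nrow(m0), 2)
  expect_true(all(as.matrix(m0)[, c(3, 6, 9)] == 0))
  m50 <- generate_terrain(seed = 2, n_objects = 50)
  expect_equal(nrow(m50), 2 + 400)
  expect_true(all(as.matrix(m50)[, c(3, 6, 9)] >= 0))
})

test_that("terrain generation rejects invalid parameters", {
  expect_error(generate_terrain(1, extent = -1), "extent")
  expect_error(generate_terrain(1, height_range = c(-1, 2)), "height_range")
  expect_error(generate_terrain(1, n_objects = -3), "n_objects")
})

test_that("terrain round-trips through the plain-text triangle list", {
  m <- generate_terrain(seed = 4, n_objects = 3, extent = 5)
  path <- tempfile(fileext = ".txt")
  write_terrain(m, path)
  m2 <- read_terrain(path, extent = 5)
  expect_equal(as.matrix(m2), as.matrix(m), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("renderer matches a brute-force ray-casting oracle", {
  w <- small_world()
  pano <- render_panorama(w$mesh, c(0.5, -0.3))
  # spot-check a grid of pixels against the per-ray oracle
  el_grid <- seq(60, -10, length.out = 25) * pi / 180
  az_grid <- 2 * pi * (seq_len(90) - 1) / 90
  idx <- expand.grid(r = c(1, 8, 15, 20, 23, 25), c = seq(1, 90, by = 7))
  for (k in seq_len(nrow(idx))) {
    r <- idx$r[k]; c <- idx$c[k]
    expect_equal(pano[r, c],
                 oracle_pixel(w$tri, c(0.5, -0.3), az_grid[c], el_grid[r]),
                 info = sprintf("pixel (%d, %d)", r, c))
  }
})

test_that("renderer handles empty scenes, pillars and bounds", {
  empty <- generate_terrain(seed = 1, n_objects = 0, extent = 5)
  p <- render_panorama(empty, c(0, 0))
  expect_true(all(p[1:21, ] == 0))   # above-horizon rows are sky
  expect_true(all(p[22:25, ] == 0.5))  # below-horizon rows are ground
  # a single pillar due +x occupies columns centred at azimuth 0
  pillar <- tibble::tibble(x1 = 2, y1 = -0.3, z1 = 0, x2 = 2, y2 = 0.3,
                           z2 = 0, x3 = 2, y3 = 0, z3 = 0.5)
  attr(pillar, "extent") <- 5
  class(pillar) <- c("terrain_mesh", class(pillar))
  pp <- render_panorama(pillar, c(0, 0))
  occ <- which(apply(pp == 1, 2, any))
  expect_true(all(occ %in% c(1:3, 88:90)))
  expect_true(1 %in% occ)
  expect_error(render_panorama(empty, c(9, 0)), "extent")
})

test_that("odour field matches its closed form", {
  f <- odour_field(sigma = 0.2)
  expect_equal(odour_concentration(f, c(0, 0)), 1)
  expect_equal(odour_concentration(f, c(0.2, 0)), exp(-0.5))
  expect_lt(odour_concentration(f, c(200, 0)), 1e-12)
  # radial monotonicity on random radii
  set.seed(1)
  r <- sort(runif(50, 0, 3))
  cc <- odour_concentration(f, cbind(r, 0))
  expect_true(all(diff(cc) <= 0))
})

test_that("analytic odour gradient agrees with finite differences", {
  f <- odour_field(sigma = 0.17)
  set.seed(2)
  h <- 1e-6
  for (i in 1:100) {
    p <- runif(2, -1, 1)
    g <- odour_gradient(f, p)
    gx <- (odour_concentration(f, p + c(h, 0)) -
             odour_concentration(f, p - c(h, 0))) / (2 * h)
    gy <- (odour_concentration(f, p + c(0, h)) -
             odour_concentration(f, p - c(0, h))) / (2 * h)
    expect_equal(g, c(gx, gy), tolerance = 1e-6)
  }
  expect_equal(odour_gradient(f, c(0, 0)), c(0, 0))
  g <- odour_gradient(f, c(0.5, 0))
  expect_lt(g[1], 0)
  expect_equal(g[2], 0)
})

test_that("wind plume elongates downwind and reduces to the isotropic field", {
  f0 <- odour_field(sigma = 0.2, wind = list(direction = 0, strength = 0))
  f1 <- odour_field(sigma = 0.2, wind = list(direction = 0, strength = 1))
  set.seed(3)
  for (i in 1:20) {
    p <- runif(2, -1, 1)
    expect_equal(odour_concentration(f0, p),
                 odour_concentration(odour_field(sigma = 0.2), p))
  }
  expect_equal(plume_concentration(f1, c(0, 0)), 1)
  # downwind beats equidistant crosswind
  expect_gt(plume_concentration(f1, c(0.5, 0)),
            plume_concentration(f1, c(0, 0.5)))
})
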