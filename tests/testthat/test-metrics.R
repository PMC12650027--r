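test_that("coverage area matches closed-form polygons", {
  sq <- tibble::tibble(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(coverage_area(sq), 1)
  expect_warning(a <- coverage_area(tibble::tibble(x = 0:3, y = 0:3)),
                 "collinear|degenerate")
  expect_equal(a, 0)
  expect_warning(coverage_area(tibble::tibble(x = 1, y = 1)), "degenerate")
  # convex polygon on an ellipse: area from the triangle-fan closed form
  set.seed(5)
  th <- sort(runif(40, 0, 2 * pi))
  px <- 2 * cos(th); py <- 0.7 * sin(th)
  fan <- sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py) / 2
  shuffled <- sample(length(px))
  expect_equal(coverage_area(tibble::tibble(x = px[shuffled], y = py[shuffled])),
               abs(fan))
})

test_that("distance and turning statistics", {
  th <- seq(0, 2 * pi, length.out = 100)
  circ <- tibble::tibble(x = 0.3 * cos(th), y = 0.3 * sin(th))
  expect_equal(max_distance(circ), 0.3)
  straight <- tibble::tibble(heading = rep(0.7, 50))
  expect_equal(turning_stats(straight), 0)
  # regular N-gon: constant exterior angle 2*pi/N per step
  N <- 12
  ngon <- tibble::tibble(heading = learnwalk:::wrap_angle(2 * pi * (1:36) / N))
  expect_equal(turning_stats(ngon), 2 * pi / N, tolerance = 1e-12)
  # each scan event credits one full pirouette revolution
  sc <- tibble::tibble(heading = rep(0, 11), scan = c(rep(0, 10), 1))
  expect_equal(turning_stats(sc), 2 * pi / 10)
  expect_equal(turning_stats(sc, pirouette = 0), 0)
})

test_that("empirical bounds table scales means and sds together", {
  b <- bio_bounds()
  expect_equal(b$area_mean, 0.07 * c(1, 8, 20, 50))
  expect_equal(b$area_sd, 0.035 * c(1, 8, 20, 50))
  expect_equal(b$dist_mean, 0.184 * c(1, 3.8, 7.6, 15.2))
  expect_equal(b$dist_sd[1], 0.0636)
})

test_that("in-band fractions count pooled trials", {
  b <- bio_bounds()
  at_mean <- tidyr::expand_grid(agent = 1:10, walk = 1:4) |>
    dplyr::left_join(b, by = "walk") |>
    dplyr::transmute(agent, walk, area = area_mean, max_dist = dist_mean)
  f <- within_bounds_fraction(at_mean, b)
  expect_equal(f$fraction, c(1, 1))
  way_off <- dplyr::mutate(at_mean, area = area * 10, max_dist = max_dist * 10)
  expect_equal(within_bounds_fraction(way_off, b)$fraction, c(0, 0))
  mixed <- at_mean
  mixed$area[1:10] <- mixed$area[1:10] * 10       # 10 of 40 area values out
  mixed$max_dist[1:4] <- mixed$max_dist[1:4] * 10 # 4 of 40 distance values out
  expect_equal(within_bounds_fraction(mixed, b)$fraction, c(0.75, 0.9))
})

test_that("weight dynamics resample, normalise and average", {
  tr <- tidyr::expand_grid(agent = 1:2, walk = 1:2, step = 1:50) |>
    dplyr::mutate(w_v = 0.2, w_olf = 0.3, w_pi = 0.5, scan = 0)
  wd <- weight_dynamics(tr, n_bins = 10)
  expect_true(all(abs(wd$profiles$q25 - wd$profiles$q75) < 1e-12))
  m <- wd$means
  expect_equal(m$mean[m$cue == "olfactory"], c(0.3, 0.3))
  expect_equal(m$mean[m$cue == "pi"], c(0.5, 0.5))
  # shares always sum to one
  sh <- learnwalk:::weight_shares(tr)
  expect_true(all(abs(sh$sh_v + sh$sh_olf + sh$sh_pi - 1) < 1e-12))
  # two-phase weights: the normalised profile recovers the switch point
  tr2 <- tibble::tibble(agent = 1, walk = 1, step = 1:100,
                        w_v = 0, w_olf = c(rep(1, 50), rep(0, 50)),
                        w_pi = c(rep(0, 50), rep(1, 50)), scan = 0)
  pr <- weight_dynamics(tr2, n_bins = 20)$profiles
  olf <- pr$q50[pr$cue == "olfactory"]
  expect_true(all(olf[1:9] == 1))
  expect_true(all(olf[12:20] == 0))
})
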