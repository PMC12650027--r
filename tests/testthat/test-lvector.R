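test_that("PI weight is the floored complement of the other two", {
  expect_equal(pi_weight(0, 0), 1)
  expect_equal(pi_weight(0.3, 0.5), 0.2)
  expect_equal(pi_weight(0.8, 0.6), 0)
})

test_that("homing vector sums available cues and flags degeneracy", {
  v <- homing_vector(c(1, 0, 0), theta_v = 0)
  expect_equal(as.numeric(v), c(1, 0))
  expect_false(attr(v, "degenerate"))
  v <- homing_vector(c(0.5, 0.5, 0), theta_v = 0, theta_olf = pi)
  expect_equal(as.numeric(v), c(0, 0), tolerance = 1e-12)
  expect_true(attr(v, "degenerate"))
  v <- homing_vector(c(0.2, 0.3, 0.5), 1, 1, 1)
  expect_equal(sqrt(sum(v^2)), 1)
  expect_equal(atan2(v[2], v[1]), 1)
  expect_true(attr(homing_vector(c(1, 1, 1)), "degenerate"))
})

test_that("visual offset mapping follows the windowed piecewise ramp", {
  tr <- c(10, 12, 14, 16, 18)
  m <- mean(tr) - sd(tr); M <- mean(tr) + sd(tr)
  expect_equal(fv_offset(tr, vn = mean(tr)), pi / 2)
  expect_equal(fv_offset(tr, vn = m - 1), pi)
  expect_equal(fv_offset(tr, vn = M + 1), 0)
  mid <- (mean(tr) + M) / 2
  expect_equal(fv_offset(tr, vn = mid), (M - mid) / (M - m) * pi)
  expect_equal(fv_offset(c(3, 3, 3), vn = 3), pi / 2)  # zero spread
  expect_equal(fv_offset(c(1, 2), vn = 1), pi / 2)     # short window
  expect_error(fv_offset(numeric(0)), "empty")
})

test_that("olfactory offset maps concentration linearly onto [0, pi]", {
  expect_equal(folf_offset(0), 0)
  expect_equal(folf_offset(1), pi)
  expect_equal(folf_offset(0.5), pi / 2)
  expect_error(folf_offset(1.2), "0, 1")
})

test_that("total offset is gated by the exploration state and clamped", {
  expect_equal(total_offset(0, c(1, 1, 1), pi, pi, pi), 0)
  expect_equal(total_offset(1, c(0, 1, 0), 0, pi, 0), pi)
  expect_equal(total_offset(1, c(0.5, 0.5, 0), pi, pi, 0), pi)  # clamped
  # monotone: raising any modality offset never lowers phi
  set.seed(3)
  for (i in 1:200) {
    w <- runif(3); f <- runif(3, 0, pi)
    phi <- total_offset(1, w, f[1], f[2], f[3])
    j <- sample(3, 1)
    f2 <- f; f2[j] <- min(pi, f[j] + runif(1, 0, pi))
    expect_gte(total_offset(1, w, f2[1], f2[2], f2[3]), phi - 1e-12)
  }
})

test_that("learning-vector rotation preserves the norm", {
  expect_equal(rotate_vec(c(0.3, -0.2), 0), c(0.3, -0.2))
  expect_equal(rotate_vec(c(0.3, -0.2), pi), -c(0.3, -0.2))
  expect_equal(rotate_vec(c(1, 0), pi / 2), c(0, 1), tolerance = 1e-12)
  expect_equal(rotate_vec(c(1, 0), pi / 2, sign = -1), c(0, -1),
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:1000) {
    v <- rnorm(2); phi <- runif(1, 0, pi)
    expect_equal(sqrt(sum(rotate_vec(v, phi)^2)), sqrt(sum(v^2)),
                 tolerance = 1e-12)
  }
})

test_that("boldness semantics at the nest; pure homing when settled", {
  # at the nest with full olfactory familiarity and ac = 1 the Learning
  # Vector points away from the nest (outbound exploration)
  homing <- homing_vector(c(0, 1, 0), theta_olf = pi / 3)
  phi <- total_offset(1, c(0, 1, 0), 0, folf_offset(1), 0)
  lv <- rotate_vec(homing, phi)
  expect_equal(atan2(lv[2], lv[1]),
               learnwalk:::wrap_angle(pi / 3 + pi), tolerance = 1e-12)
  # with ac = 0 the Learning Vector is exactly the Homing Vector
  phi0 <- total_offset(0, c(0, 1, 0), 0, folf_offset(1), 0)
  expect_equal(rotate_vec(homing, phi0), as.numeric(homing))
})
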