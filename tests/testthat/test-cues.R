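test_that("olfactory familiarity and homing direction", {
  f <- odour_field(sigma = 0.2)
  expect_equal(olf_familiarity(f, c(0, 0)), 1)
  expect_equal(olf_familiarity(f, c(0.2, 0)), exp(-0.5))
  expect_lt(olf_familiarity(f, c(50, 0)), 1e-12)
  expect_equal(olf_homing_direction(c(1, 0)), pi)
  expect_equal(olf_homing_direction(c(0, -2)), pi / 2)
  expect_equal(olf_homing_direction(c(1, 1)), -3 * pi / 4)
  expect_true(is.na(olf_homing_direction(c(0, 0))))
  # direction agrees with the field gradient at every off-nest point
  set.seed(1)
  for (i in 1:50) {
    p <- runif(2, -2, 2)
    g <- odour_gradient(f, p)
    expect_lt(abs(learnwalk:::wrap_angle(
      olf_homing_direction(p) - atan2(g[2], g[1]))), 1e-9)
  }
})

test_that("path integration accumulates and closes loops", {
  st <- pi_state(noise_sd = 0)
  for (i in 1:10) st <- pi_update(st, c(0.01, 0))
  expect_equal(st$displacement, c(0.1, 0), tolerance = 1e-12)
  # square loop closes exactly without noise
  st <- pi_state(noise_sd = 0)
  for (d in list(c(0.01, 0), c(0, 0.01), c(-0.01, 0), c(0, -0.01)))
    for (i in 1:25) st <- pi_update(st, d)
  expect_lt(sqrt(sum(st$displacement^2)), 1e-12)
})

test_that("PI noise variance scales with step count", {
  set.seed(42)
  n_steps <- 100
  sd0 <- 1e-3
  reps <- replicate(800, {
    st <- pi_state(noise_sd = sd0)
    for (i in seq_len(n_steps)) st <- pi_update(st, c(0, 0))
    st$displacement[1]
  })
  expect_equal(var(reps), n_steps * sd0^2, tolerance = 0.15)
  # loop-closure error grows like sqrt(N)
  err_at <- function(n) {
    mean(replicate(300, {
      st <- pi_state(noise_sd = sd0)
      for (i in seq_len(n)) st <- pi_update(st, c(0, 0))
      sqrt(sum(st$displacement^2))
    }))
  }
  expect_equal(err_at(400) / err_at(100), 2, tolerance = 0.15)
})

test_that("PI homing direction points nestward", {
  st <- pi_state()
  st$displacement <- c(1, 0)
  expect_equal(pi_home_direction(st), pi)
  st$displacement <- c(0, 0)
  expect_true(is.na(pi_home_direction(st)))
  set.seed(2)
  for (i in 1:20) {
    st$displacement <- rnorm(2)
    th <- pi_home_direction(st)
    expect_lt(abs(learnwalk:::wrap_angle(
      th - atan2(-st$displacement[2], -st$displacement[1]))), 1e-9)
  }
})

test_that("per-walk distance schedule multiplies out", {
  s <- dk_schedule(0.184)
  expect_equal(s[2], 0.6992)
  expect_equal(s[4], 2.7968)
  expect_equal(unclass(dk_schedule(0.5, numeric(0))), 0.5)
  expect_error(dk_schedule(-1), "positive")
  expect_error(dk_schedule(1, c(2, -1)), "positive")
})

test_that("PI offset mapping covers both forms and the clamp", {
  s <- dk_schedule(0.2, c(2, 2, 2))
  expect_equal(pi_offset(0, s, 1, scaled = FALSE), 0)
  expect_equal(pi_offset(0.2, s, 1, scaled = FALSE), 1)
  expect_equal(pi_offset(0.4, s, 1, scaled = FALSE), 1)  # clamped
  expect_equal(pi_offset(0.1, s, 1), pi / 2)
  # complement leash: full licence at the nest, zero at d_k
  expect_equal(pi_offset(0, s, 1, form = "complement"), pi)
  expect_equal(pi_offset(0.2, s, 1, form = "complement"), 0)
  expect_equal(pi_offset(0.15, s, 1, form = "complement", grace = 0.75), pi)
  expect_error(pi_offset(0.1, s, 9), "schedule")
})
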