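test_that("per-walk step budgets grow exponentially", {
  expect_equal(expected_steps(1, 100), 100)
  expect_equal(expected_steps(3, 100, growth = 2), 400)
  expect_equal(expected_steps(5, 100, growth = 1), 100)
})

test_that("scan intervals round with a floor of one step", {
  expect_equal(scan_interval(400, 20), 20L)
  expect_equal(scan_interval(100, 100), 1L)
  expect_equal(scan_interval(10, 3), 3L)
  expect_true(is.na(scan_interval(100, 0)))
})

test_that("reduced-vision variant touches only learning rate and scans", {
  cfg <- lw_config()
  red <- reduced_vision_config(cfg)
  expect_equal(red$mb$lambda_vis, cfg$mb$lambda_vis / 2)
  expect_equal(red$agent$scans_per_walk,
               pmax(1, round(cfg$agent$scans_per_walk / 4)))
  red$mb$lambda_vis <- cfg$mb$lambda_vis
  red$agent$scans_per_walk <- cfg$agent$scans_per_walk
  expect_identical(red, cfg)
})

test_that("configuration merging validates and overrides", {
  cfg <- lw_config(agent = list(p_rand = 0.25), odour = list(sigma = 0.15))
  expect_equal(cfg$agent$p_rand, 0.25)
  expect_equal(cfg$odour$sigma, 0.15)
  expect_equal(cfg$agent$U, 0.01)
  expect_error(lw_config(bogus = list(a = 1)), "unknown config group")
  path <- tempfile(fileext = ".yaml")
  write_lw_config(cfg, path)
  cfg2 <- read_lw_config(path)
  expect_equal(cfg2$odour$sigma, 0.15)
  expect_equal(cfg2$agent$p_rand, 0.25)
})

test_that("von Mises sampler concentrates around the mean direction", {
  set.seed(11)
  x <- rvonmises(4000, mu = 1, kappa = 30)
  expect_true(all(x > -pi & x <= pi))
  mdir <- atan2(mean(sin(x)), mean(cos(x)))
  expect_lt(abs(mdir - 1), 0.05)
  r <- sqrt(mean(sin(x))^2 + mean(cos(x))^2)
  expect_gt(r, 0.95)  # kappa = 30: tightly concentrated
  u <- rvonmises(2000, 0, 0)
  expect_lt(sqrt(mean(sin(u))^2 + mean(cos(u))^2), 0.07)
})

test_that("single steps move exactly one step length", {
  cfg <- small_cfg()
  w <- small_world()
  set.seed(3)
  agent <- make_agent(cfg, seed = 2)
  agent$walk_index <- 1L
  for (i in 1:25) {
    old <- agent$position
    st <- lw_step(agent, w)
    agent <- st$agent
    expect_equal(sqrt(sum((agent$position - old)^2)), cfg$agent$U,
                 tolerance = 1e-12)
    expect_true(agent$heading > -pi && agent$heading <= pi)
  }
})

test_that("a learning walk explores, scans, then homes to the nest", {
  cfg <- small_cfg()
  w <- small_world()
  agent <- make_agent(cfg, seed = 4)
  set.seed(21)
  res <- run_learning_walk(agent, w, j = 1)
  rec <- res$record
  np1 <- cfg$agent$np1
  expect_equal(attr(rec, "np_j"), np1)
  expect_gte(nrow(rec), np1)
  # constant step length along the whole trajectory
  dx <- diff(rec$x); dy <- diff(rec$y)
  expect_true(all(abs(sqrt(dx^2 + dy^2) - cfg$agent$U) < 1e-9))
  # pure homing after the exploration budget
  expect_true(all(rec$ac[seq_len(np1 - 1)] == 1))
  post <- rec[rec$ac == 0 & rec$random == 0, ]
  expect_true(all(post$phi == 0))
  expect_equal(sum(rec$scan), cfg$agent$scans_per_walk[1])
  if (attr(rec, "complete")) {
    last <- rec[nrow(rec), ]
    expect_lte(sqrt(last$x^2 + last$y^2), cfg$agent$nest_radius)
  }
})

test_that("walk series are reproducible and memory only depresses", {
  cfg <- small_cfg()
  w <- small_world()
  s1 <- run_walk_series(cfg, seed = 31, n_walks = 2, world = w,
                        snapshot_after = c(1, 2))
  s2 <- run_walk_series(cfg, seed = 31, n_walks = 2, world = w,
                        snapshot_after = c(1, 2))
  expect_equal(s1$trajectories, s2$trajectories)
  expect_true(all(s1$snapshots$walk2 <= s1$snapshots$walk1 + 1e-12))
  expect_true(all(s1$snapshots$walk1 <= 1))
  expect_equal(s1$walk_meta$np_j, c(30, 60))
  # different seed gives a different path
  s3 <- run_walk_series(cfg, seed = 32, n_walks = 1, world = w)
  expect_false(isTRUE(all.equal(s3$trajectories$x[1:20],
                                s1$trajectories$x[1:20])))
})

test_that("cohorts share the world and expand across walks", {
  cfg <- small_cfg()
  co <- run_cohort(cfg, n_agents = 3, seed = 55, n_walks = 3)
  expect_equal(length(co$series), 3)
  expect_equal(sort(unique(co$trajectories$agent)), 1:3)
  m <- walk_metrics(co$trajectories)
  expect_equal(nrow(m), 9)
  byw <- tapply(m$max_dist, m$walk, mean)
  expect_true(all(diff(byw) > 0))  # mean excursion grows across walks
})
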