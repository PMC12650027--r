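test_that("sigmoid rate transfer has the right fixed points", {
  expect_equal(neuron_rate(0), 0.5)
  expect_equal(neuron_rate(-2), 1 / (1 + exp(2)))
  expect_gt(neuron_rate(50), 1 - 1e-12)
})

test_that("network construction is reproducible and validated", {
  n1 <- mb_network(n_kc = 100, seed = 5)
  n2 <- mb_network(n_kc = 100, seed = 5)
  expect_identical(n1$conn, n2$conn)
  expect_true(all(n1$w == 1))
  expect_error(mb_network(n_vpn = 80), "Zernike feature count")
})

test_that("KC activation is sparse, deterministic and silences blank input", {
  net <- small_net()
  expect_false(any(kc_activation(net, rep(0, 81))))
  set.seed(9)
  fracs <- replicate(20, {
    f <- abs(rnorm(81))^3
    a <- kc_activation(net, f)
    expect_identical(a, kc_activation(net, f))
    mean(a)
  })
  expect_true(all(fracs > 0))
  expect_true(all(fracs <= net$kc_max / net$n_kc + 1e-12))
  expect_error(kc_activation(net, rep(1, 10)), "length")
})

test_that("MBON novelty falls with learning and weights stay bounded", {
  net <- mb_network(n_kc = 400, seed = 2, lambda_vis = 0.01)
  set.seed(4)
  f <- abs(rnorm(81))
  act <- kc_activation(net, f)
  nv0 <- mbon_novelty(net, act)
  expect_equal(nv0$novelty, 1)  # fresh network: every pattern fully novel
  net1 <- mb_learn(net, act)
  expect_equal(sum(net1$w[act]), sum(act) * 0.99)
  nv1 <- mbon_novelty(net1, act)
  expect_lt(nv1$cmbon, nv0$cmbon)
  # monotone decrease over repeated exposures, floor at zero
  prev <- nv0$novelty
  for (i in 1:120) {
    net <- mb_learn(net, act)
    cur <- mbon_novelty(net, act)$novelty
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
  expect_equal(prev, 0)
  expect_true(all(net$w >= 0 & net$w <= 1))
  # disjoint patterns are untouched
  other <- !act
  expect_true(all(net$w[other] == 1))
})

test_that("visual familiarity endpoints and clipping", {
  expect_equal(visual_familiarity(0, 80), 1)
  expect_equal(visual_familiarity(80, 80), 0)
  expect_equal(visual_familiarity(200, 80), 0)
})

test_that("familiarity is higher along a trained path than off it", {
  w <- small_world()
  net <- mb_network(n_kc = 800, seed = 6)
  on_path <- lapply(seq(-0.3, 0.3, by = 0.1), function(x) c(x, 0))
  for (rep in 1:6) for (p in on_path) {
    nv <- novelty_at(net, w$tri, p, want_active = TRUE)
    net <- mb_learn(net, nv$active)
  }
  novelty_norm <- function(p) {
    nv <- novelty_at(net, w$tri, p)
    nv$cmbon / max(1, nv$n_active)
  }
  on_mean <- mean(vapply(on_path, novelty_norm, numeric(1)))
  off <- lapply(c(2, -2.2, 2.5), function(x) c(x, x))
  off_mean <- mean(vapply(off, novelty_norm, numeric(1)))
  expect_lt(on_mean, off_mean)
})

test_that("visual homing direction flags uninformative fields", {
  w <- small_world()
  net <- mb_network(n_kc = 400, seed = 8)
  net$w <- rep(0, 400)  # fully depressed memory: flat zero novelty
  set.seed(1)
  vh <- visual_homing_direction(net, w$tri, c(0.2, 0.2))
  expect_false(vh$confident)
  expect_true(vh$theta > -pi && vh$theta <= pi)
})

test_that("MB state serialises and restores exactly", {
  net <- mb_network(n_kc = 300, seed = 12, lambda_vis = 0.02)
  set.seed(5)
  for (i in 1:5) net <- mb_learn(net, sample.int(300, 20))
  path <- tempfile(fileext = ".json")
  write_mb_network(net, path)
  net2 <- read_mb_network(path)
  expect_identical(net2$conn, net$conn)
  expect_equal(net2$w, net$w)
  w <- small_world()
  expect_equal(novelty_at(net2, w$tri, c(0.3, 0))$cmbon,
               novelty_at(net, w$tri, c(0.3, 0))$cmbon)
})
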