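# Shared small fixtures: a sparse near-field world and a reduced network so
# unit tests stay fast.  Built once per test run.

small_cfg <- function(...) {
  lw_config(
    world = list(seed = 7L, n_objects = 12, extent = 6, scatter = c(2, 5),
                 height_range = c(0.5, 1.5)),
    mb = list(n_kc = 800),
    agent = list(np1 = 30, scans_per_walk = c(3, 4, 5, 6),
                 max_homing_steps = 400),
    ...
  )
}

the_fix <- new.env()

small_world <- function() {
  if (is.null(the_fix$world)) the_fix$world <- build_world(small_cfg())
  the_fix$world
}

small_net <- function() {
  if (is.null(the_fix$net))
    the_fix$net <- mb_network(n_kc = 800, seed = 3)
  the_fix$net
}

# brute-force renderer oracle: one ray per pixel against every triangle
oracle_pixel <- function(tri, pos, az, el, eye = 0.005) {
  o <- c(pos, eye)
  d <- c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  hit <- FALSE
  for (i in seq_len(nrow(tri))) {
    v0 <- tri[i, 1:3]; v1 <- tri[i, 4:6]; v2 <- tri[i, 7:9]
    e1 <- v1 - v0; e2 <- v2 - v0
    p <- c(d[2] * e2[3] - d[3] * e2[2], d[3] * e2[1] - d[1] * e2[3],
           d[1] * e2[2] - d[2] * e2[1])
    det <- sum(e1 * p)
    if (abs(det) < 1e-9) next
    tv <- o - v0
    u <- sum(tv * p) / det
    if (u < -1e-9 || u > 1 + 1e-9) next
    q <- c(tv[2] * e1[3] - tv[3] * e1[2], tv[3] * e1[1] - tv[1] * e1[3],
           tv[1] * e1[2] - tv[2] * e1[1])
    v <- sum(d * q) / det
    if (v < -1e-9 || u + v > 1 + 1e-9) next
    if (sum(e2 * q) / det > 1e-9) { hit <- TRUE; break }
  }
  if (hit) 1 else if (el < 0) 0.5 else 0
}
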