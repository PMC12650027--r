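# The learning-walk agent: per-step sensing, cue fusion, movement,
# pirouette scans and the multi-walk protocol.

#' Expected number of exploration steps in walk j
#'
#' Exponential growth across walks: `round(np1 * growth^(j - 1))`.
#'
#' @param j walk index (1-based).
#' @param np1 expected steps in the first walk.
#' @param growth per-walk growth factor.
#' @export
expected_steps <- function(j, np1, growth = 2) {
  stopifnot(j >= 1)
  round(np1 * growth^(j - 1))
}

#' Average interval between pirouette scans
#'
#' `round(np_j / n_j)`, with a floor of one step; `n_j = 0` means a
#' scan-free walk (returns `NA`).
#'
#' @param np_j exploration steps in the walk.
#' @param n_j scans in the walk.
#' @export
scan_interval <- function(np_j, n_j) {
  if (n_j == 0) return(NA_integer_)
  max(1L, as.integer(round(np_j / n_j)))
}

#' Build the simulated environment
#'
#' @param cfg an [lw_config()].
#' @return list with `mesh` (terrain), `tri` (object-triangle matrix for
#'   the renderer) and `field` (odour field).
#' @export
build_world <- function(cfg) {
  w <- cfg$world
  mesh <- generate_terrain(seed = w$seed, n_objects = w$n_objects,
                           height_range = w$height_range, extent = w$extent,
                           scatter = w$scatter, nest_clear = w$nest_clear,
                           tri_per_object = w$tri_per_object,
                           radius_range = w$radius_range)
  field <- odour_field(c0 = cfg$odour$c0, sigma = cfg$odour$sigma,
                       wind = cfg$odour$wind, stretch = cfg$odour$stretch)
  list(mesh = mesh, tri = mesh_tri_matrix(mesh), field = field)
}

#' Create a naive agent
#'
#' @param cfg an [lw_config()].
#' @param seed integer seed for the agent's MB wiring (the walk itself uses
#'   the caller's RNG stream).
#' @return an `lw_agent`: MB network, PI state, novelty trace, pose and
#'   protocol state.
#' @export
make_agent <- function(cfg, seed = 1L) {
  m <- cfg$mb
  mb <- mb_network(n_vpn = m$n_vpn, n_kc = m$n_kc, fan_in = m$fan_in,
                   theta_kc = m$theta_kc, lambda_vis = m$lambda_vis,
                   kc_sparsity = m$kc_sparsity,
                   drive_mode = m$drive_mode %||% "fanin",
                   use_m0 = isTRUE(m$use_m0),
                   seed = seed, n_max = m$n_max, resolution = m$resolution,
                   disk_res = m$disk_res, eye_height = m$eye_height,
                   elevation = m$elevation)
  structure(list(mb = mb, pi = pi_state(cfg$pi$noise_sd), trace = numeric(0),
                 position = c(0, 0), heading = 0, theta_v = NA_real_,
                 ac = 1L, walk_index = 0L,
                 schedule = dk_schedule(cfg$pi$schedule$d1,
                                        cfg$pi$schedule$multipliers),
                 lv_sign = 1, config = cfg, seed = seed),
            class = "lw_agent")
}

# Current-position familiarity weights. n_active == 0 yields w_v = 0 (no
# visual evidence -> no visual confidence).
agent_weights <- function(agent, world, nv) {
  cfg <- agent$config
  w_v <- if (nv$n_active > 0) {
    norm <- if (cfg$mb$normalizer_mode == "total") agent$mb$n_kc else nv$n_active
    visual_familiarity(nv$cmbon, norm)
  } else 0
  w_olf <- olf_familiarity(world$field, agent$position)
  c(w_v = w_v, w_olf = w_olf, w_pi = pi_weight(w_v, w_olf))
}

#' Perform a pirouette scan
#'
#' Records the current view's novelty on the trace, depresses the active
#' KC weights (one learning exposure), and refreshes the visual homing
#' direction estimate by directional novelty sampling.
#'
#' @param agent an `lw_agent`.
#' @param world a [build_world()] environment.
#' @param learn set `FALSE` to freeze the memory (homing tests).
#' @return updated agent.
#' @export
perform_scan <- function(agent, world, learn = TRUE) {
  cfg <- agent$config
  U <- cfg$mb$scan_step %||% cfg$agent$U
  nh <- cfg$mb$n_headings
  nv <- novelty_at(agent$mb, world$tri, agent$position, want_active = learn)
  off <- runif(1, 0, 2 * pi / nh)
  thetas <- off + 2 * pi * (seq_len(nh) - 1) / nh
  nbs <- lapply(thetas, function(th) {
    novelty_at(agent$mb, world$tri,
               agent$position + U * c(cos(th), sin(th)), want_active = learn)
  })
  # direction of steepest novelty decrease, from pre-learning scores
  dec <- nv$cmbon / max(1, nv$n_active) -
    vapply(nbs, function(z) z$cmbon / max(1, z$n_active), numeric(1))
  best <- max(dec)
  cand <- which(dec >= best - (1e-12 + 1e-9 * abs(best)))
  pick <- if (length(cand) > 1) cand[sample.int(length(cand), 1)] else cand
  agent$theta_v <- wrap_angle(thetas[pick])
  if (learn) {
    agent$trace <- c(agent$trace, nv$cmbon)
    agent$mb <- mb_learn(agent$mb, nv$active)
  }
  if (cfg$lv$sign_mode == "random_segment") {
    agent$lv_sign <- sample(c(-1, 1), 1)
  } else if (cfg$lv$sign_mode == "persistent") {
    if (runif(1) > (cfg$lv$sign_repeat %||% 0.85))
      agent$lv_sign <- -agent$lv_sign
  }
  agent
}

#' Advance the agent by one step
#'
#' With probability `p_rand` the heading is drawn from a von Mises
#' distribution centred on the current heading; otherwise the cue weights,
#' the Homing Vector, the offset `phi` and the Learning Vector are computed
#' and the agent moves one step of length `U` along it.  The world boundary
#' reflects; the PI state accumulates the realised movement.
#'
#' @param agent an `lw_agent`.
#' @param world a [build_world()] environment.
#' @return list with the updated `agent` and a named numeric `row`
#'   (x, y, heading, w_v, w_olf, w_pi, phi, random flag, cmbon).
#' @export
lw_step <- function(agent, world) {
  cfg <- agent$config
  U <- cfg$agent$U
  nv <- novelty_at(agent$mb, world$tri, agent$position)
  w <- agent_weights(agent, world, nv)
  random <- runif(1) < cfg$agent$p_rand
  phi <- NA_real_
  if (random) {
    heading <- rvonmises(1, agent$heading, cfg$agent$kappa)
  } else {
    theta_olf <- olf_homing_direction(agent$position)
    theta_pi <- pi_home_direction(agent$pi)
    H <- homing_vector(w, agent$theta_v, theta_olf, theta_pi)
    if (agent$ac == 1L) {
      f_v <- if (length(agent$trace) >= 3) {
        fv_offset(agent$trace, vn = nv$cmbon, window = cfg$lv$fv_window)
      } else pi / 2
      f_olf <- folf_offset(w[["w_olf"]])
      f_pi <- pi_offset(sqrt(sum(agent$pi$displacement^2)), agent$schedule,
                        max(1L, agent$walk_index), scaled = cfg$pi$fpi_scaled,
                        form = cfg$pi$fpi_form, grace = cfg$pi$fpi_grace)
      phi <- total_offset(1, w, f_v, f_olf, f_pi)
      if (!cfg$lv$clamp_phi)
        phi <- 1 * (w[1] * f_v + w[2] * f_olf + w[3] * f_pi)
    } else phi <- 0
    L <- rotate_vec(H, phi, agent$lv_sign)
    heading <- if (sqrt(sum(L^2)) < 1e-9) agent$heading else atan2(L[2], L[1])
  }
  old <- agent$position
  new <- old + U * c(cos(heading), sin(heading))
  e <- attr(world$mesh, "extent") %||% Inf
  new <- ifelse(abs(new) > e, sign(new) * (2 * e - abs(new)), new)
  agent$position <- new
  agent$heading <- wrap_angle(heading)
  agent$pi <- pi_update(agent$pi, new - old)
  list(agent = agent,
       row = c(x = new[1], y = new[2], heading = agent$heading,
               w_v = w[[1]], w_olf = w[[2]], w_pi = w[[3]], phi = phi,
               random = as.numeric(random), cmbon = nv$cmbon,
               n_active = nv$n_active))
}

#' Run one learning walk
#'
#' The agent starts at the nest with a reset PI state and `ac = 1`,
#' explores for `np_j` steps with pirouette scans every `Iscan` steps,
#' then switches to pure homing (`ac = 0`, `phi = 0`) until it re-enters
#' the nest radius or exhausts the homing budget.
#'
#' @param agent an `lw_agent` (uses the caller's RNG stream).
#' @param world a [build_world()] environment.
#' @param j walk index (drives the step budget, the scan count and the PI
#'   distance schedule).
#' @return list with the updated `agent` and `record`, a tibble with one
#'   row per step (`step, x, y, heading, w_v, w_olf, w_pi, phi, scan,
#'   random, ac, cmbon`) and attributes `walk`, `np_j`, `iscan`,
#'   `complete`.
#' @export
run_learning_walk <- function(agent, world, j) {
  cfg <- agent$config
  np_j <- expected_steps(j, cfg$agent$np1, cfg$agent$growth)
  n_j <- cfg$agent$scans_per_walk[min(j, length(cfg$agent$scans_per_walk))]
  iscan <- scan_interval(np_j, n_j)
  agent$position <- c(0, 0)
  agent$heading <- wrap_angle(runif(1, -pi, pi))
  agent$pi <- pi_state(cfg$pi$noise_sd)
  agent$ac <- 1L
  agent$walk_index <- j
  agent$lv_sign <- if (cfg$lv$sign_mode == "ccw") 1 else sample(c(-1, 1), 1)

  max_steps <- np_j + cfg$agent$max_homing_steps
  rec <- matrix(NA_real_, max_steps, 12)
  n <- 0L
  complete <- FALSE
  scan_flag <- 0
  while (n < max_steps) {
    n <- n + 1L
    scan_flag <- 0
    if (agent$ac == 1L && !is.na(iscan) && n %% iscan == 0L && n <= np_j) {
      agent <- perform_scan(agent, world)
      scan_flag <- 1
    }
    st <- lw_step(agent, world)
    agent <- st$agent
    rec[n, ] <- c(n, st$row[1:7], scan_flag, st$row[8], agent$ac, st$row[9])
    if (n == np_j) agent$ac <- 0L
    if (agent$ac == 0L && sqrt(sum(agent$position^2)) <= cfg$agent$nest_radius) {
      complete <- TRUE
      break
    }
  }
  rec <- rec[seq_len(n), , drop = FALSE]
  colnames(rec) <- c("step", "x", "y", "heading", "w_v", "w_olf", "w_pi",
                     "phi", "scan", "random", "ac", "cmbon")
  record <- tibble::as_tibble(rec)
  attr(record, "walk") <- j
  attr(record, "np_j") <- np_j
  attr(record, "iscan") <- iscan
  attr(record, "complete") <- complete
  list(agent = agent, record = record)
}

#' Run a series of learning walks for one agent
#'
#' Sequential walks share the MB memory and the per-walk distance
#' schedule; the whole series is reproducible from `seed`.
#'
#' @param cfg an [lw_config()].
#' @param seed master seed for this agent (wiring + walk stochasticity).
#' @param n_walks number of walks.
#' @param world optional pre-built [build_world()] environment (shared
#'   across agents); built from `cfg` if missing.
#' @param snapshot_after integer vector of walk indices after which to
#'   snapshot the MB weights (for later frozen-memory homing tests).
#' @return an `lw_series`: list with `trajectories` (tibble, all walks,
#'   `walk` column), `agent`, `world`, `snapshots` (named list of weight
#'   vectors), `walk_meta` (tibble of per-walk metadata).
#' @export
run_walk_series <- function(cfg, seed = 1L, n_walks = 4, world = NULL,
                            snapshot_after = integer(0)) {
  world <- world %||% build_world(cfg)
  seeds <- derive_seeds(seed, 1 + n_walks)
  agent <- make_agent(cfg, seed = seeds[1])
  walks <- vector("list", n_walks)
  meta <- vector("list", n_walks)
  snaps <- list()
  for (j in seq_len(n_walks)) {
    set.seed(seeds[1 + j])
    res <- run_learning_walk(agent, world, j)
    agent <- res$agent
    walks[[j]] <- dplyr::mutate(res$record, walk = j, .before = 1)
    meta[[j]] <- tibble::tibble(walk = j, np_j = attr(res$record, "np_j"),
                                iscan = attr(res$record, "iscan"),
                                steps = nrow(res$record),
                                complete = attr(res$record, "complete"))
    if (j %in% snapshot_after) snaps[[paste0("walk", j)]] <- agent$mb$w
  }
  structure(list(trajectories = dplyr::bind_rows(walks), agent = agent,
                 world = world, snapshots = snaps,
                 walk_meta = dplyr::bind_rows(meta), seed = seed,
                 config = cfg),
            class = "lw_series")
}

#' Run a cohort of agents in a shared world
#'
#' All agents experience the same terrain and odour field; per-agent seeds
#' (wiring and walk stochasticity) are derived from the master seed.
#'
#' @param cfg an [lw_config()].
#' @param n_agents number of agents.
#' @param seed master seed.
#' @inheritParams run_walk_series
#' @return an `lw_cohort`: list with `series` (per-agent `lw_series`),
#'   `trajectories` (bound tibble with an `agent` column), `world`,
#'   `config`, `seed`.
#' @export
run_cohort <- function(cfg, n_agents = 10, seed = 1L, n_walks = 4,
                       snapshot_after = integer(0), world = NULL) {
  world <- world %||% build_world(cfg)
  seeds <- derive_seeds(seed + 1L, n_agents)
  series <- purrr::map(seq_len(n_agents), function(i) {
    run_walk_series(cfg, seed = seeds[i], n_walks = n_walks, world = world,
                    snapshot_after = snapshot_after)
  })
  traj <- purrr::imap(series, function(s, i) {
    dplyr::mutate(s$trajectories, agent = i, .before = 1)
  }) |> dplyr::bind_rows()
  structure(list(series = series, trajectories = traj, world = world,
                 config = cfg, seed = seed),
            class = "lw_cohort")
}
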