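# Displacement homing tests: frozen memory, no PI home vector, innate
# olfaction plus learned vision only.

#' Grid of release points
#'
#' Eight distances (1-8 m by default) crossed with eight bearings at 45
#' degree spacing: 64 points.
#'
#' @param distances release distances from the nest, meters.
#' @param angles_deg release bearings, degrees.
#' @return tibble with `dist_m`, `angle_deg`, `x`, `y`.
#' @export
release_grid <- function(distances = 1:8, angles_deg = seq(0, 315, by = 45)) {
  g <- tidyr::expand_grid(dist_m = distances, angle_deg = angles_deg)
  dplyr::mutate(g, x = .data$dist_m * cos(.data$angle_deg * pi / 180),
                y = .data$dist_m * sin(.data$angle_deg * pi / 180))
}

# One displacement trial with a frozen memory.  A displaced agent has no
# valid PI home vector, so the PI weight is forced to zero and the visual
# and olfactory weights are renormalised; ac = 0 (pure homing, phi = 0);
# scans are replaced by learning-free visual direction refreshes.  The
# whole trial loop runs in C++ (it is the experiment's hot path).
homing_trial <- function(mb, world, cfg, start) {
  tcfg <- cfg$test
  op <- mb_operator(mb)
  homing_trial_cpp(world$tri, op$re, op$im, mb$conn, mb$w, mb$theta_kc,
                   mb$eye_height, mb$resolution[1], mb$resolution[2],
                   mb$elevation[1] * pi / 180, mb$elevation[2] * pi / 180,
                   start[1], start[2], wrap_angle(runif(1, -pi, pi)),
                   cfg$agent$U, tcfg$p_rand, tcfg$kappa,
                   tcfg$success_radius, sqrt(sum(start^2)) + tcfg$margin,
                   as.integer(tcfg$max_steps), as.integer(tcfg$theta_refresh),
                   tcfg$scan_step, tcfg$min_cue,
                   as.integer(tcfg$n_headings %||% cfg$mb$n_headings),
                   world$field$sigma, world$field$c0,
                   cfg$mb$normalizer_mode == "active", mb$n_kc,
                   as.integer(tcfg$stall), tcfg$stall_eps,
                   mb$kc_max %||% 0L, mb$gain,
                   identical(mb$drive_mode, "population"), TRUE)
}

#' Run the 64-point homing test for one memory state
#'
#' @param agent an `lw_agent` (its MB memory is used read-only), or an
#'   [mb_network()].
#' @param world a [build_world()] environment.
#' @param grid a [release_grid()].
#' @param weights optional KC weight vector overriding the network's (a
#'   training snapshot).
#' @param seed optional seed for the trial stochasticity.
#' @return tibble of outcomes: `dist_m`, `angle_deg`, `success`, `steps`,
#'   `final_dist`.
#' @export
homing_test <- function(agent, world, grid = release_grid(), weights = NULL,
                        seed = NULL) {
  mb <- if (inherits(agent, "lw_agent")) agent$mb else agent
  cfg <- if (inherits(agent, "lw_agent")) agent$config else lw_config()
  if (!is.null(weights)) mb$w <- weights
  if (!is.null(seed)) set.seed(seed)
  res <- purrr::pmap(grid[, c("x", "y")], function(x, y) {
    homing_trial(mb, world, cfg, c(x, y))
  })
  dplyr::mutate(grid,
                success = purrr::map_lgl(res, "success"),
                steps = purrr::map_int(res, ~ as.integer(.x$steps)),
                final_dist = purrr::map_dbl(res, "final_dist"))
}

#' Homing tests across experience levels for a trained cohort
#'
#' For every agent of a cohort trained with MB snapshots (see
#' `snapshot_after` in [run_cohort()]), runs the full release grid with
#' the memory frozen at each requested experience level.
#'
#' @param cohort an [run_cohort()] result whose series carry snapshots.
#' @param levels walk-experience levels (must match the snapshots taken).
#' @param seed master seed for trial stochasticity.
#' @param grid a [release_grid()].
#' @return tibble of outcomes with `agent` and `walks` columns.
#' @export
homing_by_experience <- function(cohort, levels = c(1, 4), seed = 1L,
                                 grid = release_grid()) {
  seeds <- derive_seeds(seed + 17L, length(cohort$series) * length(levels))
  k <- 0L
  out <- list()
  for (i in seq_along(cohort$series)) {
    s <- cohort$series[[i]]
    for (lv in levels) {
      k <- k + 1L
      w <- s$snapshots[[paste0("walk", lv)]]
      if (is.null(w))
        abort(sprintf("agent %d has no snapshot after walk %d.", i, lv))
      oc <- homing_test(s$agent, cohort$world, grid = grid, weights = w,
                        seed = seeds[k])
      out[[k]] <- dplyr::mutate(oc, agent = i, walks = lv, .before = 1)
    }
  }
  dplyr::bind_rows(out)
}

#' Success rates by range band
#'
#' Close range is 1-4 m (32 points), far range 5-8 m (32 points), overall
#' all 64; each rate is normalised by its own point count.
#'
#' @param outcomes a [homing_test()] / [homing_by_experience()] tibble.
#' @param near_max largest distance counted as close range, meters.
#' @return tibble grouped by any `agent` / `walks` columns present, with
#'   `near`, `far`, `overall` success rates.
#' @export
success_curves <- function(outcomes, near_max = 4) {
  keys <- intersect(c("agent", "walks"), names(outcomes))
  outcomes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      near = mean(.data$success[.data$dist_m <= near_max]),
      far = mean(.data$success[.data$dist_m > near_max]),
      overall = mean(.data$success),
      .groups = "drop"
    )
}
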