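# Cohort-level experiments: the species-variant comparison.

#' Compare a nominal cohort with a reduced-visual-reliance cohort
#'
#' Runs two matched-seed cohorts in the identical world: the nominal
#' configuration and its [reduced_vision_config()] variant (half the
#' visual learning rate, a quarter of the scans).  Emits per-walk turning
#' statistics, scan counts and mean cue weights for both conditions, plus
#' the pooled relative change in mean turning angle per step.
#'
#' @param cfg the nominal [lw_config()].
#' @param n_agents agents per cohort.
#' @param seed master seed (shared, so terrains and per-agent stochastic
#'   streams match across conditions).
#' @param n_walks walks per agent.
#' @return an `lw_species` list: `normal` / `reduced` cohorts, `metrics`
#'   (per-condition [walk_metrics()]), `weight_means` (per-condition
#'   per-walk mean weight shares), and `turning_change_pct`, the percent
#'   change of the reduced cohort's pooled mean turning angle relative to
#'   the nominal cohort.
#' @export
species_compare <- function(cfg, n_agents = 10, seed = 1L, n_walks = 4) {
  red <- reduced_vision_config(cfg)
  world <- build_world(cfg)
  normal <- run_cohort(cfg, n_agents = n_agents, seed = seed,
                       n_walks = n_walks, world = world)
  reduced <- run_cohort(red, n_agents = n_agents, seed = seed,
                        n_walks = n_walks, world = world)
  mn <- dplyr::mutate(walk_metrics(normal$trajectories),
                      condition = "normal", .before = 1)
  mr <- dplyr::mutate(walk_metrics(reduced$trajectories),
                      condition = "reduced", .before = 1)
  metrics <- dplyr::bind_rows(mn, mr)
  wm <- dplyr::bind_rows(
    dplyr::mutate(weight_dynamics(normal$trajectories)$means,
                  condition = "normal", .before = 1),
    dplyr::mutate(weight_dynamics(reduced$trajectories)$means,
                  condition = "reduced", .before = 1))
  turn_n <- mean(mn$turn)
  turn_r <- mean(mr$turn)
  structure(list(normal = normal, reduced = reduced, metrics = metrics,
                 weight_means = wm,
                 turning_change_pct = (turn_r - turn_n) / turn_n * 100),
            class = "lw_species")
}
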