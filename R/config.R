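# Model configuration: one nested list covering environment, network,
# cue, fusion and protocol parameters.

lw_defaults <- function() {
  list(
    world = list(seed = 1L, n_objects = 60, extent = 10,
                 height_range = c(1, 4), scatter = c(8, 20), nest_clear = 0.1,
                 tri_per_object = 8, radius_range = c(0.4, 1.0)),
    odour = list(c0 = 1, sigma = 0.2, wind = NULL, stretch = 3),
    mb = list(n_vpn = 81, n_kc = 4000, fan_in = 10, theta_kc = 0.04,
              lambda_vis = 0.01, n_max = 16, n_headings = 8,
              normalizer_mode = "active",   # or "total" for the literal form
              kc_sparsity = 0.02, scan_step = 0.3, drive_mode = "fanin",
              use_m0 = FALSE,
              resolution = c(90, 25), disk_res = 96,
              eye_height = 0.005, elevation = c(-10, 60)),
    pi = list(noise_sd = 1e-4,
              schedule = list(d1 = 0.184, multipliers = c(3.8, 2, 2)),
              fpi_scaled = TRUE, fpi_form = "complement", fpi_grace = 0.75),
    lv = list(sign_mode = "persistent",  # "ccw" = literal one-sided form
              sign_repeat = 0.85, clamp_phi = TRUE, fv_window = 10),
    agent = list(U = 0.01, p_rand = 0.6, kappa = 20, np1 = 120, growth = 2,
                 scans_per_walk = c(10, 15, 20, 25), nest_radius = 0.05,
                 max_homing_steps = 1500),
    test = list(p_rand = 0.1, kappa = 20, success_radius = 0.1,
                max_steps = 1500, theta_refresh = 10, scan_step = 0.3,
                margin = 2, min_cue = 0.12, stall = 500, stall_eps = 0.02)
  )
}

merge_lists <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
        !is.null(names(over[[nm]]))) {
      base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
    } else {
      base[nm] <- over[nm]
    }
  }
  base
}

#' Build a model configuration
#'
#' Returns the nominal parameter set, optionally overriding any subset via
#' named nested lists, e.g.
#' `lw_config(agent = list(p_rand = 0.3), odour = list(sigma = 0.15))`.
#'
#' Groups: `world` (terrain generation), `odour` (Gaussian field), `mb`
#' (mushroom-body network and panorama encoding), `pi` (path-integration
#' noise and the per-walk distance schedule), `lv` (Learning Vector:
#' rotation sign mode, offset clamping, novelty window), `agent` (step
#' size, stochastic-step probability and concentration, per-walk step and
#' scan schedule, nest radius, homing budget) and `test` (displacement
#' homing-test protocol).
#'
#' @param ... named nested lists of overrides.
#' @return an `lw_config` list.
#' @export
lw_config <- function(...) {
  over <- list(...)
  cfg <- lw_defaults()
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) abort(paste0("unknown config group(s): ",
                                  paste(bad, collapse = ", ")))
    cfg <- merge_lists(cfg, over)
  }
  stopifnot(cfg$agent$U > 0, cfg$agent$p_rand >= 0, cfg$agent$p_rand <= 1,
            cfg$agent$growth >= 1)
  class(cfg) <- "lw_config"
  cfg
}

#' Reduced-visual-reliance variant of a configuration
#'
#' Halves the visual learning rate and quarters the scan counts per walk
#' (minimum one scan), leaving everything else untouched; models ants from
#' visually sparse habitats.
#'
#' @param cfg an [lw_config()].
#' @export
reduced_vision_config <- function(cfg) {
  cfg$mb$lambda_vis <- cfg$mb$lambda_vis / 2
  cfg$agent$scans_per_walk <- pmax(1, round(cfg$agent$scans_per_walk / 4))
  cfg
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @export
read_lw_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(lw_config, over)
}

#' @rdname read_lw_config
#' @param cfg an [lw_config()].
#' @export
write_lw_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
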