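# Trajectory metrics and the comparison against empirical ranges.

#' Convex-hull coverage area of a trajectory
#'
#' @param traj tibble (or data frame) with `x`, `y` columns, meters.
#' @return area in m^2; 0 (with a warning) for degenerate trajectories.
#' @export
coverage_area <- function(traj) {
  xy <- unique(cbind(traj$x, traj$y))
  if (nrow(xy) < 3) {
    warning("degenerate trajectory: fewer than 3 distinct points.")
    return(0)
  }
  h <- grDevices::chull(xy[, 1], xy[, 2])
  px <- xy[h, 1]; py <- xy[h, 2]
  # shoelace on the hull vertices
  area <- abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
  if (area == 0) warning("degenerate trajectory: collinear points.")
  area
}

#' Maximum distance from the nest
#'
#' @inheritParams coverage_area
#' @export
max_distance <- function(traj) max(sqrt(traj$x^2 + traj$y^2))

#' Mean absolute turning angle per step
#'
#' Heading differences are wrapped to `(-pi, pi]` before averaging.  A
#' pirouette is a full-body scanning rotation executed on the spot; the
#' per-step heading trace cannot represent it, so each scan event adds
#' `pirouette` radians of turning (a full revolution by default).  Set
#' `pirouette = 0` for the bare heading-difference statistic.
#'
#' @param traj tibble with a `heading` column (radians) and optionally a
#'   `scan` flag column.
#' @param pirouette turning attributed to each scan event, radians.
#' @return mean turning in radians per step.
#' @export
turning_stats <- function(traj, pirouette = 2 * pi) {
  h <- traj$heading
  if (length(h) < 2) return(0)
  extra <- if ("scan" %in% names(traj)) pirouette * sum(traj[["scan"]]) else 0
  (sum(abs(wrap_angle(diff(h)))) + extra) / (length(h) - 1)
}

# Per-step normalised weight shares (sum to 1).
weight_shares <- function(traj) {
  s <- traj$w_v + traj$w_olf + traj$w_pi
  s[s == 0] <- 1
  dplyr::mutate(traj, sh_v = .data$w_v / s, sh_olf = .data$w_olf / s,
                sh_pi = .data$w_pi / s)
}

#' Per-walk trajectory metrics
#'
#' Coverage area (convex hull), maximum excursion, mean absolute turning
#' angle, scan count and mean normalised cue-weight shares, per agent and
#' walk.
#'
#' @param trajectories cohort trajectory tibble (columns `agent`, `walk`,
#'   `x`, `y`, `heading`, `w_*`, `scan`).
#' @return tibble of per-(agent, walk) metrics.
#' @export
walk_metrics <- function(trajectories) {
  keys <- intersect(c("agent", "walk"), names(trajectories))
  trajectories |>
    weight_shares() |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      area = coverage_area(dplyr::pick(dplyr::everything())),
      max_dist = max_distance(dplyr::pick(dplyr::everything())),
      turn = turning_stats(dplyr::pick(dplyr::everything())),
      scans = sum(.data$scan),
      w_v = mean(.data$sh_v), w_olf = mean(.data$sh_olf),
      w_pi = mean(.data$sh_pi),
      .groups = "drop"
    )
}

#' Empirical per-walk bounds for area and maximum distance
#'
#' First-walk values from field observations of learning walks
#' (area 0.07 +/- 0.035 m^2, maximum distance 0.184 +/- 0.0636 m), with
#' mean and SD scaled by the reported fold-increases across walks
#' (area x8, x2.5, x2.5; distance x3.8, x2, x2).
#'
#' @param area1 mean and sd of the first-walk coverage area (m^2).
#' @param dist1 mean and sd of the first-walk maximum distance (m).
#' @param area_mult,dist_mult per-walk fold-changes.
#' @return tibble: `walk`, `area_mean`, `area_sd`, `dist_mean`, `dist_sd`.
#' @export
bio_bounds <- function(area1 = c(0.07, 0.035), dist1 = c(0.184, 0.0636),
                       area_mult = c(8, 2.5, 2.5), dist_mult = c(3.8, 2, 2)) {
  fa <- c(1, cumprod(area_mult))
  fd <- c(1, cumprod(dist_mult))
  tibble::tibble(walk = seq_along(fa),
                 area_mean = area1[1] * fa, area_sd = area1[2] * fa,
                 dist_mean = dist1[1] * fd, dist_sd = dist1[2] * fd)
}

#' Fraction of trials inside the empirical bands
#'
#' Pools all (agent, walk) metric values and reports, per metric, the
#' fraction lying within the per-walk `mean +/- sd` band.
#'
#' @param metrics a [walk_metrics()] tibble.
#' @param bounds a [bio_bounds()] tibble.
#' @return tibble with `metric` ("area", "max_dist") and `fraction`.
#' @export
within_bounds_fraction <- function(metrics, bounds) {
  m <- dplyr::left_join(metrics, bounds, by = "walk")
  tibble::tibble(
    metric = c("area", "max_dist"),
    fraction = c(
      mean(m$area >= m$area_mean - m$area_sd & m$area <= m$area_mean + m$area_sd),
      mean(m$max_dist >= m$dist_mean - m$dist_sd & m$max_dist <= m$dist_mean + m$dist_sd)
    )
  )
}

#' Cue-weight dynamics within and across walks
#'
#' Each walk is resampled to `n_bins` normalised steps; quartiles across
#' agents summarise the within-walk weight profile, and per-walk means
#' (average share over all steps and agents) summarise the across-walk
#' trend.
#'
#' @param trajectories cohort trajectory tibble.
#' @param n_bins number of normalised step bins.
#' @return list with `profiles` (tibble: `walk`, `bin`, `cue`, `q25`,
#'   `q50`, `q75`, `mean`) and `means` (tibble: `walk`, `cue`, `mean`).
#' @export
weight_dynamics <- function(trajectories, n_bins = 100) {
  tr <- weight_shares(trajectories)
  keys <- intersect(c("agent", "walk"), names(tr))
  long <- tr |>
    dplyr::select(dplyr::all_of(c(keys, "step", "sh_v", "sh_olf", "sh_pi"))) |>
    tidyr::pivot_longer(dplyr::all_of(c("sh_v", "sh_olf", "sh_pi")),
                        names_to = "cue", values_to = "w") |>
    dplyr::mutate(cue = c(sh_v = "visual", sh_olf = "olfactory",
                          sh_pi = "pi")[.data$cue])
  resampled <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "cue")))) |>
    dplyr::reframe(bin = seq_len(n_bins),
                   w = approx(seq_along(.data$w), .data$w,
                              xout = seq(1, length(.data$w),
                                         length.out = n_bins))$y)
  profiles <- resampled |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(intersect("walk", keys), "cue", "bin")))) |>
    dplyr::summarise(q25 = quantile(.data$w, 0.25),
                     q50 = quantile(.data$w, 0.5),
                     q75 = quantile(.data$w, 0.75),
                     mean = mean(.data$w), .groups = "drop")
  means <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(intersect("walk", keys), "cue")))) |>
    dplyr::summarise(mean = mean(.data$w), .groups = "drop")
  list(profiles = profiles, means = means)
}
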