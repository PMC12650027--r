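# Innate olfactory homing estimate and the noisy path-integration state.

#' Olfactory familiarity
#'
#' With the field normalised to peak 1 at the nest, the olfactory
#' familiarity score is the concentration itself.
#'
#' @param field an [odour_field()].
#' @param position `(x, y)` meters (or a two-column matrix).
#' @return `omega_olf` in `[0, 1]`.
#' @export
olf_familiarity <- function(field, position) {
  odour_concentration(field, position)
}

#' Olfactory homing direction
#'
#' For the isotropic nest-centred field the up-gradient direction is simply
#' the bearing to the nest, `atan2(-y, -x)`.
#'
#' @param position `(x, y)` meters.
#' @return angle in `(-pi, pi]`, or `NA` at the nest itself where the
#'   direction is undefined.
#' @export
olf_homing_direction <- function(position) {
  if (position[1] == 0 && position[2] == 0) return(NA_real_)
  wrap_angle(atan2(-position[2], -position[1]))
}

#' Path-integration state
#'
#' Accumulates outbound movement vectors with small per-step Gaussian
#' errors, the model's stand-in for biological noise in self-motion
#' estimation.
#'
#' @param noise_sd per-component per-step error SD, meters (1% of the
#'   default 0.01 m step).
#' @return a `pi_state` object with zero displacement.
#' @export
pi_state <- function(noise_sd = 1e-4) {
  structure(list(displacement = c(0, 0), noise_sd = noise_sd),
            class = "pi_state")
}

#' Accumulate one movement step into the PI state
#'
#' `displacement <- displacement + step_vector + delta`, with `delta`
#' components i.i.d. `N(0, noise_sd^2)` drawn from the caller's RNG stream.
#'
#' @param state a [pi_state()].
#' @param step_vector realised movement `(dx, dy)`, meters.
#' @return updated state.
#' @export
pi_update <- function(state, step_vector) {
  state$displacement <- state$displacement + step_vector +
    rnorm(2, 0, state$noise_sd)
  state
}

#' Nestward direction indicated by path integration
#'
#' The PI state holds the outbound (nest-to-agent) vector estimate; the
#' homing direction is its antipode, `atan2(-dy, -dx)`.
#'
#' @param state a [pi_state()].
#' @param eps vector lengths at or below this are treated as undefined.
#' @return angle in `(-pi, pi]`, or `NA` when the vector is degenerate.
#' @export
pi_home_direction <- function(state, eps = 1e-6) {
  d <- state$displacement
  if (sqrt(sum(d^2)) <= eps) return(NA_real_)
  wrap_angle(atan2(-d[2], -d[1]))
}

#' Per-walk maximum-distance schedule
#'
#' The expected maximum excursion of walk k: `d1` for the first walk,
#' then multiplied cumulatively by `multipliers` (default 3.8, 2, 2, the
#' empirical fold-increases across the first four walks).
#'
#' @param d1 first-walk maximum distance, meters (empirical default
#'   0.184 m).
#' @param multipliers fold-changes for successive walks (> 0).
#' @return numeric vector `d_k`, class `dk_schedule`.
#' @examples
#' dk_schedule(0.184)  # 0.184 0.6992 1.3984 2.7968
#' @export
dk_schedule <- function(d1 = 0.184, multipliers = c(3.8, 2, 2)) {
  if (d1 <= 0) abort("`d1` must be positive.")
  if (any(multipliers <= 0)) abort("`multipliers` must be positive.")
  structure(c(d1, d1 * cumprod(multipliers)), class = "dk_schedule")
}

#' Path-integration offset contribution
#'
#' Ratio of the current PI vector length to the walk's expected maximum,
#' clamped to `[0, 1]`; in scaled mode (the default) multiplied by `pi` so
#' the contribution is an angular deviation in `[0, pi]` like the other
#' two mappings.
#'
#' @param r current PI vector length, meters.
#' @param schedule a [dk_schedule()].
#' @param k walk index (1-based).
#' @param scaled multiply by `pi` (angular mode) or return the bare ratio.
#' @param form `"ratio"`: the literal ratio `r / d_k` (larger excursion,
#'   larger offset); `"complement"`: the remaining exploration licence of
#'   the walk, which makes the schedule act as a leash (offset, hence
#'   boldness, shrinks as the PI vector approaches the walk's expected
#'   maximum).
#' @param grace for `"complement"`, the fraction of `d_k` over which the
#'   licence stays at its maximum before declining linearly to zero at
#'   `d_k` (piecewise-linear leash; 0 gives a single linear ramp).
#' @export
pi_offset <- function(r, schedule, k, scaled = TRUE,
                      form = c("ratio", "complement"), grace = 0) {
  form <- match.arg(form)
  if (k < 1 || k > length(schedule)) abort("`k` outside the schedule.")
  dk <- schedule[k]
  if (dk <= 0) abort("invalid schedule: d_k <= 0.")
  ratio <- min(r / dk, 1)
  f <- if (form == "complement") {
    min(1, (1 - ratio) / (1 - grace))
  } else ratio
  if (scaled) f * pi else f
}
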