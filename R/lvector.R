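# Fusion of the three cue estimates into the Homing Vector, the
# familiarity-driven exploration offset phi, and the Learning Vector.

#' Path-integration weight
#'
#' PI acts as the fallback cue: its weight is whatever confidence the other
#' two leave, floored at zero: `max(1 - w_v - w_olf, 0)`.
#'
#' @param w_v,w_olf visual and olfactory familiarity weights in `[0, 1]`.
#' @export
pi_weight <- function(w_v, w_olf) pmax(1 - w_v - w_olf, 0)

#' Weighted Homing Vector
#'
#' Sum of the unit vectors of the available cue directions, each scaled by
#' its weight.  A cue whose direction is undefined (`NA`) contributes
#' nothing.
#'
#' @param weights numeric `c(w_v, w_olf, w_pi)`.
#' @param theta_v,theta_olf,theta_pi cue directions in radians, `NA` when
#'   unavailable.
#' @return length-2 numeric; attribute `degenerate` is TRUE when no cue was
#'   available or the sum (near-)cancels.
#' @export
homing_vector <- function(weights, theta_v = NA, theta_olf = NA,
                          theta_pi = NA) {
  th <- c(theta_v, theta_olf, theta_pi)
  ok <- is.finite(th)
  v <- c(0, 0)
  if (any(ok)) {
    v <- c(sum(weights[ok] * cos(th[ok])), sum(weights[ok] * sin(th[ok])))
  }
  attr(v, "degenerate") <- !any(ok) || sqrt(sum(v^2)) < 1e-9
  v
}

#' Visual familiarity-to-offset mapping
#'
#' Piecewise-linear map of the current MBON novelty `vn` against the recent
#' novelty trace: with window mean `V` and SD `s`, values at or below
#' `V - s` (very familiar) map to `pi`, values at or above `V + s` (very
#' novel) to 0, linear in between.  A degenerate window (fewer than 3
#' entries or zero spread) maps to the neutral `pi/2`.
#'
#' @param trace numeric vector of MBON novelty scores recorded at scans
#'   (oldest first).
#' @param vn current novelty score; defaults to the last trace entry.
#' @param window number of most recent entries used.
#' @return offset in `[0, pi]`.
#' @export
fv_offset <- function(trace, vn = NULL, window = 10) {
  if (length(trace) == 0) abort("empty novelty trace.")
  vn <- vn %||% trace[length(trace)]
  w <- utils::tail(trace, window)
  if (length(w) < 3 || sd(w) == 0) return(pi / 2)
  m <- mean(w) - sd(w); M <- mean(w) + sd(w)
  if (vn <= m) return(pi)
  if (vn >= M) return(0)
  (M - vn) / (M - m) * pi
}

#' Olfactory familiarity-to-offset mapping
#'
#' Directly maps the relative concentration to an angular deviation:
#' `c * pi`.
#'
#' @param c concentration in `[0, 1]`.
#' @export
folf_offset <- function(c) {
  if (any(c < 0 | c > 1)) abort("`c` must lie in [0, 1].")
  c * pi
}

#' Total exploration offset phi
#'
#' Weighted sum of the three modality offsets, gated by the exploration
#' state `ac` (0 forces pure homing) and clamped to `[0, pi]`.
#'
#' @param ac binary exploration state.
#' @param weights numeric `c(w_v, w_olf, w_pi)`.
#' @param f_v,f_olf,f_pi modality offsets in `[0, pi]`.
#' @export
total_offset <- function(ac, weights, f_v, f_olf, f_pi) {
  phi <- ac * (weights[1] * f_v + weights[2] * f_olf + weights[3] * f_pi)
  min(max(phi, 0), pi)
}

#' Rotate the Homing Vector into the Learning Vector
#'
#' Standard 2D rotation by `sign * phi`; the norm is preserved.  The
#' default fixed counter-clockwise sign follows the model's literal form;
#' `sign = -1` gives the mirrored loop.
#'
#' @param homing length-2 numeric.
#' @param phi rotation magnitude in `[0, pi]`.
#' @param sign `+1` (CCW) or `-1` (CW).
#' @export
rotate_vec <- function(homing, phi, sign = 1) {
  a <- sign * phi
  c(cos(a) * homing[1] - sin(a) * homing[2],
    sin(a) * homing[1] + cos(a) * homing[2])
}
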