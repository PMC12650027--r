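# Mushroom-body familiarity network: VPN -> KC -> MBON with synaptic
# depression of active KC->MBON weights.  The MBON output is a scalar
# novelty score; repeated exposure to a view lowers it.

#' Sigmoid firing-rate transfer
#'
#' Default rate transfer `1 / (1 + exp(-input))` used for model neurons.
#'
#' @param input net input (any real).
#' @return rate in `(0, 1)`.
#' @export
neuron_rate <- function(input) 1 / (1 + exp(-input))

#' Construct a mushroom-body network
#'
#' Each of `n_kc` Kenyon cells receives a fixed random fan-in of `fan_in`
#' visual projection neurons (VPNs, one per Zernike amplitude); all
#' KC-to-MBON weights start at 1 and are depressed during learning.
#'
#' @param n_vpn number of VPNs; must equal the Zernike feature count,
#'   `(n_max + 2)^2 / 4`.
#' @param n_kc number of Kenyon cells.
#' @param fan_in VPNs sampled per KC.
#' @param theta_kc KC activation threshold on the mean of its (min-max
#'   normalised) VPN inputs.
#' @param lambda_vis learning rate: weight decrement per exposure of an
#'   active KC.
#' @param kc_sparsity cap on the active fraction of KCs per presentation:
#'   of the above-threshold KCs, only the `kc_sparsity * n_kc` with the
#'   strongest drives fire (winner-take-all sparsity control of the kind
#'   attributed to APL-like inhibitory feedback).
#' @param drive_mode denominator of the KC drive: `"fanin"` (mean of the
#'   connected inputs, the default) or `"population"` (sum normalised by
#'   `n_vpn`, a much sparser threshold code).
#' @param use_m0 keep the rotation-symmetric (m = 0) Zernike amplitudes in
#'   the MB input; by default they are zeroed (they carry no bearing
#'   pattern and mask the location-specific code).
#' @param seed integer seed for the VPN-KC wiring.
#' @param n_max Zernike order (implies `n_vpn`).
#' @param resolution panorama grid `c(n_az, n_el)` the network is wired for.
#' @param disk_res unit-disk raster side used in the encoding operator.
#' @param eye_height,elevation renderer parameters (see
#'   [render_panorama()]).
#' @return an `mb_network` object.
#' @export
mb_network <- function(n_vpn = 81, n_kc = 4000, fan_in = 10, theta_kc = 0.04,
                       lambda_vis = 0.01, kc_sparsity = 0.02,
                       drive_mode = c("fanin", "population"), use_m0 = FALSE,
                       seed = 1,
                       n_max = 16, resolution = c(90, 25), disk_res = 96,
                       eye_height = 0.005, elevation = c(-10, 60)) {
  nf <- (n_max + 2)^2 / 4
  if (n_vpn != nf)
    abort(sprintf("`n_vpn` (%d) must match the Zernike feature count %d for n_max = %d.",
                  n_vpn, nf, n_max))
  drive_mode <- match.arg(drive_mode)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  conn <- t(vapply(seq_len(n_kc), function(i) sample.int(n_vpn, fan_in),
                   integer(fan_in)))
  structure(list(conn = conn, w = rep(1, n_kc), theta_kc = theta_kc,
                 lambda_vis = lambda_vis,
                 kc_max = as.integer(round(kc_sparsity * n_kc)),
                 n_vpn = n_vpn, n_kc = n_kc,
                 fan_in = fan_in, seed = seed, n_max = n_max,
                 resolution = as.integer(resolution), disk_res = disk_res,
                 eye_height = eye_height, elevation = elevation,
                 gain = NULL, drive_mode = drive_mode, use_m0 = use_m0),
            class = "mb_network")
}

# Encoding operator for the MB input.  Unless `use_m0` is set, the
# rotation-symmetric (m = 0) moment rows are zeroed: they carry no bearing
# pattern and mostly encode overall skyline energy, which is shared by all
# views and would mask the location-specific component of the code.
mb_operator <- function(net) {
  if (isTRUE(net$use_m0))
    return(zm_operator(net$n_max, net$resolution[1], net$resolution[2],
                       net$disk_res))
  key <- paste0("mbop0_", net$n_max, "_", net$resolution[1], "_",
                net$resolution[2])
  if (is.null(the_cache[[key]])) {
    op <- zm_operator(net$n_max, net$resolution[1], net$resolution[2],
                      net$disk_res)
    z <- op$pairs$m == 0
    op$re[z, ] <- 0
    op$im[z, ] <- 0
    the_cache[[key]] <- op
  }
  the_cache[[key]]
}

#' Kenyon-cell activation for a feature vector
#'
#' Features are log-compressed (`log1p` of the amplitude relative to the
#' spectrum median) and min-max normalised to `[0, 1]` per presentation,
#' so KC competition reflects the mid-spectrum pattern of the view rather
#' than the few globally dominant amplitudes; a KC is
#' active iff the mean of its connected VPN values exceeds `theta_kc` and
#' it is among the `kc_max` most strongly driven KCs (the winner-take-all
#' sparsity cap).  The cap keeps the active population at a fixed size, so
#' MBON scores are comparable across views; the threshold silences truly
#' featureless input.
#'
#' @param net an [mb_network()].
#' @param features numeric vector of length `n_vpn` (Zernike amplitudes).
#' @return logical vector of length `n_kc`.
#' @export
kc_activation <- function(net, features) {
  if (length(features) != net$n_vpn)
    abort("`features` length must equal the number of VPNs.")
  if (!is.null(net$gain)) features <- features * net$gain
  f <- if (diff(range(features)) > 0) {
    lf <- log1p(features / max(stats::median(features), 1e-12))
    (lf - min(lf)) / (max(lf) - min(lf))
  } else rep(0, length(features))
  drive <- rowMeans(matrix(f[net$conn], nrow(net$conn), ncol(net$conn)))
  act <- drive > net$theta_kc
  kmax <- net$kc_max %||% 0L
  if (kmax > 0 && sum(act) > kmax) {
    keep <- order(drive, decreasing = TRUE)[seq_len(kmax)]
    act <- rep(FALSE, length(act))
    act[keep] <- TRUE
  }
  act
}

#' MBON novelty score
#'
#' `cmbon` is the sum of KC-to-MBON weights over active KCs; the normalised
#' novelty divides by the active-KC count so that a never-seen pattern
#' scores 1 and a fully depressed one 0.
#'
#' @param net an [mb_network()].
#' @param active logical (or index) vector of active KCs.
#' @return list with `cmbon` (raw weighted sum), `n_active`, and `novelty`
#'   in `[0, 1]`.
#' @export
mbon_novelty <- function(net, active) {
  idx <- if (is.logical(active)) which(active) else as.integer(active)
  cmbon <- sum(net$w[idx])
  list(cmbon = cmbon, n_active = length(idx),
       novelty = cmbon / max(1, length(idx)))
}

#' Depress the weights of active KCs (one learning exposure)
#'
#' Subtractive rule with a floor at zero: `w <- max(0, w - lambda_vis)` for
#' each active KC; inactive weights are untouched.
#'
#' @inheritParams mbon_novelty
#' @return the updated network.
#' @export
mb_learn <- function(net, active) {
  idx <- if (is.logical(active)) which(active) else as.integer(active)
  net$w[idx] <- pmax(0, net$w[idx] - net$lambda_vis)
  net
}

#' Visual familiarity from a raw MBON score
#'
#' `omega_v = 1 - cmbon / normalizer`, clipped to `[0, 1]`.  The default
#' normaliser in the simulation is the current active-KC count (novel view
#' -> 0, fully learned -> 1); pass `normalizer = net$n_kc` for the literal
#' total-KC normalisation.
#'
#' @param cmbon raw MBON score.
#' @param normalizer positive scalar.
#' @export
visual_familiarity <- function(cmbon, normalizer) {
  stopifnot(normalizer > 0)
  min(1, max(0, 1 - cmbon / normalizer))
}

#' Novelty of the view at a position (fused fast path)
#'
#' Renders the panorama at `position`, encodes it and runs the MB forward
#' pass in one C++ call.
#'
#' @param net an [mb_network()].
#' @param mesh a [generate_terrain()] mesh (or a pre-extracted triangle
#'   matrix).
#' @param position `(x, y)` meters.
#' @param want_active also return the active KC indices (needed for
#'   learning).
#' @return list with `cmbon`, `n_active` (and `active` if requested).
#' @export
novelty_at <- function(net, mesh, position, want_active = FALSE) {
  tri <- if (is.matrix(mesh)) mesh else mesh_tri_matrix(mesh)
  op <- mb_operator(net)
  novelty_at_cpp(tri, position[1], position[2], net$eye_height,
                 net$resolution[1], net$resolution[2],
                 net$elevation[1] * pi / 180, net$elevation[2] * pi / 180,
                 op$re, op$im, net$conn, net$w, net$theta_kc, want_active,
                 net$kc_max %||% 0L, net$gain,
                 identical(net$drive_mode, "population"))
}

#' Visual homing direction by directional novelty sampling
#'
#' Evaluates the MBON novelty at `n_headings` equally spaced neighbouring
#' positions at distance `U` and returns the heading that maximises the
#' novelty decrease relative to the current position (i.e. the most
#' familiar-looking direction).  Ties are broken uniformly at random with
#' the caller's RNG stream.
#'
#' @param net an [mb_network()].
#' @param mesh terrain mesh (or triangle matrix).
#' @param position `(x, y)` meters.
#' @param U sampling step, meters.
#' @param n_headings number of equally spaced sample headings (>= 4).
#' @param offset rotation offset of the heading sample grid, radians.
#' @return list with `theta` (radians, in `(-pi, pi]`), `confident`
#'   (FALSE when all sampled directions look alike), and `delta` (the best
#'   novelty decrease).
#' @export
visual_homing_direction <- function(net, mesh, position, U = 0.01,
                                    n_headings = 8, offset = 0) {
  stopifnot(n_headings >= 4)
  tri <- if (is.matrix(mesh)) mesh else mesh_tri_matrix(mesh)
  h <- novelty_at(net, tri, position)
  here <- h$cmbon / max(1, h$n_active)
  thetas <- offset + 2 * pi * (seq_len(n_headings) - 1) / n_headings
  nb <- vapply(thetas, function(th) {
    z <- novelty_at(net, tri, position + U * c(cos(th), sin(th)))
    z$cmbon / max(1, z$n_active)
  }, numeric(1))
  dec <- here - nb
  best <- max(dec)
  tol <- 1e-12 + 1e-9 * abs(best)
  cand <- which(dec >= best - tol)
  pick <- if (length(cand) > 1) cand[sample.int(length(cand), 1)] else cand
  list(theta = wrap_angle(thetas[pick]),
       confident = (max(dec) - min(dec)) > 1e-12,
       delta = best)
}

#' Calibrate VPN gains to the world's amplitude statistics
#'
#' Optional adaptive gain control: samples panoramas at random positions
#' and sets each VPN's gain to the reciprocal of that feature's mean
#' amplitude, whitening the habitat's average spectrum.  Sharpens the KC
#' code's spatial selectivity (shorter correlation length) at the cost of
#' generalisation; the default pipeline leaves gains unset.
#'
#' @param net an [mb_network()].
#' @param mesh terrain mesh (or triangle matrix).
#' @param radius positions are sampled uniformly in the disc of this
#'   radius around the nest.
#' @param n_views number of calibration views.
#' @return the network with its `gain` field set.
#' @export
mb_calibrate <- function(net, mesh, radius = 8, n_views = 50) {
  tri <- if (is.matrix(mesh)) mesh else mesh_tri_matrix(mesh)
  op <- mb_operator(net)
  tot <- numeric(net$n_vpn)
  for (i in seq_len(n_views)) {
    r <- radius * sqrt(runif(1)); a <- runif(1, 0, 2 * pi)
    pano <- render_panorama_cpp(tri, r * cos(a), r * sin(a), net$eye_height,
                                net$resolution[1], net$resolution[2],
                                net$elevation[1] * pi / 180,
                                net$elevation[2] * pi / 180)
    v <- as.numeric(pano)
    tot <- tot + sqrt((op$re %*% v)^2 + (op$im %*% v)^2)[, 1]
  }
  m <- tot / n_views
  net$gain <- ifelse(m > 0, 1 / m, 0)
  net
}

#' Serialise / restore an MB network
#'
#' Writes the wiring seed, parameters and weight vector to a versioned JSON
#' file, so a trained memory can be reused between learning and testing
#' phases.
#'
#' @param net an [mb_network()].
#' @param path file path.
#' @export
write_mb_network <- function(net, path) {
  obj <- list(format = "learnwalk-mb", version = 1L,
              params = net[c("n_vpn", "n_kc", "fan_in", "theta_kc",
                             "lambda_vis", "kc_max", "drive_mode", "use_m0",
                             "seed", "n_max", "resolution", "disk_res",
                             "eye_height", "elevation")],
              gain = net$gain,
              w = net$w)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mb_network
#' @export
read_mb_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "learnwalk-mb"))
    abort("Not a learnwalk MB network file.")
  p <- obj$params
  net <- mb_network(n_vpn = p$n_vpn, n_kc = p$n_kc, fan_in = p$fan_in,
                    theta_kc = p$theta_kc, lambda_vis = p$lambda_vis,
                    kc_sparsity = p$kc_max / p$n_kc,
                    drive_mode = p$drive_mode, use_m0 = isTRUE(p$use_m0),
                    seed = p$seed, n_max = p$n_max,
                    resolution = p$resolution, disk_res = p$disk_res,
                    eye_height = p$eye_height, elevation = p$elevation)
  net$w <- as.numeric(obj$w)
  if (length(obj$gain)) net$gain <- as.numeric(obj$gain)
  net
}
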