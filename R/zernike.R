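# Rotation-invariant panorama encoding via Zernike moment amplitudes.
#
# The panorama (azimuth x elevation) is mapped onto the unit disk so that a
# change of viewer heading becomes a rigid rotation of the disk; the moduli
# of the Zernike moments are invariant under such rotations, giving a
# heading-independent feature vector that feeds the visual projection
# neurons of the mushroom-body network.

the_cache <- new.env(parent = emptyenv())

#' Zernike (n, m) index pairs
#'
#' All pairs with `0 <= m <= n <= n_max` and `n - m` even, ordered n-major,
#' m-minor.  For even `n_max` the number of pairs is `(n_max + 2)^2 / 4`
#' (81 for `n_max = 16`).
#'
#' @param n_max maximum radial order (even, >= 0).
#' @return tibble with columns `n`, `m`.
#' @export
zm_pairs <- function(n_max = 16) {
  stopifnot(n_max >= 0)
  do.call(rbind, lapply(0:n_max, function(n) {
    m <- seq(n %% 2, n, by = 2)
    data.frame(n = n, m = m)
  })) |> tibble::as_tibble()
}

# Radial polynomial R_nm evaluated at rho (vectorised).
zm_radial <- function(n, m, rho) {
  s_max <- (n - m) / 2
  out <- 0
  for (s in 0:s_max) {
    coef <- (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s))
    out <- out + coef * rho^(n - 2 * s)
  }
  out
}

# Complex Zernike basis over a D x D Cartesian raster of the unit disk.
# Returns list(re, im): n_feat x D^2 matrices including the (n+1)/pi and
# pixel-area factors, zero outside the unit circle.
zernike_basis <- function(n_max, D) {
  key <- paste0("basis_", n_max, "_", D)
  if (!is.null(the_cache[[key]])) return(the_cache[[key]])
  ctr <- (2 * (seq_len(D) - 1) + 1) / D - 1  # pixel centres in (-1, 1)
  x <- rep(ctr, times = D)                    # column-major: x varies fastest
  y <- rep(ctr, each = D)
  rho <- sqrt(x^2 + y^2)
  theta <- atan2(y, x)
  inside <- rho <= 1
  dA <- (2 / D)^2
  pairs <- zm_pairs(n_max)
  nf <- nrow(pairs)
  re <- matrix(0, nf, D^2)
  im <- matrix(0, nf, D^2)
  for (i in seq_len(nf)) {
    n <- pairs$n[i]; m <- pairs$m[i]
    rad <- numeric(D^2)
    rad[inside] <- zm_radial(n, m, rho[inside])
    fac <- (n + 1) / pi * dA
    re[i, ] <- fac * rad * cos(m * theta) * inside
    im[i, ] <- fac * rad * (-sin(m * theta)) * inside
  }
  the_cache[[key]] <- list(re = re, im = im, pairs = pairs)
  the_cache[[key]]
}

#' Map a panorama onto the unit disk
#'
#' Azimuth becomes the polar angle and elevation the radius (top of the
#' field of view at the centre, bottom at the rim), so that a cyclic
#' azimuth shift of the panorama is a rotation of the disk.  Intensities
#' are sampled bilinearly; pixels outside the unit circle are zero.
#'
#' @param view a [render_panorama()] panorama (or any `n_el x n_az` matrix,
#'   row 1 = top).
#' @param D output raster side length (square).
#' @return a `D x D` matrix (`disk_image`).
#' @export
preprocess_panorama <- function(view, D = 96) {
  n_el <- nrow(view); n_az <- ncol(view)
  ctr <- (2 * (seq_len(D) - 1) + 1) / D - 1
  x <- rep(ctr, times = D)
  y <- rep(ctr, each = D)
  rho <- sqrt(x^2 + y^2)
  phi <- atan2(y, x) %% (2 * pi)
  val <- numeric(D^2)
  inside <- rho <= 1
  rc <- 1 + rho[inside] * (n_el - 1)           # fractional row (top = 1)
  cc <- 1 + phi[inside] / (2 * pi) * n_az      # fractional column, wraps
  r0 <- pmin(pmax(floor(rc), 1), n_el); r1 <- pmin(r0 + 1, n_el)
  fr <- rc - floor(rc)
  c0 <- floor(cc); fc <- cc - c0
  c0w <- ((c0 - 1) %% n_az) + 1; c1w <- (c0 %% n_az) + 1
  v <- (1 - fr) * (1 - fc) * view[cbind(r0, c0w)] +
       (1 - fr) * fc       * view[cbind(r0, c1w)] +
       fr       * (1 - fc) * view[cbind(r1, c0w)] +
       fr       * fc       * view[cbind(r1, c1w)]
  val[inside] <- v
  m <- matrix(val, D, D)  # column-major: x fastest, matches zernike_basis
  structure(m, class = c("disk_image", "matrix", "array"))
}

#' Zernike moment amplitudes of a disk image
#'
#' @param disk square matrix raster of the unit disk (see
#'   [preprocess_panorama()]).
#' @param n_max maximum radial order (even).
#' @return numeric vector of amplitudes `|Z_nm|`, ordered as [zm_pairs()];
#'   length 81 for `n_max = 16`.
#' @export
zernike_amplitudes <- function(disk, n_max = 16) {
  if (!is.matrix(disk) || nrow(disk) != ncol(disk))
    abort("`disk` must be a square matrix raster.")
  if (n_max %% 2 != 0) abort("`n_max` must be even.")
  b <- zernike_basis(n_max, nrow(disk))
  v <- as.numeric(disk)
  sqrt((b$re %*% v)^2 + (b$im %*% v)^2)[, 1]
}

# Combined linear operator panorama -> Zernike moments, built on a polar
# quadrature: the panorama grid itself provides the disk sample points
# (elevation -> radius, azimuth -> polar angle), so a cyclic azimuth shift
# of the panorama permutes the quadrature nodes and the amplitudes are
# exactly invariant.  One matrix-vector product per view yields all
# amplitudes.  (`D` is accepted for interface parity with the Cartesian
# raster path but does not enter the quadrature.)
zm_operator <- function(n_max, n_az, n_el, D = 96) {
  key <- paste0("op_", n_max, "_", n_az, "_", n_el)
  if (!is.null(the_cache[[key]])) return(the_cache[[key]])
  pairs <- zm_pairs(n_max)
  nf <- nrow(pairs)
  rho <- (seq_len(n_el) - 1) / (n_el - 1)   # row 1 (top) at the centre
  phi <- 2 * pi * (seq_len(n_az) - 1) / n_az
  d_rho <- 1 / (n_el - 1)
  d_phi <- 2 * pi / n_az
  # trapezoid end-point correction in rho
  wr <- rho * d_rho; wr[c(1, n_el)] <- wr[c(1, n_el)] / 2
  re <- matrix(0, nf, n_el * n_az)
  im <- matrix(0, nf, n_el * n_az)
  for (i in seq_len(nf)) {
    n <- pairs$n[i]; m <- pairs$m[i]
    rad <- zm_radial(n, m, rho) * wr * (n + 1) / pi * d_phi
    re[i, ] <- as.numeric(outer(rad, cos(m * phi)))
    im[i, ] <- as.numeric(outer(rad, -sin(m * phi)))
  }
  op <- list(re = re, im = im, pairs = pairs)
  the_cache[[key]] <- op
  op
}

#' Zernike amplitudes of a panorama (production encoding)
#'
#' Encodes a panorama directly through the polar-quadrature moment
#' operator (azimuth = polar angle, elevation = radius).  Amplitudes are
#' exactly invariant under cyclic azimuth shifts of the panorama, i.e.
#' under changes of viewer heading.
#'
#' @param view an `n_el x n_az` panorama matrix (row 1 = top).
#' @param n_max maximum radial order (even).
#' @return numeric amplitude vector ordered as [zm_pairs()].
#' @export
panorama_amplitudes <- function(view, n_max = 16) {
  op <- zm_operator(n_max, ncol(view), nrow(view))
  v <- as.numeric(view)
  sqrt((op$re %*% v)^2 + (op$im %*% v)^2)[, 1]
}
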