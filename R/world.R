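#' Generate a synthetic tussock terrain
#'
#' Builds the visual environment the agent learns: a flat ground plane with
#' cone-shaped, tussock-like objects scattered at random positions and
#' heights.  A clear disc around the nest (the origin) is kept free of
#' objects.  Generation is fully deterministic given `seed` and the
#' parameters.
#'
#' @param seed integer seed controlling object placement.
#' @param n_objects number of cone objects (>= 0).
#' @param height_range length-2 numeric, min/max object height in meters.
#' @param extent half-width of the square world, meters; the world spans
#'   `[-extent, extent]` in x and y (the navigable arena; landmarks may
#'   stand outside it).
#' @param scatter radial annulus `c(min, max)` (m) in which objects are
#'   scattered uniformly by area.  The default keeps the arena itself an
#'   open clearing with all landmarks distant, so panoramas change
#'   smoothly (metre-scale parallax) across the whole arena, the regime
#'   snapshot-based familiarity relies on.
#' @param nest_clear radius (m) of the object-free disc around the nest
#'   (only binding when `scatter[1]` is smaller).
#' @param tri_per_object number of side triangles per cone (also the number
#'   of base vertices).
#' @param radius_range base radius of each cone as a multiple of its height
#'   (length-2 numeric, sampled uniformly).
#' @return a `terrain_mesh`: a tibble with one triangle per row (columns
#'   `x1 y1 z1 x2 y2 z2 x3 y3 z3`, meters) and attributes `extent`, `seed`.
#'   The first two rows are the ground-plane triangles (all `z = 0`).
#' @examples
#' mesh <- generate_terrain(seed = 1, n_objects = 5)
#' nrow(mesh)  # 2 ground triangles + 5 * 8
#' @export
generate_terrain <- function(seed, n_objects = 60, height_range = c(1, 4),
                             extent = 10, scatter = c(8, 20), nest_clear = 0.1,
                             tri_per_object = 8, radius_range = c(0.4, 1.0)) {
  if (extent <= 0) abort("`extent` must be positive.")
  if (any(height_range <= 0) || height_range[2] < height_range[1])
    abort("`height_range` must be a positive, increasing pair.")
  if (n_objects < 0) abort("`n_objects` must be >= 0.")

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  e <- extent
  ground <- rbind(
    c(-e, -e, 0, e, -e, 0, e, e, 0),
    c(-e, -e, 0, e, e, 0, -e, e, 0)
  )
  tris <- ground
  if (n_objects > 0) {
    k <- tri_per_object
    base_ang <- 2 * pi * (seq_len(k) - 1) / k
    obj <- vector("list", n_objects)
    for (i in seq_len(n_objects)) {
      repeat {
        r <- sqrt(runif(1, scatter[1]^2, scatter[2]^2))
        a <- runif(1, 0, 2 * pi)
        cx <- r * cos(a); cy <- r * sin(a)
        if (cx^2 + cy^2 > nest_clear^2) break
      }
      h <- runif(1, height_range[1], height_range[2])
      rb <- h * runif(1, radius_range[1], radius_range[2])
      bx <- cx + rb * cos(base_ang); by <- cy + rb * sin(base_ang)
      j <- c(seq_len(k)[-1], 1L)
      obj[[i]] <- cbind(bx, by, 0, bx[j], by[j], 0, cx, cy, h)
    }
    tris <- rbind(tris, do.call(rbind, obj))
  }
  colnames(tris) <- c("x1", "y1", "z1", "x2", "y2", "z2", "x3", "y3", "z3")
  mesh <- tibble::as_tibble(tris)
  attr(mesh, "extent") <- extent
  attr(mesh, "seed") <- seed
  attr(mesh, "nest_clear") <- nest_clear
  class(mesh) <- c("terrain_mesh", class(mesh))
  mesh
}

# Object (non-ground) triangles as a plain matrix for the C++ renderer.
mesh_tri_matrix <- function(mesh) {
  m <- as.matrix(mesh[, c("x1", "y1", "z1", "x2", "y2", "z2", "x3", "y3", "z3")])
  zmax <- pmax(m[, 3], m[, 6], m[, 9])
  m[zmax > 0, , drop = FALSE]
}

#' Render a panoramic snapshot
#'
#' Casts one ray per (azimuth, elevation) cell from a viewer at `position`
#' (eye slightly above ground) and segments the scene into object (1),
#' ground below the horizon (0.5) and sky (0).  The panorama is allocentric:
#' it depends only on position; viewer heading corresponds to a cyclic
#' azimuth shift handled downstream by the rotation-invariant encoding.
#'
#' @param mesh a [generate_terrain()] mesh.
#' @param position length-2 numeric `(x, y)` in meters; must lie within the
#'   world extent.
#' @param resolution `c(n_az, n_el)` grid size (azimuth columns x elevation
#'   rows).
#' @param eye_height viewer eye height above ground, meters.
#' @param elevation field-of-view elevation limits in degrees,
#'   `c(min, max)`.
#' @return a `panorama`: an `n_el x n_az` matrix of intensities in
#'   `[0, 1]`; row 1 is the top of the field of view, column j is azimuth
#'   `2*pi*(j-1)/n_az` (CCW from +x).
#' @export
render_panorama <- function(mesh, position, resolution = c(90, 25),
                            eye_height = 0.005, elevation = c(-10, 60)) {
  e <- attr(mesh, "extent")
  if (!is.null(e) && (abs(position[1]) > e || abs(position[2]) > e))
    abort("`position` lies outside the world extent.")
  tri <- mesh_tri_matrix(mesh)
  pano <- render_panorama_cpp(tri, position[1], position[2], eye_height,
                              as.integer(resolution[1]), as.integer(resolution[2]),
                              elevation[1] * pi / 180, elevation[2] * pi / 180)
  structure(pano, class = c("panorama", "matrix", "array"),
            azimuth0 = 0, elevation = elevation)
}

#' Nest-centred Gaussian odour field
#'
#' The nest continuously emits an odour (CO2-like point source) whose
#' concentration decays as an isotropic Gaussian,
#' `C(x, y) = c0 * exp(-(x^2 + y^2) / (2 sigma^2))`.  An optional wind
#' elongates the field into an anisotropic plume along the downwind axis.
#'
#' @param c0 peak (nest) concentration; the model normalises to 1.
#' @param sigma diffusion spread, meters.
#' @param wind optional `list(direction =, strength =)`; direction in
#'   radians, strength in `[0, 1]`.
#' @param stretch plume elongation factor along the wind at full strength.
#' @return an `odour_field` object.
#' @export
odour_field <- function(c0 = 1, sigma = 0.2, wind = NULL, stretch = 3) {
  stopifnot(c0 > 0, sigma > 0)
  structure(list(c0 = c0, sigma = sigma, centre = c(0, 0),
                 wind = wind, stretch = stretch),
            class = "odour_field")
}

#' Odour concentration at a position
#'
#' @param field an [odour_field()].
#' @param position length-2 numeric or a two-column matrix of positions.
#' @return concentration(s) in `[0, c0]`.
#' @export
odour_concentration <- function(field, position) {
  p <- if (is.matrix(position)) position else matrix(position, ncol = 2)
  if (!is.null(field$wind) && field$wind$strength > 0)
    return(plume_concentration(field, position))
  r2 <- p[, 1]^2 + p[, 2]^2
  field$c0 * exp(-r2 / (2 * field$sigma^2))
}

#' Anisotropic plume concentration
#'
#' With wind, the Gaussian is stretched along the downwind axis by
#' `1 + (stretch - 1) * strength`; at zero strength it reduces exactly to
#' [odour_concentration()].
#'
#' @inheritParams odour_concentration
#' @export
plume_concentration <- function(field, position) {
  p <- if (is.matrix(position)) position else matrix(position, ncol = 2)
  w <- field$wind
  if (is.null(w)) abort("`field` has no wind set.")
  s_par <- field$sigma * (1 + (field$stretch - 1) * w$strength)
  u <- p[, 1] * cos(w$direction) + p[, 2] * sin(w$direction)
  v <- -p[, 1] * sin(w$direction) + p[, 2] * cos(w$direction)
  field$c0 * exp(-(u^2 / (2 * s_par^2) + v^2 / (2 * field$sigma^2)))
}

#' Analytic gradient of the isotropic odour field
#'
#' Closed form `(1 / sigma^2) * exp(-(x^2 + y^2) / (2 sigma^2)) * (-x, -y)`
#' (units: concentration per meter), pointing up-gradient, i.e. toward the
#' nest.
#'
#' @inheritParams odour_concentration
#' @return length-2 numeric (or two-column matrix) gradient.
#' @export
odour_gradient <- function(field, position) {
  p <- if (is.matrix(position)) position else matrix(position, ncol = 2)
  c_ <- field$c0 * exp(-(p[, 1]^2 + p[, 2]^2) / (2 * field$sigma^2))
  g <- cbind(-p[, 1], -p[, 2]) * c_ / field$sigma^2
  if (!is.matrix(position)) g <- drop(g)
  g
}

#' Write / read a terrain mesh as a plain-text triangle list
#'
#' One triangle per line, nine whitespace-separated numbers
#' `x1 y1 z1 x2 y2 z2 x3 y3 z3` (meters).
#'
#' @param mesh a `terrain_mesh`.
#' @param path file path.
#' @export
write_terrain <- function(mesh, path) {
  m <- as.matrix(mesh[, 1:9])
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_terrain
#' @param extent world half-width to attach on read (defaults to the largest
#'   absolute vertex coordinate).
#' @export
read_terrain <- function(path, extent = NULL) {
  m <- as.matrix(utils::read.table(path))
  colnames(m) <- c("x1", "y1", "z1", "x2", "y2", "z2", "x3", "y3", "z3")
  mesh <- tibble::as_tibble(m)
  attr(mesh, "extent") <- extent %||% max(abs(m[, c(1, 2, 4, 5, 7, 8)]))
  class(mesh) <- c("terrain_mesh", class(mesh))
  mesh
}

`%||%` <- function(a, b) if (is.null(a)) b else a
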