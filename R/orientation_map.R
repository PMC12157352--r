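#' Generate a smooth pinwheel orientation-preference map
#'
#' Builds the precomputed orientation map that parameterises thalamocortical
#' Gabors and the orientation bias of cortical wiring.  Complex Gaussian
#' noise is band-pass filtered in the Fourier domain with an annular filter
#' centred on the hypercolumn spatial frequency; the half-angle of the
#' resulting field gives a smooth, pinwheel-bearing map with an
#' approximately uniform orientation histogram.  Any smooth uniform map
#' would serve; this construction is the package default and is pluggable.
#'
#' @param extent_mm sheet size, `c(width, height)` in mm (scalar recycled).
#' @param resolution_mm grid spacing in mm.
#' @param hypercolumn_mm hypercolumn scale (one full orientation cycle) in
#'   mm; must be at least twice the resolution.
#' @param seed RNG seed; the map is deterministic given the seed.
#' @param rel_bandwidth annular filter full width relative to the centre
#'   frequency (default 0.5).
#' @return object of class `"orientation_map"`: `theta` (matrix of preferred
#'   orientations in `[0, pi)`, rows indexing x), `x_mm`, `y_mm` (grid-point
#'   centres, sheet centred on 0), plus the generating parameters.
#' @export
generate_orientation_map <- function(extent_mm = c(5, 5),
                                     resolution_mm = 0.05,
                                     hypercolumn_mm = 1, seed = 1,
                                     rel_bandwidth = 0.5) {
  if (length(extent_mm) == 1) extent_mm <- rep(extent_mm, 2)
  stopifnot(all(extent_mm > 0), resolution_mm > 0, hypercolumn_mm > 0)
  if (hypercolumn_mm < 2 * resolution_mm)
    stop("hypercolumn scale below twice the grid resolution (aliasing)")
  nx <- max(4L, as.integer(round(extent_mm[1] / resolution_mm)))
  ny <- max(4L, as.integer(round(extent_mm[2] / resolution_mm)))
  set.seed(seed)
  z <- matrix(stats::rnorm(nx * ny), nx, ny) +
    1i * matrix(stats::rnorm(nx * ny), nx, ny)
  fx <- stats::fft(z)
  kx <- c(0:(nx %/% 2), -((nx - (nx %/% 2) - 1):1)) / (nx * resolution_mm)
  ky <- c(0:(ny %/% 2), -((ny - (ny %/% 2) - 1):1)) / (ny * resolution_mm)
  k <- sqrt(outer(kx^2, ky^2, "+"))
  k0 <- 1 / hypercolumn_mm
  keep <- abs(k - k0) <= rel_bandwidth * k0 / 2
  field <- stats::fft(fx * keep, inverse = TRUE)
  theta <- (Arg(field) %% (2 * pi)) / 2
  structure(list(
    theta = theta,
    x_mm = (seq_len(nx) - (nx + 1) / 2) * resolution_mm,
    y_mm = (seq_len(ny) - (ny + 1) / 2) * resolution_mm,
    extent_mm = extent_mm, resolution_mm = resolution_mm,
    hypercolumn_mm = hypercolumn_mm, seed = seed),
    class = "orientation_map")
}

#' Look up preferred orientation at sheet positions
#'
#' @param map an [generate_orientation_map()] result.
#' @param position_mm numeric vector `c(x, y)` or a 2-column matrix of
#'   positions (mm, sheet centred on 0).
#' @param method `"nearest"` (grid-point lookup, the default) or
#'   `"bilinear"` (interpolation of the doubled-angle complex field).
#' @return orientations in `[0, pi)`.
#' @export
orientation_at <- function(map, position_mm, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  p <- if (is.matrix(position_mm)) position_mm else
    matrix(position_mm, ncol = 2)
  half <- map$extent_mm / 2
  eps <- map$resolution_mm / 2 + 1e-9
  if (any(abs(p[, 1]) > half[1] + eps | abs(p[, 2]) > half[2] + eps))
    stop("position outside the cortical sheet")
  if (method == "nearest") {
    ix <- pmin(pmax(round((p[, 1] - map$x_mm[1]) / map$resolution_mm) + 1, 1),
               length(map$x_mm))
    iy <- pmin(pmax(round((p[, 2] - map$y_mm[1]) / map$resolution_mm) + 1, 1),
               length(map$y_mm))
    th <- map$theta[cbind(ix, iy)]
  } else {
    gx <- (p[, 1] - map$x_mm[1]) / map$resolution_mm + 1
    gy <- (p[, 2] - map$y_mm[1]) / map$resolution_mm + 1
    x0 <- pmin(pmax(floor(gx), 1), length(map$x_mm) - 1)
    y0 <- pmin(pmax(floor(gy), 1), length(map$y_mm) - 1)
    tx <- pmin(pmax(gx - x0, 0), 1); ty <- pmin(pmax(gy - y0, 0), 1)
    z <- exp(2i * map$theta)
    zi <- (1 - tx) * (1 - ty) * z[cbind(x0, y0)] +
      tx * (1 - ty) * z[cbind(x0 + 1, y0)] +
      (1 - tx) * ty * z[cbind(x0, y0 + 1)] +
      tx * ty * z[cbind(x0 + 1, y0 + 1)]
    th <- (Arg(zi) %% (2 * pi)) / 2
  }
  th %% pi
}

#' Circular difference between orientation preferences
#'
#' Orientations live on `[0, pi)`; the difference between two preferences is
#' `min(|a - b|, pi - |a - b|)`, in `[0, pi/2]`.
#'
#' @param a,b orientations in radians.
#' @return circular differences in `[0, pi/2]`.
#' @export
orientation_diff <- function(a, b) {
  d <- abs((a %% pi) - (b %% pi))
  pmin(d, pi - d)
}
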