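#' Drifting-grating stimulus specification
#'
#' Sinusoidal drifting grating confined to a disk or ring (annulus)
#' aperture, on a mean-luminance background.  `diameter_deg` is the disk
#' diameter, or the ring inner diameter; rings additionally carry
#' `outer_diameter_deg`.  A zero-diameter disk is a blank (uniform grey)
#' screen; a zero-inner-diameter ring is the solid disk of the outer
#' diameter.
#'
#' @param shape `"disk"`, `"ring"`, `"blank"` or `"full_field"`.
#' @param diameter_deg disk diameter or ring inner diameter (deg, >= 0).
#' @param outer_diameter_deg ring outer diameter (deg, > inner; rings only).
#' @param orientation_rad grating orientation in `[0, pi)`.
#' @param spatial_freq_cpd spatial frequency (cycles/degree, default 0.8,
#'   matching the thalamocortical Gabor frequency).
#' @param temporal_freq_hz drift temporal frequency (Hz, default 2).
#' @param contrast Michelson contrast in `[0, 1]`.
#' @param duration_ms stimulus duration (ms).
#' @return list of class `"stimulus_spec"`.
#' @export
stimulus_spec <- function(shape = c("disk", "ring", "blank", "full_field"),
                          diameter_deg = 0, outer_diameter_deg = NA,
                          orientation_rad = 0, spatial_freq_cpd = 0.8,
                          temporal_freq_hz = 2, contrast = 1,
                          duration_ms = 1500) {
  shape <- match.arg(shape)
  stopifnot(diameter_deg >= 0, contrast >= 0, contrast <= 1,
            spatial_freq_cpd > 0, temporal_freq_hz >= 0, duration_ms > 0)
  if (shape == "ring") {
    if (!is.finite(outer_diameter_deg) || outer_diameter_deg <= diameter_deg)
      stop("ring outer diameter must exceed the inner diameter")
  }
  structure(list(shape = shape, diameter_deg = diameter_deg,
                 outer_diameter_deg = outer_diameter_deg,
                 orientation_rad = orientation_rad %% pi,
                 spatial_freq_cpd = spatial_freq_cpd,
                 temporal_freq_hz = temporal_freq_hz, contrast = contrast,
                 duration_ms = duration_ms),
            class = "stimulus_spec")
}

#' Render a stimulus specification as a space-time contrast movie
#'
#' Frames hold luminance contrast (fraction of mean luminance, in
#' `[-1, 1]`); outside the aperture the contrast is 0 (mean luminance).
#' Apertures use the strict-inequality convention `r < d/2`, so a disk of
#' diameter d and the ring with inner diameter d tile the full outer disk
#' exactly, pixel for pixel.
#'
#' @param spec a [stimulus_spec()].
#' @param field_extent_deg width of the square field (deg); the field is
#'   centred on 0.
#' @param pixel_deg pixel size (deg, default 0.05).
#' @param frame_dt_ms frame step (ms, default 5); the LGN front-end
#'   interpolates to the simulation step.
#' @param phase0_rad spatial phase of the grating at t = 0.
#' @return list of class `"stimulus_movie"`: `frames` (pixels x pixels x
#'   frames array, x indexing rows), `x_deg`, `y_deg`, `pixel_deg`,
#'   `frame_dt_ms`.
#' @export
make_grating_movie <- function(spec, field_extent_deg = 6, pixel_deg = 0.05,
                               frame_dt_ms = 5, phase0_rad = 0) {
  stopifnot(inherits(spec, "stimulus_spec"), field_extent_deg > 0,
            pixel_deg > 0, frame_dt_ms > 0)
  n <- as.integer(round(field_extent_deg / pixel_deg))
  x <- (seq_len(n) - (n + 1) / 2) * pixel_deg
  y <- x
  nt <- as.integer(ceiling(spec$duration_ms / frame_dt_ms))
  r <- sqrt(outer(x^2, y^2, "+"))
  mask <- switch(spec$shape,
    blank = matrix(FALSE, n, n),
    full_field = matrix(TRUE, n, n),
    disk = r < spec$diameter_deg / 2,
    ring = r < spec$outer_diameter_deg / 2 & !(r < spec$diameter_deg / 2))
  frames <- array(0, dim = c(n, n, nt))
  if (any(mask) && spec$contrast > 0) {
    xp <- outer(x * cos(spec$orientation_rad), y * sin(spec$orientation_rad),
                "+")
    spatial <- 2 * pi * spec$spatial_freq_cpd * xp + phase0_rad
    for (ti in seq_len(nt)) {
      ph <- 2 * pi * spec$temporal_freq_hz * (ti - 1) * frame_dt_ms / 1000
      fr <- spec$contrast * sin(spatial - ph)
      fr[!mask] <- 0
      frames[, , ti] <- fr
    }
  }
  structure(list(frames = frames, x_deg = x, y_deg = y,
                 pixel_deg = pixel_deg, frame_dt_ms = frame_dt_ms,
                 field_extent_deg = field_extent_deg, spec = spec),
            class = "stimulus_movie")
}
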