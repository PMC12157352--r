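#' Default LGN front-end parameters
#'
#' Centre-surround (difference-of-Gaussians) spatial filter, biphasic
#' temporal kernel, and leaky integrate-and-fire parameters for the LGN
#' relay cells.  These values are documented package defaults (typical for
#' cat X-type geniculate cells), not quantities constrained by the cortical
#' model: the centre width is chosen so the cells respond well at the
#' 0.8 cycles/degree protocol grating, and `noise_sd` is calibrated (see
#' [calibrate_lgn_noise()]) so the blank-stimulus firing rate matches
#' `baseline_target_hz`.
#'
#' @param sigma_center_deg,sigma_surround_deg DoG widths (deg).
#' @param surround_gain surround/centre volume ratio (< 1).
#' @param current_gain_na drive current for a full-contrast uniform step
#'   through the centre mechanism (nA).
#' @param tau_fast_ms,tau_slow_ms,slow_weight biphasic temporal kernel:
#'   difference of two unit-area alpha functions, the slow one weighted by
#'   `slow_weight` (transient emphasis; DC gain `1 - slow_weight`).
#' @param tau_m,r_mohm,e_l,v_thr,v_reset,t_ref_ms LIF membrane parameters.
#' @param noise_sd SD of the injected Gaussian noise current (nA sqrt(ms)).
#' @param baseline_target_hz target spontaneous rate under a blank screen.
#' @return parameter list.
#' @export
lgn_params <- function(sigma_center_deg = 0.15, sigma_surround_deg = 0.45,
                       surround_gain = 0.85, current_gain_na = 0.45,
                       tau_fast_ms = 12, tau_slow_ms = 24, slow_weight = 0.6,
                       tau_m = 10, r_mohm = 100, e_l = -70, v_thr = -55,
                       v_reset = -65, t_ref_ms = 2, noise_sd = 0.343,
                       baseline_target_hz = 10) {
  stopifnot(sigma_center_deg < sigma_surround_deg)
  as.list(environment())
}

#' Mosaic of ON and OFF LGN relay cells
#'
#' Two interleaved jittered grids of ON and OFF cells tiling the square
#' visual field.
#'
#' @param n_cells total cell count (default 14400).
#' @param field_extent_deg field width (deg, centred on 0; default 6).
#' @param on_fraction fraction of ON cells (default 0.5).
#' @param jitter_frac positional jitter as a fraction of the grid spacing.
#' @param seed RNG seed.
#' @return data.frame: `cell`, `x_deg`, `y_deg`, `polarity` ("ON"/"OFF").
#' @export
lgn_mosaic <- function(n_cells = 14400, field_extent_deg = 6,
                       on_fraction = 0.5, jitter_frac = 0.25, seed = 1) {
  set.seed(seed)
  n_on <- round(n_cells * on_fraction)
  counts <- c(ON = n_on, OFF = n_cells - n_on)
  half <- field_extent_deg / 2
  pos <- lapply(names(counts), function(pol) {
    np <- counts[[pol]]
    m <- ceiling(sqrt(np))
    sp <- field_extent_deg / m
    g <- expand.grid(x = (seq_len(m) - (m + 1) / 2) * sp,
                     y = (seq_len(m) - (m + 1) / 2) * sp)
    g <- g[seq_len(np), ]
    g$x <- pmin(pmax(g$x + stats::runif(np, -1, 1) * jitter_frac * sp, -half), half)
    g$y <- pmin(pmax(g$y + stats::runif(np, -1, 1) * jitter_frac * sp, -half), half)
    # OFF grid offset by half a spacing to interleave the mosaics
    if (pol == "OFF") {
      g$x <- pmin(pmax(g$x + sp / 2, -half), half)
      g$y <- pmin(pmax(g$y + sp / 2, -half), half)
    }
    data.frame(x_deg = g$x, y_deg = g$y, polarity = pol)
  })
  out <- do.call(rbind, pos)
  out <- cbind(cell = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

# sparse DoG spatial weight matrix (cells x pixels); rows integrate to
# (1 - surround_gain) for a unit-contrast full-field stimulus
lgn_spatial_weights <- function(movie, cells, params, support_sigmas = 3.5) {
  px <- movie$x_deg; py <- movie$y_deg
  np <- length(px) * length(py)
  sc <- params$sigma_center_deg; ss <- params$sigma_surround_deg
  rmax <- support_sigmas * ss
  area <- movie$pixel_deg^2
  ii <- list(); jj <- list(); vv <- list()
  for (ci in seq_len(nrow(cells))) {
    xi <- which(abs(px - cells$x_deg[ci]) <= rmax)
    yi <- which(abs(py - cells$y_deg[ci]) <= rmax)
    if (!length(xi) || !length(yi)) next
    dx2 <- (px[xi] - cells$x_deg[ci])^2
    dy2 <- (py[yi] - cells$y_deg[ci])^2
    r2 <- outer(dx2, dy2, "+")
    w <- exp(-r2 / (2 * sc^2)) / (2 * pi * sc^2) -
      params$surround_gain * exp(-r2 / (2 * ss^2)) / (2 * pi * ss^2)
    # pixel linear index: row-major over (x, y) grid as stored in frames
    pix <- outer(xi, (yi - 1) * length(px), "+")
    ii[[ci]] <- rep.int(ci, length(pix))
    jj[[ci]] <- as.integer(pix)
    vv[[ci]] <- as.numeric(w) * area
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(nrow(cells), np))
}

# biphasic temporal kernel sampled at the movie frame step; unit-area fast
# alpha function minus slow_weight times a unit-area slow alpha function
lgn_temporal_kernel <- function(params, frame_dt_ms, length_ms = 200) {
  t <- seq(0, length_ms, by = frame_dt_ms)
  alpha <- function(tau) {
    k <- t / tau^2 * exp(-t / tau)
    k / sum(k * frame_dt_ms)
  }
  (alpha(params$tau_fast_ms) - params$slow_weight *
      alpha(params$tau_slow_ms)) * frame_dt_ms
}

#' Receptive-field drive currents for a set of LGN cells
#'
#' Space-time convolution of each cell's centre-surround receptive field
#' (DoG spatial filter times a biphasic temporal kernel) with a stimulus
#' movie, at movie frame resolution.  OFF cells receive the negated filter.
#'
#' @param movie a [make_grating_movie()] result.
#' @param cells an [lgn_mosaic()] data.frame (must lie within the movie).
#' @param params [lgn_params()].
#' @param weights optional precomputed spatial weight matrix (cells x
#'   pixels) from an earlier call on the same movie geometry; avoids
#'   rebuilding it for every stimulus condition.
#' @return matrix of drive currents (nA), cells x frames, with the weight
#'   matrix attached as attribute `weights` for reuse.
#' @export
lgn_drive_set <- function(movie, cells, params = lgn_params(),
                          weights = NULL) {
  half <- movie$field_extent_deg / 2
  if (any(abs(cells$x_deg) > half | abs(cells$y_deg) > half))
    stop("cell position outside the movie extent")
  W <- if (is.null(weights)) lgn_spatial_weights(movie, cells, params)
       else weights
  nt <- dim(movie$frames)[3]
  Fm <- matrix(movie$frames, ncol = nt)
  spat <- as.matrix(W %*% Fm)
  k <- lgn_temporal_kernel(params, movie$frame_dt_ms)
  # causal convolution of every row with the kernel, via FFT along time
  npad <- stats::nextn(nt + length(k) - 1)
  K <- stats::fft(c(k, numeric(npad - length(k))))
  S <- stats::mvfft(rbind(t(spat), matrix(0, npad - nt, nrow(spat))))
  drv <- t(Re(stats::mvfft(S * K, inverse = TRUE))[seq_len(nt), , drop = FALSE] / npad)
  sign <- ifelse(cells$polarity == "OFF", -1, 1)
  structure(params$current_gain_na / (1 - params$surround_gain) * drv * sign,
            weights = W)
}

#' Drive current for a single LGN cell
#'
#' Convenience wrapper around [lgn_drive_set()] for one receptive field,
#' resampled to the integration step.
#'
#' @param movie a [make_grating_movie()] result.
#' @param x_deg,y_deg receptive-field centre (deg).
#' @param polarity `"ON"` or `"OFF"`.
#' @param params [lgn_params()].
#' @param dt_ms output sampling step (ms); linear interpolation between
#'   movie frames.
#' @return numeric current trace (nA).
#' @export
dog_drive <- function(movie, x_deg, y_deg, polarity = "ON",
                      params = lgn_params(), dt_ms = 0.1) {
  cells <- data.frame(cell = 1L, x_deg = x_deg, y_deg = y_deg,
                      polarity = polarity)
  drv <- lgn_drive_set(movie, cells, params)[1, ]
  nt <- length(drv)
  t_frames <- (seq_len(nt) - 1) * movie$frame_dt_ms
  t_out <- seq(0, t_frames[nt], by = dt_ms)
  stats::approx(t_frames, drv, xout = t_out)$y
}

#' Simulate the LGN relay population
#'
#' Integrates every cell as a leaky integrate-and-fire unit driven by its
#' receptive-field current plus Gaussian noise (the noise is what produces
#' the spontaneous baseline rate).
#'
#' @param drives cells x frames drive matrix from [lgn_drive_set()] (may be
#'   all zeros for a blank).
#' @param frame_dt_ms frame step of `drives` (ms).
#' @param duration_ms simulated time (ms).
#' @param params [lgn_params()].
#' @param dt_ms integration step (ms, default 0.1).
#' @param seed RNG seed (reproducible given the seed).
#' @return list: `spikes` (list of spike-time vectors, ms, one per cell),
#'   `n_cells`, `duration_ms`.
#' @export
simulate_lgn <- function(drives, frame_dt_ms, duration_ms,
                         params = lgn_params(), dt_ms = 0.1, seed = 1) {
  set.seed(seed)
  n_steps <- as.integer(round(duration_ms / dt_ms))
  res <- lif_population_cpp(drives, frame_dt_ms, dt_ms, n_steps,
                            params$tau_m, params$r_mohm, params$e_l,
                            params$v_thr, params$v_reset, params$t_ref_ms,
                            params$noise_sd)
  spk <- split(res$step * dt_ms, factor(res$cell, levels = seq_len(nrow(drives))))
  list(spikes = unname(spk), n_cells = nrow(drives),
       duration_ms = duration_ms)
}

#' Calibrate the LGN noise current against the target baseline rate
#'
#' Root-finds the noise SD so the blank-stimulus population rate matches
#' `params$baseline_target_hz`.
#'
#' @param params [lgn_params()].
#' @param n_cells cells used for the Monte-Carlo estimate.
#' @param duration_ms simulated time per evaluation.
#' @param seed RNG seed.
#' @param tol acceptable rate error (Hz).
#' @return a copy of `params` with `noise_sd` replaced by the calibrated
#'   value (attribute `achieved_hz` records the fitted rate).
#' @export
calibrate_lgn_noise <- function(params = lgn_params(), n_cells = 200,
                                duration_ms = 3000, seed = 1, tol = 0.5) {
  blank <- matrix(0, n_cells, 4)
  rate_at <- function(sd) {
    p <- params; p$noise_sd <- sd
    sim <- simulate_lgn(blank, frame_dt_ms = duration_ms / 3, duration_ms,
                        p, seed = seed)
    mean(lengths(sim$spikes)) / (duration_ms / 1000)
  }
  f <- function(sd) rate_at(sd) - params$baseline_target_hz
  root <- stats::uniroot(f, c(0.05, 3), tol = 0.01)
  params$noise_sd <- root$root
  attr(params, "achieved_hz") <- root$f.root + params$baseline_target_hz
  params
}
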