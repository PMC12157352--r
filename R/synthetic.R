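#' Ground-truth disk/ring size-tuning profiles
#'
#' Builds a noiseless pair of disk and ring tuning curves with known
#' integration properties.  The disk curve follows a ratio-of-Gaussians
#' size-tuning profile (response to a disk of diameter d is the ratio of the
#' integrated centre Gaussian to 1 plus the integrated surround Gaussian),
#' rescaled so that the peak equals `peak_amp` and the largest-disk response
#' equals exactly `(1 - suppression) * peak_amp`.  The ring curve starts at
#' the largest-disk response (a zero-inner-diameter ring is the largest
#' solid disk) and declines so that the ring matched to the peak disk equals
#' exactly `residual * peak_amp`; with `tiling_linear = TRUE` the rings are
#' instead the exact linear complements `R_i = D_largest - D_i`.
#'
#' @param diameters increasing diameters starting at 0 (visual degrees).
#' @param peak_diameter_deg intended diameter of the peak disk response.
#' @param peak_amp peak disk response amplitude (measure units, e.g. mV).
#' @param suppression fractional drop from peak to largest disk, in [0, 1).
#' @param residual ring response at the peak diameter as a fraction of the
#'   peak disk response (ignored when `tiling_linear`).
#' @param tiling_linear make the cell a perfect linear summator.
#' @return list `D`, `R` (baseline-subtracted responses on the diameter
#'   grid) and `peak_index`.
#' @export
disk_ring_profiles <- function(diameters, peak_diameter_deg, peak_amp,
                               suppression = 0.2, residual = 0.5,
                               tiling_linear = FALSE) {
  stopifnot(diameters[1] == 0, !is.unsorted(diameters),
            suppression >= 0, suppression < 1, peak_amp > 0)
  d <- diameters
  dmax <- d[length(d)]
  if (peak_diameter_deg <= 0 || peak_diameter_deg >= dmax)
    stop("peak diameter must lie strictly inside the diameter range")
  # erf via pnorm
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  rog <- function(dd, wc, beta) erf(dd / wc)^2 / (1 + beta * erf(dd / 2 / wc)^2)
  # choose (wc, beta) so the continuous profile peaks near peak_diameter_deg
  # and its tail matches the requested suppression
  obj <- function(p) {
    wc <- exp(p[1]); beta <- exp(p[2])
    pk <- stats::optimize(function(x) -rog(x, wc, beta),
                          c(1e-3, dmax))$minimum
    v_pk <- rog(pk, wc, beta)
    tail_err <- rog(dmax, wc, beta) / v_pk - (1 - suppression)
    (pk - peak_diameter_deg)^2 / dmax^2 + tail_err^2
  }
  fit <- stats::optim(c(log(peak_diameter_deg / 1.5), log(0.25)), obj)
  wc <- exp(fit$par[1]); beta <- exp(fit$par[2])
  D <- rog(d, wc, beta)
  D <- peak_amp * D / max(D)
  # pin the defining values exactly
  ipk <- which.max(D)
  D[length(D)] <- (1 - suppression) * peak_amp
  D[ipk] <- peak_amp
  if (tiling_linear) {
    R <- D[length(D)] - D
  } else {
    R0 <- D[length(D)]
    r_at_pk <- residual * peak_amp
    if (r_at_pk >= R0) stop("residual*peak exceeds the largest-disk response")
    # monotone interpolation through the anchors (0, R0), (d_pk, r*A), tail
    dp <- d[ipk]
    tail_val <- min(r_at_pk, R0) * 0.2
    R <- stats::approx(c(0, dp, dmax), c(R0, r_at_pk, tail_val), xout = d)$y
  }
  list(D = D, R = R, peak_index = ipk)
}

#' Specification of a synthetic cell
#'
#' @param type `"complex"` (size-tuned sustained depolarisation, VmDC) or
#'   `"simple"` (size-tuned modulation at the fundamental, VmF1).
#' @param peak_diameter_deg,peak_amp_mv,suppression,residual,tiling_linear
#'   passed to [disk_ring_profiles()].
#' @param baseline_mv resting membrane potential (mV).
#' @param noise_sd_mv Gaussian Vm noise SD per sample (0 for noiseless).
#' @param rate_gain_hz_per_mv,rate_threshold_mv threshold-linear link from
#'   (noise-free) Vm to instantaneous firing rate:
#'   `rate = gain * max(0, Vm - (baseline + threshold))`.
#' @param insert_spike_waveforms add a stereotyped 2 ms depolarising
#'   waveform at each generated spike time, to exercise spike removal.
#' @param trials number of trials per condition.
#' @return list of class `"synthetic_cell_spec"`.
#' @export
synthetic_cell_spec <- function(type = c("complex", "simple"),
                                peak_diameter_deg = 1.5, peak_amp_mv = 12,
                                suppression = 0.2, residual = 0.5,
                                tiling_linear = FALSE, baseline_mv = -70,
                                noise_sd_mv = 0, rate_gain_hz_per_mv = 4,
                                rate_threshold_mv = 4,
                                insert_spike_waveforms = FALSE, trials = 10) {
  structure(list(
    type = match.arg(type), peak_diameter_deg = peak_diameter_deg,
    peak_amp_mv = peak_amp_mv, suppression = suppression,
    residual = residual, tiling_linear = tiling_linear,
    baseline_mv = baseline_mv, noise_sd_mv = noise_sd_mv,
    rate_gain_hz_per_mv = rate_gain_hz_per_mv,
    rate_threshold_mv = rate_threshold_mv,
    insert_spike_waveforms = insert_spike_waveforms, trials = trials),
    class = "synthetic_cell_spec")
}

#' Generate a synthetic disks-and-rings recording set with known ground truth
#'
#' Emulates the cyclegram structure of intracellular recordings: per
#' condition and trial, Vm is baseline + the condition's tuned DC offset
#' (complex cells) or a tuned sinusoid at the stimulus fundamental (simple
#' cells), plus Gaussian noise and optionally inserted spike waveforms.
#' Spike trains are drawn as an inhomogeneous Poisson process from a
#' threshold-linear function of the noise-free Vm.  The generative tuning
#' curves and their exact integration metrics are attached as attribute
#' `truth`, so the whole analysis chain can be validated against them.
#'
#' @param spec a [synthetic_cell_spec()].
#' @param diameters disk-diameter grid (deg), starting at 0.
#' @param period_ms,duration_ms,dt_ms protocol timing (defaults: 500 ms
#'   cycle, 1500 ms trials, 1 ms sampling).
#' @param seed RNG seed (the generator is fully reproducible).
#' @return a [sim_records()] object with one cell; attribute `truth` holds
#'   the noiseless [size_tuning_curve()] and its SI/residual/NLI/mean-LI.
#' @export
generate_synthetic_records <- function(spec, diameters = c(0, 0.5, 1, 1.5,
                                                           2, 3, 4, 6),
                                       period_ms = 500, duration_ms = 1500,
                                       dt_ms = 1, seed = 1) {
  stopifnot(inherits(spec, "synthetic_cell_spec"), diameters[1] == 0)
  prof <- disk_ring_profiles(diameters, spec$peak_diameter_deg,
                             spec$peak_amp_mv, spec$suppression,
                             spec$residual, spec$tiling_linear)
  nd <- length(diameters)
  protocol <- rbind(
    data.frame(cond = seq_len(nd), shape = "disk", size_deg = diameters,
               outer_deg = NA_real_),
    data.frame(cond = nd + seq_len(nd - 1L), shape = "ring",
               size_deg = diameters[-1],
               outer_deg = diameters[nd]))
  amps <- c(prof$D, prof$R[-1])  # ring inner 0 == largest disk, not re-made
  n <- as.integer(duration_ms / dt_ms)
  t_ms <- (seq_len(n) - 1) * dt_ms
  mod <- sin(2 * pi * t_ms / period_ms)
  set.seed(seed)
  vm <- vector("list", nrow(protocol))
  spikes <- vector("list", nrow(protocol))
  wave_len <- max(2L, as.integer(round(2 / dt_ms)))
  for (ci in seq_len(nrow(protocol))) {
    a <- amps[ci]
    clean <- spec$baseline_mv +
      if (spec$type == "complex") rep(a, n) else a * mod
    rate_hz <- spec$rate_gain_hz_per_mv *
      pmax(0, clean - (spec$baseline_mv + spec$rate_threshold_mv))
    vm[[ci]] <- vector("list", spec$trials)
    spikes[[ci]] <- vector("list", spec$trials)
    for (tr in seq_len(spec$trials)) {
      v <- clean + if (spec$noise_sd_mv > 0)
        stats::rnorm(n, 0, spec$noise_sd_mv) else 0
      spk <- t_ms[stats::runif(n) < rate_hz * dt_ms / 1000]
      if (spec$insert_spike_waveforms && length(spk)) {
        for (s in spk) {
          i0 <- as.integer(s / dt_ms) + 1L
          idx <- i0:min(n, i0 + wave_len)
          v[idx] <- v[idx] + 40 * rev(seq_along(idx)) / length(idx)
        }
      }
      vm[[ci]][[tr]] <- matrix(v, ncol = 1)
      spikes[[ci]][[tr]] <- list(spk)
    }
  }
  truth_curve <- size_tuning_curve(
    diameters, spec$baseline_mv + prof$D,
    spec$baseline_mv + prof$R, baseline = spec$baseline_mv,
    measure = if (spec$type == "complex") "VmDC" else "VmF1")
  truth <- list(
    curve = truth_curve,
    SI = as.numeric(suppression_index(truth_curve)),
    residual = as.numeric(residual_index(truth_curve)),
    NLI = as.numeric(nonlinearity_index(truth_curve)),
    mean_LI = linearity_index(truth_curve)$mean)
  rec <- sim_records(
    protocol = protocol,
    cells = data.frame(cell = 1L, layer = NA, cell_class = spec$type,
                       ecc_deg = 0),
    vm = vm, spikes = spikes, vm_dt_ms = dt_ms, duration_ms = duration_ms,
    period_ms = period_ms,
    meta = list(origin = "synthetic", seed = seed, spec = unclass(spec)))
  attr(rec, "truth") <- truth
  rec
}
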