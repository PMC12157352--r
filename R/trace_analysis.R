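#' Remove action potentials from a membrane-potential trace
#'
#' Replaces each spike by a linear interpolation of the subthreshold
#' trajectory and then smooths with a five-point running average, so that
#' cyclegram measures (VmDC, VmF1, VmSD) reflect synaptic input rather than
#' spike waveforms.
#'
#' Two detection conventions are supported:
#' \describe{
#'   \item{`"onset"`}{for experimental-style traces: spike onset is the first
#'     sample at which dV/dt exceeds `dvdt_thresh`; Vm is interpolated from
#'     the onset value to the first sample after the peak at which the trace
#'     repolarises back below the onset value.}
#'   \item{`"window"`}{for model traces with known spike times (integrate-and-
#'     fire reset transients): Vm is interpolated across a fixed window of
#'     `window_ms` around each spike time.}
#' }
#'
#' @param vm numeric Vm trace (mV), evenly sampled.
#' @param dt_ms sampling step in ms.
#' @param method `"onset"` or `"window"`.
#' @param spike_times_ms spike times (ms, relative to the first sample) for
#'   `method = "window"`.
#' @param dvdt_thresh onset detection threshold in mV/ms (default 10).
#' @param window_ms interpolation window for `method = "window"` (default 2).
#' @param max_spike_ms longest credible spike for `method = "onset"`: if the
#'   trace has not repolarised below the onset value within this window
#'   (e.g. the subthreshold Vm is rising through the spike), interpolation
#'   ends at the post-peak minimum inside the window instead (default 5).
#' @param smooth apply the five-point running average (default TRUE).
#' @return cleaned Vm trace, same length as the input.
#' @export
remove_spikes <- function(vm, dt_ms, method = c("onset", "window"),
                          spike_times_ms = NULL, dvdt_thresh = 10,
                          window_ms = 2, smooth = TRUE, max_spike_ms = 5) {
  method <- match.arg(method)
  n <- length(vm)
  if (n < 5) stop("trace shorter than the smoothing window")
  out <- vm
  if (method == "onset") {
    dv <- c(0, diff(vm)) / dt_ms
    i <- 2L
    while (i <= n) {
      if (dv[i] > dvdt_thresh) {
        on <- i - 1L
        v_on <- vm[on]
        # ride to the peak, then find repolarisation below the onset value
        j <- i
        while (j < n && vm[j + 1L] >= vm[j]) j <- j + 1L
        lim <- min(n, on + as.integer(ceiling(max_spike_ms / dt_ms)))
        k <- j
        while (k < lim && vm[k] > v_on) k <- k + 1L
        if (vm[k] > v_on && k > j)  # no recross: end at the post-peak minimum
          k <- j + which.min(vm[j:lim]) - 1L
        idx <- on:k
        out[idx] <- seq(vm[on], vm[k], length.out = length(idx))
        i <- k + 1L
      } else i <- i + 1L
    }
  } else {
    if (is.null(spike_times_ms)) stop("method='window' needs spike_times_ms")
    half <- window_ms / dt_ms
    for (t in spike_times_ms) {
      a <- max(1L, floor(t / dt_ms) - 1L)
      b <- min(n, ceiling(t / dt_ms + half) + 1L)
      idx <- a:b
      out[idx] <- seq(out[a], out[b], length.out = length(idx))
    }
  }
  if (smooth) out <- running_mean5(out)
  out
}

# five-point running average with shrinking windows at the edges
running_mean5 <- function(x) {
  n <- length(x)
  sm <- stats::filter(x, rep(1 / 5, 5), sides = 2)
  sm <- as.numeric(sm)
  for (i in c(1L, 2L, n - 1L, n)) {
    idx <- max(1L, i - 2L):min(n, i + 2L)
    sm[i] <- mean(x[idx])
  }
  sm
}

#' Cycle-averaged response (cyclegram) from a Vm trace and/or spike train
#'
#' Cuts the analysis window into complete stimulus cycles, averages the Vm
#' over cycles (and trials), and accumulates spikes into a peristimulus
#' histogram over one cycle.  Partial cycles are discarded.
#'
#' @param vm a numeric Vm trace, or a list of per-trial traces, or `NULL`.
#' @param spikes numeric spike times (ms), or a list of per-trial spike-time
#'   vectors, or `NULL`.
#' @param period_ms stimulus temporal period (ms).
#' @param dt_ms Vm sampling step (ms); `period_ms` must be a multiple.
#' @param t_start_ms start of the analysis window (ms from trace onset);
#'   earlier samples (onset transient) are dropped.
#' @param duration_ms total trace duration (ms); defaults to the Vm length.
#' @param n_bins PSTH bins per cycle (default 64).
#' @return object of class `"cyclegram"`: `vm` (cycle-averaged trace),
#'   `segments` (samples x cycles matrix of single-cycle Vm), `psth`
#'   (rate in Hz per bin), `n_cycles`, `n_trials`, plus the timing fields.
#' @export
build_cyclegram <- function(vm = NULL, spikes = NULL, period_ms, dt_ms = 1,
                            t_start_ms = 0, duration_ms = NULL, n_bins = 64) {
  if (is.null(vm) && is.null(spikes)) stop("need vm and/or spikes")
  if (!is.null(vm) && !is.list(vm)) vm <- list(vm)
  if (!is.null(spikes) && !is.list(spikes)) spikes <- list(spikes)
  n_trials <- max(length(vm), length(spikes))
  if (is.null(duration_ms))
    duration_ms <- if (!is.null(vm)) length(vm[[1]]) * dt_ms else
      stop("duration_ms required when only spikes are given")
  spp <- period_ms / dt_ms
  if (abs(spp - round(spp)) > 1e-9) stop("period must be a multiple of dt")
  spp <- as.integer(round(spp))
  n_cyc <- floor((duration_ms - t_start_ms) / period_ms + 1e-9)
  if (n_cyc < 1) stop("analysis window contains no complete cycle")
  segments <- NULL
  if (!is.null(vm)) {
    segments <- do.call(cbind, lapply(vm, function(tr) {
      i0 <- as.integer(round(t_start_ms / dt_ms))
      idx <- i0 + seq_len(n_cyc * spp)
      if (max(idx) > length(tr)) stop("trace shorter than duration_ms")
      matrix(tr[idx], nrow = spp)
    }))
  }
  psth <- NULL; n_spk <- 0
  if (!is.null(spikes)) {
    phase <- unlist(lapply(spikes, function(s) {
      s <- s[s >= t_start_ms & s < t_start_ms + n_cyc * period_ms]
      (s - t_start_ms) %% period_ms
    }))
    n_spk <- length(phase)
    cnt <- tabulate(pmin(n_bins, 1L + floor(phase / period_ms * n_bins)),
                    nbins = n_bins)
    # rate in Hz: spikes per bin / (bin width * cycles * trials)
    bin_s <- period_ms / n_bins / 1000
    psth <- cnt / (bin_s * n_cyc * length(spikes))
  }
  structure(list(
    vm = if (is.null(segments)) NULL else rowMeans(segments),
    segments = segments, psth = psth, n_spikes = n_spk,
    period_ms = period_ms, dt_ms = dt_ms, n_bins = n_bins,
    n_cycles = n_cyc, n_trials = n_trials), class = "cyclegram")
}

# least-squares fit of C + A*sin(2*pi*t/T + phi); returns c(dc, amplitude)
sine_fit <- function(y, t, period) {
  w <- 2 * pi / period
  X <- cbind(1, cos(w * t), sin(w * t))
  cf <- unname(stats::lm.fit(X, y)$coefficients)
  c(dc = cf[1], amplitude = sqrt(cf[2]^2 + cf[3]^2))
}

#' Response measures from a cyclegram
#'
#' VmDC is the mean of the cycle-averaged Vm; VmF1 the amplitude of the
#' least-squares sinusoid at the stimulus fundamental fitted to the averaged
#' cyclegram (phase free); MFR the mean firing rate (spikes per cycle over
#' cycle duration); spikesF1 the amplitude of the sinusoid fitted to the
#' PSTH cyclegram.
#'
#' @param cg a [build_cyclegram()] result.
#' @return named list: `VmDC`, `VmF1` (mV, `NA` without Vm), `MFR`,
#'   `spikesF1` (Hz, `NA` without spikes).
#' @export
quantify_cyclegram <- function(cg) {
  stopifnot(inherits(cg, "cyclegram"))
  out <- list(VmDC = NA_real_, VmF1 = NA_real_,
              MFR = NA_real_, spikesF1 = NA_real_)
  if (!is.null(cg$vm)) {
    t <- (seq_along(cg$vm) - 1) * cg$dt_ms
    f <- sine_fit(cg$vm, t, cg$period_ms)
    out$VmDC <- f[["dc"]]
    out$VmF1 <- f[["amplitude"]]
  }
  if (!is.null(cg$psth)) {
    out$MFR <- cg$n_spikes / (cg$n_cycles * cg$n_trials) /
      (cg$period_ms / 1000)
    tb <- (seq_len(cg$n_bins) - 0.5) * cg$period_ms / cg$n_bins
    out$spikesF1 <- sine_fit(cg$psth, tb, cg$period_ms)[["amplitude"]]
  }
  out
}

#' Trial-to-trial Vm standard deviation (synaptic-noise proxy)
#'
#' Two conventions:
#' \describe{
#'   \item{`"three_part"`}{each single-trial cycle segment is divided into
#'     three equal parts; the SD is computed on each part, averaged over the
#'     three, then over trials/cycles.}
#'   \item{`"sliding_100ms"`}{the mean of SDs computed in a 100 ms sliding
#'     window over the course of each trace, averaged over traces.}
#' }
#' With `f1_subtract = TRUE` (the convention for simple cells, whose Vm is
#' strongly modulated at the fundamental) the fitted fundamental sinusoid is
#' removed from each segment first.
#'
#' @param segments samples x trials (or cycles) matrix of single-trial Vm
#'   segments; for `three_part` each column is one cycle, for
#'   `sliding_100ms` each column is a trace of any length >= the window.
#' @param dt_ms sampling step (ms).
#' @param mode `"three_part"` or `"sliding_100ms"`.
#' @param f1_subtract remove the fitted fundamental before computing SDs.
#' @param period_ms stimulus period, required when `f1_subtract = TRUE`.
#' @param window_ms sliding-window length (default 100).
#' @return VmSD in mV.
#' @export
vm_sd <- function(segments, dt_ms, mode = c("three_part", "sliding_100ms"),
                  f1_subtract = FALSE, period_ms = NULL, window_ms = 100) {
  mode <- match.arg(mode)
  segments <- as.matrix(segments)
  n <- nrow(segments)
  if (f1_subtract) {
    if (is.null(period_ms)) stop("period_ms required for f1_subtract")
    t <- (seq_len(n) - 1) * dt_ms
    w <- 2 * pi / period_ms
    X <- cbind(1, cos(w * t), sin(w * t))
    segments <- apply(segments, 2, function(y) stats::lm.fit(X, y)$residuals)
  }
  if (mode == "three_part") {
    if (n < 3) stop("segment too short to divide in three")
    part <- rep(1:3, times = diff(floor(n * 0:3 / 3)))
    mean(apply(segments, 2, function(y) mean(tapply(y, part, stats::sd))))
  } else {
    wlen <- as.integer(round(window_ms / dt_ms))
    if (n < wlen) stop("segment shorter than the sliding window")
    mean(apply(segments, 2, function(y) {
      # running SD via cumulative sums
      c1 <- cumsum(y); c2 <- cumsum(y^2)
      s1 <- c1[wlen:n] - c(0, c1)[seq_len(n - wlen + 1L)]
      s2 <- c2[wlen:n] - c(0, c2)[seq_len(n - wlen + 1L)]
      v <- (s2 - s1^2 / wlen) / (wlen - 1)
      mean(sqrt(pmax(v, 0)))
    }))
  }
}

#' Classify a cell as simple or complex from its modulation ratio
#'
#' A cell is simple when its spiking response at the stimulus fundamental
#' (spikes F1) exceeds its mean rate (F0), complex otherwise.  Simple cells
#' whose mean Vm depolarisation exceeds their Vm fundamental amplitude are
#' flagged for exclusion (their subthreshold behaviour contradicts the
#' spiking classification).
#'
#' @param spikes_f1 F1 amplitude of the spike response (Hz).
#' @param mfr mean firing rate (Hz).
#' @param vm_dc_depol mean Vm depolarisation from rest (mV), optional.
#' @param vm_f1 Vm F1 amplitude (mV), optional.
#' @return list: `class` ("simple", "complex", or `NA` when unclassifiable),
#'   `excluded` (logical), `reason`.
#' @export
classify_cell <- function(spikes_f1, mfr, vm_dc_depol = NA, vm_f1 = NA) {
  if (!is.finite(mfr) || (mfr == 0 && (!is.finite(spikes_f1) || spikes_f1 == 0)))
    return(list(class = NA_character_, excluded = TRUE,
                reason = "no spikes: unclassifiable"))
  cls <- if (spikes_f1 > mfr) "simple" else "complex"
  excl <- FALSE; reason <- ""
  if (cls == "simple" && is.finite(vm_dc_depol) && is.finite(vm_f1) &&
      vm_dc_depol > vm_f1) {
    excl <- TRUE
    reason <- "simple cell with Vm depolarisation exceeding its F1 component"
  }
  list(class = cls, excluded = excl, reason = reason)
}

#' Select cells for population analysis
#'
#' Keeps cells whose receptive-field position lies within `max_ecc_deg` of
#' the stimulus centre and whose mean firing rate exceeds `min_rate_hz`
#' (strict inequality) for at least one disk condition.
#'
#' @param cells data.frame with columns `cell` (id), `ecc_deg` (eccentricity
#'   of the RF centre, visual degrees) and `max_disk_rate_hz` (maximum over
#'   disk conditions of the trial-averaged firing rate).
#' @param max_ecc_deg eccentricity cut (default 0.4 deg).
#' @param min_rate_hz rate cut (default 1 spike/s).
#' @return the selected subset, with an attribute `excluded` recording the
#'   dropped cells and the reason.
#' @export
select_cells <- function(cells, max_ecc_deg = 0.4, min_rate_hz = 1) {
  stopifnot(all(c("cell", "ecc_deg", "max_disk_rate_hz") %in% names(cells)))
  far <- cells$ecc_deg > max_ecc_deg
  quiet <- !far & cells$max_disk_rate_hz <= min_rate_hz
  keep <- !far & !quiet
  excluded <- data.frame(
    cell = cells$cell[!keep],
    reason = ifelse(far[!keep], "outside eccentricity window",
                    "max disk rate at or below threshold"))
  structure(cells[keep, , drop = FALSE], excluded = excluded)
}
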