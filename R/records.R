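#' Recording container for one disks-and-rings protocol
#'
#' Common container emitted by both the network simulator and the synthetic
#' trace generator, and consumed by the analysis chain, so the analysis code
#' is agnostic to data origin.
#'
#' @param protocol data.frame with one row per stimulus condition: `cond`
#'   (id), `shape` (`"disk"`, `"ring"`, `"blank"`), `size_deg` (disk diameter
#'   or ring inner diameter), `outer_deg` (ring outer diameter, `NA` for
#'   disks).
#' @param cells data.frame describing recorded cells: `cell` (id), plus any
#'   of `layer`, `cell_class`, `ecc_deg`, `pref_or`.
#' @param vm nested list: `vm[[cond]][[trial]]` is a samples x cells matrix
#'   of membrane potential (mV) at `vm_dt_ms` resolution.
#' @param spikes nested list: `spikes[[cond]][[trial]][[cell]]` is a vector
#'   of spike times (ms from stimulus onset).
#' @param vm_dt_ms Vm recording step (ms).
#' @param duration_ms trial duration (ms).
#' @param period_ms stimulus temporal period (ms).
#' @param meta free-form provenance list (seeds, config hash, scale).
#' @return object of class `"sim_records"`.
#' @export
sim_records <- function(protocol, cells, vm, spikes, vm_dt_ms, duration_ms,
                        period_ms, meta = list()) {
  stopifnot(is.data.frame(protocol),
            all(c("cond", "shape", "size_deg") %in% names(protocol)),
            is.data.frame(cells), "cell" %in% names(cells),
            length(vm) == nrow(protocol), length(spikes) == nrow(protocol))
  structure(list(protocol = protocol, cells = cells, vm = vm,
                 spikes = spikes, vm_dt_ms = vm_dt_ms,
                 duration_ms = duration_ms, period_ms = period_ms,
                 meta = meta),
            class = "sim_records")
}

#' @export
print.sim_records <- function(x, ...) {
  cat(sprintf(
    "<sim_records> %d conditions x %d trials, %d cells, %g ms trials (Vm @ %g ms)\n",
    nrow(x$protocol), length(x$vm[[1]]), nrow(x$cells), x$duration_ms,
    x$vm_dt_ms))
  invisible(x)
}

#' Per-cell, per-condition response measures from a recording set
#'
#' For every condition and recorded cell: removes spikes from each trial's
#' Vm, builds the trial-averaged cyclegram and PSTH over the analysis window,
#' and extracts VmDC, VmF1, VmSD (with and without subtraction of the
#' fundamental), mean firing rate, and spikes F1.
#'
#' @param records a [sim_records()] object.
#' @param discard_ms onset transient dropped from each trial before cycle
#'   averaging (default 500 ms).
#' @param n_bins PSTH bins per cycle.
#' @param vmsd_mode `"three_part"` (per-cycle thirds) or `"sliding_100ms"`.
#' @param spike_removal `"window"` (model traces, interpolate the reset
#'   transient) or `"onset"` (dV/dt detection) or `"none"`.
#' @return data.frame with columns cond, cell, VmDC, VmF1, VmSD, VmSD_f1sub,
#'   MFR, spikesF1.
#' @export
measure_protocol <- function(records, discard_ms = 500, n_bins = 64,
                             vmsd_mode = "three_part",
                             spike_removal = "window") {
  stopifnot(inherits(records, "sim_records"))
  period <- records$period_ms
  dt <- records$vm_dt_ms
  cells <- records$cells$cell
  out <- vector("list", nrow(records$protocol) * length(cells))
  k <- 0L
  for (ci in seq_len(nrow(records$protocol))) {
    vm_trials <- records$vm[[ci]]
    spk_trials <- records$spikes[[ci]]
    for (j in seq_along(cells)) {
      traces <- lapply(seq_along(vm_trials), function(tr) {
        v <- vm_trials[[tr]][, j]
        if (spike_removal == "none") return(v)
        remove_spikes(v, dt, method = spike_removal,
                      spike_times_ms = spk_trials[[tr]][[j]])
      })
      spk <- lapply(spk_trials, function(s) s[[j]])
      cg <- build_cyclegram(vm = traces, spikes = spk, period_ms = period,
                            dt_ms = dt, t_start_ms = discard_ms,
                            duration_ms = records$duration_ms,
                            n_bins = n_bins)
      q <- quantify_cyclegram(cg)
      seg <- if (vmsd_mode == "three_part") cg$segments else
        do.call(cbind, traces)
      k <- k + 1L
      out[[k]] <- data.frame(
        cond = records$protocol$cond[ci], cell = cells[j],
        VmDC = q$VmDC, VmF1 = q$VmF1,
        VmSD = vm_sd(seg, dt, mode = vmsd_mode),
        VmSD_f1sub = vm_sd(seg, dt, mode = vmsd_mode, f1_subtract = TRUE,
                           period_ms = period),
        MFR = q$MFR, spikesF1 = q$spikesF1)
    }
  }
  do.call(rbind, out)
}

#' Size-tuning curves and integration metrics per cell
#'
#' Assembles matched disk/ring size-tuning curves from a measures table and
#' computes the four spatial-integration indices for each cell.  The blank
#' disk (diameter 0) supplies the baseline; the largest disk doubles as the
#' zero-inner-diameter ring.
#'
#' @param measures output of [measure_protocol()].
#' @param protocol the protocol data.frame of the recording set.
#' @param measure which response measure to analyse (`"VmDC"`, `"VmF1"`,
#'   `"VmSD"`, `"MFR"`, `"spikesF1"`, or `"VmSD_f1sub"`).
#' @return data.frame: cell, SI (percent), residual, NLI, mean_LI (percent),
#'   plus an attribute `curves` (named list of [size_tuning_curve()]s).
#' @export
integration_metrics <- function(measures, protocol, measure = "VmDC") {
  stopifnot(measure %in% names(measures))
  disks <- protocol[protocol$shape %in% c("disk", "blank"), ]
  disks <- disks[order(disks$size_deg), ]
  rings <- protocol[protocol$shape == "ring", ]
  rings <- rings[order(rings$size_deg), ]
  diam <- disks$size_deg
  # degenerate rings reuse disk conditions: inner 0 is the largest solid
  # disk, and inner = outer is an empty aperture (the blank)
  ring_cond <- rings$cond[match(diam, rings$size_deg)]
  ring_cond[1] <- disks$cond[length(diam)]
  if (is.na(ring_cond[length(diam)]) &&
      length(rings) && all(is.na(match(diam[length(diam)], rings$size_deg))))
    ring_cond[length(diam)] <- disks$cond[1]
  if (anyNA(ring_cond))
    stop("protocol lacks rings matching some disk diameters")
  cells <- unique(measures$cell)
  curves <- list()
  rows <- lapply(cells, function(cl) {
    m <- measures[measures$cell == cl, ]
    dv <- m[[measure]][match(disks$cond, m$cond)]
    rv <- m[[measure]][match(ring_cond, m$cond)]
    cv <- size_tuning_curve(diam, dv, rv, baseline = dv[1], measure = measure)
    curves[[as.character(cl)]] <<- cv
    data.frame(cell = cl,
               SI = as.numeric(suppression_index(cv)),
               residual = as.numeric(residual_index(cv)),
               NLI = as.numeric(nonlinearity_index(cv)),
               mean_LI = linearity_index(cv)$mean)
  })
  structure(do.call(rbind, rows), curves = curves)
}
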