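# Flatten a connectome into the CSR arrays the C++ integrator consumes.
# Sources are the N cortical neurons followed by the M LGN cells.
compile_network <- function(con, cfg) {
  pop <- con$populations
  N <- nrow(pop); M <- nrow(con$lgn)
  dt <- cfg$sim$dt_ms
  col <- function(f) unlist(lapply(con$edges, `[[`, f), use.names = FALSE)
  src <- col("src"); tgt <- col("tgt"); w <- col("weight_ns")
  delay <- col("delay_ms"); taur <- col("tau_rec")
  src_global <- ifelse(col("lgn_source"), N + src, src)
  # all outgoing synapses of a source must share one recovery constant
  # (true of the model tables); the integrator keeps one resource state
  # per source
  src_tau <- rep(NA_real_, N + M)
  first <- !duplicated(src_global)
  src_tau[src_global[first]] <- taur[first]
  if (any(src_tau[src_global] != taur))
    stop("per-source recovery constants are not unique")
  src_tau[is.na(src_tau)] <- 30
  ord <- order(src_global)
  is_inh <- pop$cell_class == "inh"
  pars <- function(f) ifelse(is_inh, cfg$neuron$inh[[f]], cfg$neuron$exc[[f]])
  list(
    n_neurons = N, n_ext = M,
    tau_m = pars("tau_m"), r_mohm = pars("r_mohm"), e_l = pars("e_l"),
    v_t = pars("v_t"),
    t_ref_steps = as.integer(ceiling(pars("t_ref") / dt)),
    out_ptr = c(0L, cumsum(tabulate(src_global, nbins = N + M))),
    syn_tgt = as.integer(tgt[ord]) - 1L,
    syn_w = w[ord],
    syn_delay = pmax(1L, as.integer(ceiling(delay[ord] / dt - 1e-9))),
    src_tau_rec = src_tau,
    src_is_inh = c(is_inh, rep(FALSE, M)),
    dt = dt)
}

# One network integration given LGN spike trains (list of ms vectors).
run_network_once <- function(net, cfg, lgn_spikes, duration_ms, record_idx) {
  dt <- net$dt
  n_steps <- as.integer(round(duration_ms / dt))
  steps <- unlist(lapply(lgn_spikes, function(s) as.integer(round(s / dt))))
  srcs <- rep.int(seq_along(lgn_spikes) - 1L, lengths(lgn_spikes))
  keep <- steps < n_steps
  ord <- order(steps[keep])
  res <- eif_network_cpp(
    net$n_neurons, net$tau_m, net$r_mohm, net$e_l, net$v_t, net$t_ref_steps,
    cfg$neuron$delta_t, cfg$neuron$v_spike, cfg$neuron$v_reset,
    cfg$neuron$e_exc, cfg$neuron$e_inh,
    cfg$synapse$tau_exc, cfg$synapse$tau_inh,
    net$out_ptr, net$syn_tgt, net$syn_w, net$syn_delay, net$src_tau_rec,
    net$src_is_inh, cfg$synapse$stp_u,
    steps[keep][ord], srcs[keep][ord],
    dt, n_steps, as.integer(record_idx) - 1L,
    as.integer(round(cfg$sim$vm_record_dt_ms / dt)),
    rep(0, net$n_neurons), rep(0, net$n_neurons),
    net$e_l)
  res
}

#' Build the disks-and-rings stimulus protocol table
#'
#' Disk conditions at every configured diameter (diameter 0 is the blank)
#' and ring conditions at every non-zero inner diameter with the configured
#' outer diameter.  The two degenerate rings are not duplicated as separate
#' conditions: the zero-inner ring is the largest disk, and the ring whose
#' inner diameter equals the outer diameter is an empty aperture (the
#' blank).
#'
#' @param cfg a [model_config()].
#' @return data.frame: `cond`, `shape`, `size_deg`, `outer_deg`.
#' @export
protocol_table <- function(cfg) {
  d <- cfg$protocol$disk_diameters_deg
  outer <- cfg$protocol$ring_outer_deg
  ri <- d[d > 0 & d < outer]
  rbind(
    data.frame(cond = seq_along(d), shape = "disk", size_deg = d,
               outer_deg = NA_real_),
    data.frame(cond = length(d) + seq_along(ri), shape = "ring",
               size_deg = ri, outer_deg = outer))
}

#' Run the disks-and-rings protocol on a connectome
#'
#' For each stimulus condition and trial: renders the grating movie,
#' filters it through the LGN front-end, integrates the cortical network,
#' and records spikes and membrane potential of the cells near the field
#' centre.  The grating orientation is the map orientation at the sheet
#' centre (cells at the centre see their preferred stimulus); trial
#' variability comes from the LGN noise current (trial-specific seeds);
#' the presentation order of condition/trial pairs is shuffled with its own
#' seed and logged (each pair is simulated independently, so the order is
#' bookkeeping, not dynamics).
#'
#' @param con a [build_connectome()].
#' @param cfg the configuration used to build it.
#' @param seed master seed for this protocol run.
#' @param trials trials per condition (default from the config).
#' @param conditions optional subset of condition ids to simulate.
#' @param record_cells optional explicit cortical ids to record; default is
#'   all cells within `cfg$sim$record_ecc_deg` of the field centre.
#' @param progress print one line per simulated condition.
#' @return a [sim_records()] object; `meta` carries seeds, config hash,
#'   presentation order and the per-recorded-cell layer/class table.
#' @export
run_protocol <- function(con, cfg, seed = 1, trials = cfg$protocol$trials,
                         conditions = NULL, record_cells = NULL,
                         progress = FALSE) {
  prot <- protocol_table(cfg)
  if (!is.null(conditions)) prot <- prot[prot$cond %in% conditions, ]
  pop <- con$populations
  if (is.null(record_cells))
    record_cells <- pop$id[pop$ecc_deg <= cfg$sim$record_ecc_deg]
  if (!length(record_cells)) stop("no cells in the recording window")
  net <- compile_network(con, cfg)
  stim_or <- orientation_at(con$map, c(0, 0))
  lp <- cfg$lgn
  lgn_cells <- con$lgn
  dur <- cfg$protocol$duration_ms
  period <- 1000 / cfg$protocol$temporal_freq_hz
  vm <- vector("list", nrow(prot))
  spikes <- vector("list", nrow(prot))
  lgn_W <- NULL  # DoG weight matrix, shared across conditions
  for (i in seq_len(nrow(prot))) {
    row <- prot[i, ]
    spec <- if (row$shape == "disk" && row$size_deg == 0)
      stimulus_spec("blank", duration_ms = dur)
    else stimulus_spec(row$shape, row$size_deg,
                       outer_diameter_deg = row$outer_deg,
                       orientation_rad = stim_or,
                       spatial_freq_cpd = cfg$protocol$spatial_freq_cpd,
                       temporal_freq_hz = cfg$protocol$temporal_freq_hz,
                       contrast = cfg$protocol$contrast, duration_ms = dur)
    movie <- make_grating_movie(spec, cfg$geometry$lgn_field_deg,
                                cfg$protocol$pixel_deg,
                                cfg$protocol$frame_dt_ms)
    drives <- lgn_drive_set(movie, lgn_cells, lp, weights = lgn_W)
    if (is.null(lgn_W)) lgn_W <- attr(drives, "weights")
    vm[[i]] <- vector("list", trials)
    spikes[[i]] <- vector("list", trials)
    for (tr in seq_len(trials)) {
      lgn_dt <- if (is.null(cfg$sim$lgn_dt_ms)) cfg$sim$dt_ms else
        cfg$sim$lgn_dt_ms
      lgn_sim <- simulate_lgn(drives, cfg$protocol$frame_dt_ms, dur, lp,
                              dt_ms = lgn_dt,
                              seed = seed * 997L + row$cond * 89L + tr)
      res <- run_network_once(net, cfg, lgn_sim$spikes, dur, record_cells)
      vm[[i]][[tr]] <- res$vm[, , drop = FALSE]
      spk_ms <- res$step * cfg$sim$dt_ms
      spikes[[i]][[tr]] <- unname(split(
        spk_ms, factor(res$cell, levels = record_cells)))
    }
    if (progress)
      message(sprintf("condition %d/%d (%s %.2f deg) done",
                      i, nrow(prot), row$shape, row$size_deg))
  }
  cells <- pop[match(record_cells, pop$id),
               c("id", "pop", "layer", "cell_class", "ecc_deg", "pref_or")]
  names(cells)[1] <- "cell"
  set.seed(seed + 7L)
  order_tbl <- expand.grid(cond = prot$cond, trial = seq_len(trials))
  sim_records(
    protocol = prot[, c("cond", "shape", "size_deg", "outer_deg")],
    cells = cells, vm = vm, spikes = spikes,
    vm_dt_ms = cfg$sim$vm_record_dt_ms, duration_ms = dur,
    period_ms = period,
    meta = list(seed = seed, config_hash = con$provenance$config_hash,
                scale = con$provenance$scale,
                variant = con$provenance$variant,
                stimulus_orientation = stim_or,
                presentation_order = order_tbl[sample.int(nrow(order_tbl)), ]))
}

#' Tsodyks-Markram released fraction per presynaptic spike
#'
#' Deterministic mean-field short-term depression with fixed utilisation
#' `u`: at each spike the synapse releases `u * x` of its resources, the
#' remainder recovering towards 1 with time constant `tau_rec`.  This is
#' the identical update the network integrator applies per source.
#'
#' @param spike_times_ms increasing presynaptic spike times (ms).
#' @param u utilisation of synaptic resources (default 0.75).
#' @param tau_rec recovery time constant (ms).
#' @return released fraction (conductance increment in units of the
#'   synaptic weight) at each spike.
#' @export
tm_release <- function(spike_times_ms, u = 0.75, tau_rec = 125) {
  stopifnot(!is.unsorted(spike_times_ms))
  tm_release_cpp(as.numeric(spike_times_ms), u, tau_rec)
}

#' Membrane response of a passive cell to one depressing synapse
#'
#' Drives a single (effectively non-spiking) neuron through one synapse
#' receiving a prescribed presynaptic spike train, for validating synaptic
#' integration and short-term depression along the full network code path.
#'
#' @param spike_times_ms presynaptic spike times (ms).
#' @param weight_ns synaptic weight (nS).
#' @param tau_rec recovery constant (ms).
#' @param inhibitory deliver onto the inhibitory conductance.
#' @param stp_u utilisation (0 disables depression).
#' @param duration_ms,dt_ms integration window and step.
#' @param cfg a [model_config()] for membrane/synapse constants.
#' @return list: `vm` (mV at `dt_ms`), `t_ms`.
#' @export
simulate_epsp_train <- function(spike_times_ms, weight_ns = 1, tau_rec = 125,
                                inhibitory = FALSE, stp_u = 0.75,
                                duration_ms = 1000, dt_ms = 0.1,
                                cfg = model_config()) {
  p <- cfg$neuron$exc
  n_steps <- as.integer(round(duration_ms / dt_ms))
  steps <- as.integer(round(spike_times_ms / dt_ms))
  res <- eif_network_cpp(
    1L, p$tau_m, p$r_mohm, p$e_l, 1e6, 1L,
    cfg$neuron$delta_t, 1e6, cfg$neuron$v_reset,  # unreachable threshold
    cfg$neuron$e_exc, cfg$neuron$e_inh,
    cfg$synapse$tau_exc, cfg$synapse$tau_inh,
    c(0L, 0L, 1L), 0L, weight_ns, 1L,
    c(30, tau_rec), c(FALSE, inhibitory), stp_u,
    sort(steps), rep(0L, length(steps)),
    dt_ms, n_steps, 0L, 1L, 0, 0, p$e_l)
  list(vm = res$vm[, 1], t_ms = (seq_len(n_steps) - 1) * dt_ms)
}

#' Simulate a single neuron with constant inputs
#'
#' Integrates one exponential integrate-and-fire neuron (no synapses) under
#' a constant injected current and/or constant excitatory conductance, for
#' f-I curves, rheobase location and integrator checks.
#'
#' @param cell_class `"exc"` or `"inh"`.
#' @param cfg a [model_config()] supplying the membrane parameters.
#' @param i_ext_na constant injected current (nA).
#' @param g_exc_ns constant excitatory conductance (nS).
#' @param duration_ms,dt_ms integration time and step.
#' @param v0 initial potential (default leak).
#' @param delta_t_override threshold slope factor override (mV), e.g. a
#'   tiny value to approach the leaky integrate-and-fire limit.
#' @return list: `spike_times_ms`, `vm` (at `dt_ms` resolution), `rate_hz`.
#' @export
simulate_single_eif <- function(cell_class = "exc", cfg = model_config(),
                                i_ext_na = 0, g_exc_ns = 0,
                                duration_ms = 1000, dt_ms = 0.01,
                                v0 = NULL, delta_t_override = NULL) {
  p <- cfg$neuron[[cell_class]]
  n_steps <- as.integer(round(duration_ms / dt_ms))
  res <- eif_network_cpp(
    1L, p$tau_m, p$r_mohm, p$e_l, p$v_t,
    as.integer(ceiling(p$t_ref / dt_ms)),
    if (is.null(delta_t_override)) cfg$neuron$delta_t else delta_t_override,
    cfg$neuron$v_spike, cfg$neuron$v_reset,
    cfg$neuron$e_exc, cfg$neuron$e_inh,
    cfg$synapse$tau_exc, cfg$synapse$tau_inh,
    c(0L, 0L), integer(0), numeric(0), integer(0), 30,
    FALSE, cfg$synapse$stp_u, integer(0), integer(0),
    dt_ms, n_steps, 0L, 1L,
    i_ext_na, g_exc_ns, if (is.null(v0)) p$e_l else v0)
  list(spike_times_ms = res$step * dt_ms,
       vm = res$vm[, 1],
       rate_hz = length(res$step) / (duration_ms / 1000))
}
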