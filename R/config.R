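#' Base model configuration
#'
#' Full parameter set of the two-layer V1 model: geometry, neuron counts,
#' membrane parameters, connectivity kernels (hyperbolic distance profiles,
#' push-pull, orientation bias, local + long-range Gaussian mixture),
#' per-projection in-degrees/weights/short-term-depression constants, and
#' the disks-and-rings stimulation protocol.  Field names mirror the model
#' tables entry-for-entry so parameter provenance is auditable.
#'
#' @param contrast protocol grating contrast (default 1).
#' @param temporal_freq_hz protocol drift frequency (default 2 Hz).
#' @return nested configuration list of class `"v1_config"`.
#' @export
model_config <- function(contrast = 1, temporal_freq_hz = 2) {
  cfg <- list(
    geometry = list(
      sheet_mm = c(5, 5),
      magnification_mm_per_deg = 5 / 6,  # 5 mm sheet spans the 6 deg field
      lgn_field_deg = 6),
    counts = list(l4_exc = 37500, l4_inh = 9375,
                  l23_exc = 37500, l23_inh = 9375, lgn = 14400,
                  lgn_on_fraction = 0.5),
    map = list(hypercolumn_mm = 1, resolution_mm = 0.05),
    neuron = list(
      exc = list(tau_m = 8, r_mohm = 250, e_l = -80, v_t = -57, t_ref = 2),
      inh = list(tau_m = 9, r_mohm = 327, e_l = -78, v_t = -58, t_ref = 0.5),
      delta_t = 0.8, v_spike = -40, v_reset = -70, e_exc = 0, e_inh = -80),
    synapse = list(
      tau_exc = 1.5, tau_inh = 4.2, stp_u = 0.75,
      delay_const_ee = 1.4, delay_const_ei = 0.5, delay_const_inh = 1,
      delay_ms_per_mm = 0.33, thalamic_delay_ms = c(1.4, 2.4)),
    gabor = list(freq_cpd = 0.8, sigma_deg = 0.17, gamma = 2.5, G = 0.085),
    # hyperbolic distance-profile parameters exp(-alpha*sqrt(theta^2+x^2)),
    # x in micrometres, by (source, target) population pair
    table1 = data.frame(
      src = c("l4_exc", "l4_exc", "l4_exc", "l4_exc",
              "l4_inh", "l4_inh", "l23_inh", "l23_inh"),
      tgt = c("l4_exc", "l4_inh", "l23_exc", "l23_inh",
              "l4_exc", "l4_inh", "l23_exc", "l23_inh"),
      alpha = c(0.0139, 0.0148, 0.0174, 0.0197,
                0.0126, 0.0119, 0.0149, 0.0150),
      theta = c(207.7, 191.8, 154.4, 131.5, 237.5, 256.4, 189.5, 188.61)),
    # per-projection in-degrees, weights (nS), kernels, recovery constants
    projections = data.frame(
      src = c("lgn_on", "lgn_off", "lgn_on", "lgn_off",
              "l4_exc", "l4_exc", "l4_inh", "l4_inh",
              "l4_exc", "l4_exc", "l23_exc", "l23_exc",
              "l23_inh", "l23_inh", "l23_exc", "l23_exc"),
      tgt = c("l4_exc", "l4_exc", "l4_inh", "l4_inh",
              "l4_exc", "l4_inh", "l4_exc", "l4_inh",
              "l23_exc", "l23_inh", "l23_exc", "l23_inh",
              "l23_exc", "l23_inh", "l4_exc", "l4_inh"),
      in_degree = c(NA, NA, NA, NA, NA, NA, 200, 120,
                    404, 242, 1435, 861, 460, 276, 160, 96),
      weight_ns = c(1.2, 1.2, 1.2, 1.2, 0.18, 0.22, 1, 1,
                    1, 1, 0.18, 0.35, 1, 1, 0.18, 0.22),
      kernel = c("gabor", "gabor", "gabor", "gabor",
                 "push", "push", "pull", "pull",
                 "ff_orient", "ff_orient", "lr_mixture", "lr_mixture",
                 "dist_only", "dist_only", "fb_orient", "fb_orient"),
      tau_rec = c(125, 125, 125, 125, 30, 30, 70, 70,
                  30, 30, 30, 30, 30, 30, 30, 30)),
    thalamic = list(
      n_exc_per_polarity = c(45, 95),   # uniform per-polarity afferent count
      n_inh_per_polarity = c(56, 84),
      # recurrent L4 in-degrees are the totals minus the thalamic count
      l4_exc_total_exc = 640, l4_inh_total_exc = 384),
    pushpull = list(sigma = 1.3, mu_exc = 1, mu_inh = -1,
                    corr_grid_deg = 0.1),
    l23 = list(sigma_local_um = 270,
               sigma_lr_ee_um = 1000, sigma_lr_ei_um = 1000,
               alpha_lr = 4,
               sigma_or_ee = 1.3, sigma_or_ei = 1.3, sigma_or_ff = 1.3),
    combine = "product",  # distance x functional; "sum" keeps Eq. literal
    lgn = lgn_params(),
    protocol = list(
      disk_diameters_deg = c(0, 0.4, 0.8, 1.2, 1.8, 2.4, 3.2, 4, 5, 6),
      ring_outer_deg = 6, contrast = contrast,
      temporal_freq_hz = temporal_freq_hz, spatial_freq_cpd = 0.8,
      duration_ms = 1500, trials = 10,
      pixel_deg = 0.05, frame_dt_ms = 5),
    sim = list(dt_ms = 0.1, lgn_dt_ms = 0.1, vm_record_dt_ms = 1,
               record_ecc_deg = 0.4),
    provenance = list(scale = 1, scaled = FALSE, variant = "base"))
  class(cfg) <- "v1_config"
  cfg
}

#' Density/area-scaled configuration for desk-scale runs
#'
#' Scales neuron counts and sheet/field area by `s` while keeping the
#' per-neuron in-degrees (and hence the synaptic drive per neuron) at their
#' full-scale values; linear dimensions, and the protocol diameters with
#' them, shrink by `sqrt(s)`.  `s = 1` reproduces the full-scale counts.
#'
#' @param s scale factor in (0, 1].
#' @param overrides named list of config entries to replace after scaling
#'   (names in `$section$field` nesting, e.g.
#'   `list(protocol = list(trials = 3))`); values are merged shallowly per
#'   section.
#' @param base base configuration (default [model_config()]).
#' @return scaled `"v1_config"`; provenance marks it scaled.
#' @export
make_scaled_config <- function(s, overrides = list(), base = model_config()) {
  stopifnot(s > 0, s <= 1)
  cfg <- base
  lin <- sqrt(s)
  for (f in c("l4_exc", "l4_inh", "l23_exc", "l23_inh", "lgn"))
    cfg$counts[[f]] <- max(1L, as.integer(floor(base$counts[[f]] * s)))
  cfg$geometry$sheet_mm <- base$geometry$sheet_mm * lin
  cfg$geometry$lgn_field_deg <- base$geometry$lgn_field_deg * lin
  cfg$protocol$disk_diameters_deg <- base$protocol$disk_diameters_deg * lin
  cfg$protocol$ring_outer_deg <- base$protocol$ring_outer_deg * lin
  cfg$sim$record_ecc_deg <- base$sim$record_ecc_deg * lin
  for (sec in names(overrides))
    for (f in names(overrides[[sec]]))
      cfg[[sec]][[f]] <- overrides[[sec]][[f]]
  # each projection's in-degree must not exceed its source pool
  pj <- cfg$projections
  fixed <- !is.na(pj$in_degree) & !startsWith(pj$src, "lgn")
  pool <- unlist(cfg$counts[pj$src[fixed]])
  bad <- pj$in_degree[fixed] > pool
  if (any(bad))
    stop("scale too small: in-degree ", max(pj$in_degree[fixed][bad]),
         " exceeds its source population (",
         min(pool[bad]), "); increase s or override in_degree")
  cfg$provenance <- list(scale = s, scaled = !isTRUE(all.equal(s, 1)),
                         variant = cfg$provenance$variant,
                         overrides = overrides)
  cfg
}

#' Sparsify the synaptic in-degrees at fixed mean conductance
#'
#' Multiplies every per-target in-degree (including the thalamic afferent
#' ranges and the layer 4 excitatory totals) by `k` and every synaptic
#' weight by `1/k`, so each neuron receives the same mean synaptic
#' conductance from each projection through fewer, stronger synapses.
#' This is the standard device for desk-scale runs of dense recurrent
#' models: it preserves working points while cutting synapse counts (at
#' the cost of larger synaptic quanta, i.e. more input fluctuation).
#'
#' @param cfg a `"v1_config"`.
#' @param k in-degree scale in (0, 1].
#' @param thalamic also sparsify the thalamocortical afferents (default
#'   FALSE: LGN deliveries are a small share of the synaptic traffic, and
#'   sparsifying them would force duplicate afferents with oversized
#'   quanta of correlated feedforward input).
#' @return the sparsified configuration; provenance records `k`.
#' @export
sparsify_config <- function(cfg, k, thalamic = FALSE) {
  stopifnot(k > 0, k <= 1)
  pj <- cfg$projections
  gab <- pj$kernel == "gabor"
  scale_row <- !gab | thalamic
  pj$in_degree <- ifelse(is.na(pj$in_degree) | !scale_row, pj$in_degree,
                         pmax(1L, as.integer(round(pj$in_degree * k))))
  pj$weight_ns <- ifelse(scale_row, pj$weight_ns / k, pj$weight_ns)
  cfg$projections <- pj
  th <- cfg$thalamic
  if (thalamic) {
    th$n_exc_per_polarity <- pmax(1L, as.integer(round(th$n_exc_per_polarity * k)))
    th$n_inh_per_polarity <- pmax(1L, as.integer(round(th$n_inh_per_polarity * k)))
  }
  # the layer 4 recurrent totals are "total minus thalamic count"; keep the
  # recurrent part at scale k whatever the thalamic choice
  mean_exc <- round(mean(th$n_exc_per_polarity) * 2)
  mean_inh <- round(mean(th$n_inh_per_polarity) * 2)
  th$l4_exc_total_exc <- as.integer(mean_exc +
    round((cfg$thalamic$l4_exc_total_exc - mean_exc) * k))
  th$l4_inh_total_exc <- as.integer(mean_inh +
    round((cfg$thalamic$l4_inh_total_exc - mean_inh) * k))
  cfg$thalamic <- th
  cfg$provenance$sparsify_k <- k
  cfg
}

#' Layer 2/3 long-range connectivity variants
#'
#' The named variants change exactly one parameter family of the long-range
#' excitatory-to-excitatory horizontal connections, keeping the
#' corresponding excitatory-to-inhibitory parameters at base: the spatial
#' range `sigma_lr_ee_um` (broad 1250 um / narrow 740 um vs base 1000 um)
#' or the iso-orientation bias `sigma_or_ee` (high bias 0.7 rad / low bias
#' 3.5 rad vs base 1.3 rad).
#'
#' @param name one of `"base"`, `"broad_EE"`, `"narrow_EE"`,
#'   `"high_bias_EE"`, `"low_bias_EE"`.
#' @param base configuration to modify (default [model_config()]).
#' @return the variant `"v1_config"`.
#' @export
make_variant_config <- function(name = c("base", "broad_EE", "narrow_EE",
                                         "high_bias_EE", "low_bias_EE"),
                                base = model_config()) {
  name <- match.arg(name)
  cfg <- base
  switch(name,
         base = NULL,
         broad_EE = { cfg$l23$sigma_lr_ee_um <- 1250 },
         narrow_EE = { cfg$l23$sigma_lr_ee_um <- 740 },
         high_bias_EE = { cfg$l23$sigma_or_ee <- 0.7 },
         low_bias_EE = { cfg$l23$sigma_or_ee <- 3.5 })
  cfg$provenance$variant <- name
  cfg
}

#' Differences between two configurations
#'
#' Flattens both configurations and reports the leaves whose values differ
#' (provenance fields are ignored).  Used to audit that each variant
#' changes exactly one parameter.
#'
#' @param a,b `"v1_config"` objects.
#' @return character vector of differing leaf names (empty when identical).
#' @export
config_diff <- function(a, b) {
  fa <- unlist(a[setdiff(names(a), "provenance")])
  fb <- unlist(b[setdiff(names(b), "provenance")])
  keys <- union(names(fa), names(fb))
  keys[vapply(keys, function(k) !isTRUE(all.equal(fa[[k]], fb[[k]])), TRUE)]
}

#' Configuration hash for provenance records
#'
#' MD5 digest of the serialised configuration (provenance excluded), so two
#' runs from the same parameters can be recognised as identical.
#'
#' @param cfg a `"v1_config"`.
#' @return hex digest string.
#' @export
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg[setdiff(names(cfg), "provenance")], f, version = 2)
  unname(tools::md5sum(f))
}
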