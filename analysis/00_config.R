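# Shared configuration for the analysis workflow: the reduced-scale model
# used on a desk machine, and the four long-range-connectivity variants.
#
# Full-scale integration (s = 1) is a cluster-sized computation; these
# scripts run the density-scaled configuration described in the methods
# vignette (scale 0.08 on a 3.83 mm sheet spanning a 4.6 deg field,
# synapses sparsified to 40% of the tabulated in-degrees at inversely
# scaled weights).  Every output is stamped with the scale and seeds.

library(v1rings)

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

MASTER_SEED <- 1

analysis_config <- function(trials = 2) {
  cfg <- make_scaled_config(0.08, overrides = list(
    geometry = list(sheet_mm = c(3.83, 3.83), lgn_field_deg = 4.6),
    protocol = list(disk_diameters_deg = c(0, 0.5, 1.0, 1.5, 2.2, 3.0, 4.0),
                    ring_outer_deg = 4.0, trials = trials, pixel_deg = 0.1),
    sim = list(record_ecc_deg = 0.35, lgn_dt_ms = 0.5)))
  cfg$counts$lgn <- 8464  # keep the LGN mosaic at full areal density
  sparsify_config(cfg, 0.4)
}

VARIANTS <- c("broad_EE", "narrow_EE", "high_bias_EE", "low_bias_EE")
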