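# Reduced-scale behavioural runs shared by the end-to-end tests: the base
# model plus the four long-range-connectivity variants, simulated once per
# test session and summarised into per-cell integration metrics.
#
# Problem size (see the methods vignette): density scale 0.08 on a 3.83 mm
# sheet spanning a 4.6 deg field, full-density LGN mosaic, cortical
# synapses sparsified to 40% of the tabulated in-degrees at inversely
# scaled weights, 5 disk diameters, 1000 ms trials (2 for base, 1 for the
# variants).  Index magnitudes at this scale carry the reduced-geometry
# distortions discussed in the methods vignette.
.beh_cache <- new.env(parent = emptyenv())

behaviour_config <- function() {
  cfg <- make_scaled_config(0.08, overrides = list(
    geometry = list(sheet_mm = c(3.83, 3.83), lgn_field_deg = 4.6),
    protocol = list(disk_diameters_deg = c(0, 0.5, 1.0, 1.7, 2.8),
                    ring_outer_deg = 2.8, trials = 2, pixel_deg = 0.1,
                    duration_ms = 1000),
    sim = list(record_ecc_deg = 0.35, lgn_dt_ms = 0.5)))
  cfg$counts$lgn <- 8464
  sparsify_config(cfg, 0.4)
}

# per-cell metrics table for one recording set: classification at the best
# disk, selection by eccentricity and best-disk rate, indices per measure
behaviour_metrics <- function(rec) {
  m <- measure_protocol(rec)
  cells <- rec$cells
  disks <- rec$protocol$cond[rec$protocol$shape == "disk"]
  md <- m[m$cond %in% disks, ]
  best <- do.call(rbind, lapply(split(md, md$cell), function(x)
    x[which.max(x$MFR), ]))
  cls <- vapply(seq_len(nrow(best)), function(i) {
    cc <- classify_cell(best$spikesF1[i], best$MFR[i])
    if (is.na(cc$class)) NA_character_ else cc$class
  }, "")
  ids <- as.integer(rownames(best))
  dc <- integration_metrics(m, rec$protocol, "VmDC")
  f1 <- integration_metrics(m, rec$protocol, "VmF1")
  mfr <- integration_metrics(m, rec$protocol, "MFR")
  data.frame(
    cell = ids,
    pop = cells$pop[match(ids, cells$cell)],
    class = cls,
    selected = best$MFR > 1,
    NLI_VmDC = dc$NLI[match(ids, dc$cell)],
    LI_VmDC = dc$mean_LI[match(ids, dc$cell)],
    SI_MFR = mfr$SI[match(ids, mfr$cell)],
    NLI_VmF1 = f1$NLI[match(ids, f1$cell)],
    LI_VmF1 = f1$mean_LI[match(ids, f1$cell)])
}

behaviour_runs <- function() {
  if (!is.null(.beh_cache$runs)) return(.beh_cache$runs)
  cfg <- behaviour_config()
  con <- build_connectome(cfg, seed = 1)
  runs <- list(base = behaviour_metrics(run_protocol(con, cfg, seed = 1)))
  for (v in c("broad_EE", "narrow_EE", "high_bias_EE", "low_bias_EE")) {
    vcfg <- make_variant_config(v, cfg)
    vcon <- apply_variant(con, vcfg)
    runs[[v]] <- behaviour_metrics(run_protocol(vcon, vcfg, seed = 1,
                                                trials = 1))
  }
  .beh_cache$runs <- runs
  runs
}

complex_l23 <- function(tab) tab[tab$selected & !is.na(tab$class) &
                                   tab$class == "complex" &
                                   tab$pop == "l23_exc", ]
simple_l4 <- function(tab) tab[tab$selected & !is.na(tab$class) &
                                 tab$class == "simple" &
                                 tab$pop == "l4_exc", ]
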