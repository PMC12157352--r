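# Turn the raw recordings into per-cell, per-condition response measures
# (VmDC, VmF1, VmSD, MFR, spikes F1), classify cells simple/complex at
# their best disk, and apply the population selection criteria
# (eccentricity window, best-disk rate > 1 spike/s).
#
# Writes results/measures_<name>.csv and results/cells_<name>.csv.

source("analysis/00_config.R")

models <- c("base", VARIANTS)
for (name in models) {
  f <- file.path(RESULTS_DIR, paste0("records_", name, ".rds"))
  if (!file.exists(f)) stop("run analysis/01_simulate.R first (missing ", f, ")")
  rec <- readRDS(f)
  message("measuring ", name, " ...")
  m <- measure_protocol(rec)
  disks <- rec$protocol$cond[rec$protocol$shape == "disk"]
  cells <- rec$cells
  md <- m[m$cond %in% disks, ]
  best <- do.call(rbind, lapply(split(md, md$cell), function(x)
    x[which.max(x$MFR), ]))
  cls <- vapply(seq_len(nrow(best)), function(i) {
    cc <- classify_cell(best$spikesF1[i], best$MFR[i])
    if (is.na(cc$class)) NA_character_ else cc$class
  }, "")
  cells$class <- cls[match(cells$cell, best$cell)]
  cells$max_disk_rate_hz <- best$MFR[match(cells$cell, best$cell)]
  sel <- select_cells(cells[, c("cell", "ecc_deg", "max_disk_rate_hz")])
  cells$selected <- cells$cell %in% sel$cell
  message(sprintf("  %d/%d cells selected; %d simple / %d complex among them",
                  sum(cells$selected), nrow(cells),
                  sum(cells$class[cells$selected] == "simple", na.rm = TRUE),
                  sum(cells$class[cells$selected] == "complex", na.rm = TRUE)))
  write.csv(m, file.path(RESULTS_DIR, paste0("measures_", name, ".csv")),
            row.names = FALSE)
  write.csv(cells, file.path(RESULTS_DIR, paste0("cells_", name, ".csv")),
            row.names = FALSE)
}
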