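# Build the reduced-scale connectome and run the disks-and-rings protocol
# for the base model and the four long-range-connectivity variants.
#
# The variants differ from base only in the layer 2/3 E->E long-range
# parameters, so the base connectome is reused and only that projection is
# resampled per variant.  Writes one recording container per model to
# results/records_<name>.rds (~10 min on one core per model).

source("analysis/00_config.R")

cfg <- analysis_config()
message("building base connectome (seed ", MASTER_SEED, ") ...")
con <- build_connectome(cfg, seed = MASTER_SEED)
print(con)

run_one <- function(con, cfg, name) {
  message("simulating ", name, " ...")
  rec <- run_protocol(con, cfg, seed = MASTER_SEED, progress = TRUE)
  saveRDS(rec, file.path(RESULTS_DIR, paste0("records_", name, ".rds")))
  rec
}

run_one(con, cfg, "base")
for (v in VARIANTS) {
  vcfg <- make_variant_config(v, cfg)
  vcon <- apply_variant(con, vcfg)
  run_one(vcon, vcfg, v)
}
message("done; recordings in ", RESULTS_DIR)
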