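# Shared small connectome for the wiring audits: full (unsparsified)
# Table in-degrees at reduced neuron counts, built once per test run.
.con_cache <- new.env(parent = emptyenv())

audit_config <- function() {
  cfg <- make_scaled_config(0.06, overrides = list(
    geometry = list(sheet_mm = c(1.6, 1.6), lgn_field_deg = 1.92),
    sim = list(record_ecc_deg = 0.2, lgn_dt_ms = 0.5)))
  cfg$counts$lgn <- 1400
  cfg
}

audit_connectome <- function() {
  if (is.null(.con_cache$con))
    .con_cache$con <- build_connectome(audit_config(), seed = 42)
  .con_cache$con
}
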