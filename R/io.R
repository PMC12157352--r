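#' Write spike trains as two-column text
#'
#' Plain-text exchange format: one row per spike, columns `cell` (id) and
#' `time_ms`, tab-separated with a header line.
#'
#' @param spikes list of per-cell spike-time vectors (ms), or the
#'   `spikes[[cond]][[trial]]` entry of a [sim_records()] object.
#' @param file output path.
#' @param cell_ids ids to label the cells with (default sequential).
#' @export
write_spike_trains <- function(spikes, file, cell_ids = seq_along(spikes)) {
  df <- data.frame(cell = rep(cell_ids, lengths(spikes)),
                   time_ms = unlist(spikes, use.names = FALSE))
  utils::write.table(df[order(df$time_ms), ], file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' Read two-column spike-train text
#'
#' @param file path written by [write_spike_trains()].
#' @param n_cells number of cells (ids without spikes get empty vectors);
#'   default: the largest id present.
#' @return list of per-cell spike-time vectors (ms).
#' @export
read_spike_trains <- function(file, n_cells = NULL) {
  df <- utils::read.table(file, header = TRUE)
  if (is.null(n_cells)) n_cells <- max(df$cell)
  out <- split(df$time_ms, factor(df$cell, levels = seq_len(n_cells)))
  lapply(unname(out), sort)
}

#' Save / load a recording container
#'
#' The binary container keyed by condition and trial is R serialisation of
#' the [sim_records()] object (schema documented there); the plain-text
#' alternative for spike data is [write_spike_trains()].
#'
#' @param records a [sim_records()] object.
#' @param file path (.rds).
#' @export
save_records <- function(records, file) {
  stopifnot(inherits(records, "sim_records"))
  saveRDS(records, file)
}

#' @rdname save_records
#' @export
load_records <- function(file) {
  r <- readRDS(file)
  stopifnot(inherits(r, "sim_records"))
  r
}

#' Save / load an orientation map
#'
#' Binary grid plus generation header (extent, resolution, hypercolumn
#' scale, seed), so downstream wiring is reproducible across runs.
#'
#' @param map an [generate_orientation_map()] result.
#' @param file path (.rds).
#' @export
save_orientation_map <- function(map, file) {
  stopifnot(inherits(map, "orientation_map"))
  saveRDS(map, file)
}

#' @rdname save_orientation_map
#' @export
load_orientation_map <- function(file) {
  m <- readRDS(file)
  stopifnot(inherits(m, "orientation_map"))
  m
}

#' Save / load a connectome
#'
#' Per-projection edge tables (source, target, weight, delay, recovery
#' constant) with the provenance header (seed lineage, config hash, scale,
#' variant), loadable without rebuilding.
#'
#' @param con a [build_connectome()] result.
#' @param file path (.rds).
#' @export
save_connectome <- function(con, file) {
  stopifnot(inherits(con, "connectome"))
  saveRDS(con, file)
}

#' @rdname save_connectome
#' @export
load_connectome <- function(file) {
  con <- readRDS(file)
  stopifnot(inherits(con, "connectome"))
  con
}

#' Read a stimulation protocol from a YAML config file
#'
#' One protocol = an ordered list of stimulus entries plus `trials` and
#' optionally `inter_trial_blank_ms`.  Each entry carries the
#' [stimulus_spec()] fields (`shape`, `diameter_deg`,
#' `outer_diameter_deg`, `orientation_rad`, `spatial_freq_cpd`,
#' `temporal_freq_hz`, `contrast`, `duration_ms`); omitted fields take the
#' `stimulus_spec()` defaults.
#'
#' @param file YAML path.
#' @return list with `stimuli` (list of [stimulus_spec()]), `trials`,
#'   `inter_trial_blank_ms`.
#' @export
read_protocol_config <- function(file) {
  y <- yaml::read_yaml(file)
  if (is.null(y$stimuli)) stop("protocol config needs a 'stimuli' list")
  stimuli <- lapply(y$stimuli, function(s) do.call(stimulus_spec, s))
  list(stimuli = stimuli,
       trials = if (is.null(y$trials)) 10L else as.integer(y$trials),
       inter_trial_blank_ms = if (is.null(y$inter_trial_blank_ms)) 0
                              else y$inter_trial_blank_ms)
}
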