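#' Run configuration
#'
#' A run configuration is a plain named list, serializable to YAML, holding
#' the manifest path, channel map, channel roles, segmentation parameters,
#' screen parameters, and the seed. Every `run_*` command writes the
#' effective configuration next to its outputs so a run can be reproduced
#' exactly.
#'
#' @param manifest Path to a field manifest CSV (see [read_manifest()]).
#' @param channel_map Named list/vector: channel name -> TIFF page index.
#' @param gc_channel,fc_channel,dna_channel Channel roles for scoring.
#' @param seg Named list of [seg_params()] overrides.
#' @param screen Named list: `k_sd`, `direction`, `conc_low`, `conc_high`.
#' @param seed Integer seed for any stochastic step.
#' @return A list of class `run_config`.
#' @export
run_config <- function(manifest = NULL,
                       channel_map = list(dapi = 1L, ubf = 2L, ncl = 3L),
                       gc_channel = "ncl", fc_channel = "ubf",
                       dna_channel = "dapi",
                       seg = list(), screen = list(k_sd = 2, direction = "below",
                                                   conc_low = 1, conc_high = 10),
                       seed = 1L) {
  structure(list(manifest = manifest, channel_map = channel_map,
                 gc_channel = gc_channel, fc_channel = fc_channel,
                 dna_channel = dna_channel, seg = seg, screen = screen,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file to read.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  base <- run_config()
  base[names(cfg)] <- cfg
  base
}

write_effective_config <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "effective_config.yaml"))
}

#' Score all fields of a manifest
#'
#' The core imaging pipeline: read each field, segment nuclei on the DNA
#' channel and nucleoli on the FC channel, measure background-subtracted
#' compartment intensities, and compute the per-cell normality score. Writes
#' `per_cell.csv` and the effective config to `out_dir`.
#'
#' @param config A [run_config()] (needs `manifest`).
#' @param out_dir Output directory.
#' @param seg_params_obj Optional ready-made [seg_params()] (otherwise built
#'   from `config$seg`).
#' @return The per-cell data frame, invisibly.
#' @export
run_score <- function(config, out_dir, seg_params_obj = NULL) {
  if (is.null(config$manifest)) stopf("config$manifest is required")
  sp <- if (!is.null(seg_params_obj)) seg_params_obj else
    do.call(seg_params, config$seg)
  fields <- read_manifest(config$manifest, config$channel_map)
  rows <- lapply(fields, function(f) {
    nuc <- segment_nuclei(get_channel(f, config$dna_channel), sp)
    noli <- segment_nucleoli(get_channel(f, config$fc_channel), nuc, sp)
    meas <- measure_cells(f, nuc, noli,
                          channels = c(config$gc_channel, config$fc_channel),
                          bg_radius = sp$nucleolus_bg_radius)
    if (nrow(meas) == 0L) return(NULL)
    meas$score <- normality_score(meas, config$gc_channel, config$fc_channel)
    meas$field_id <- f$field_id
    meas$well_id <- if (is.null(f$well_id)) NA_character_ else f$well_id
    meas
  })
  per_cell <- do.call(rbind, rows)
  if (is.null(per_cell)) stopf("no cells found in any field")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(per_cell, file.path(out_dir, "per_cell.csv"),
                   row.names = FALSE)
  write_effective_config(config, out_dir)
  invisible(per_cell)
}

#' Screen-level analysis of a per-cell table
#'
#' Runs [screen_plate()] on a per-cell CSV plus layout CSV and writes
#' `wells.csv`, `hits.csv`, `enrichment.csv`.
#'
#' @param config A [run_config()].
#' @param per_cell_csv,layout_csv Input CSV paths.
#' @param out_dir Output directory.
#' @return The `plate_result`, invisibly.
#' @export
run_screen <- function(config, per_cell_csv, layout_csv, out_dir) {
  per_cell <- utils::read.csv(per_cell_csv)
  layout <- utils::read.csv(layout_csv)
  res <- screen_plate(per_cell, layout,
                      k = config$screen$k_sd %||% 2,
                      direction = config$screen$direction %||% "below",
                      conc_low = config$screen$conc_low %||% 1,
                      conc_high = config$screen$conc_high %||% 10)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$wells, file.path(out_dir, "wells.csv"), row.names = FALSE)
  utils::write.csv(res$categories, file.path(out_dir, "hits.csv"), row.names = FALSE)
  if (!is.null(res$enrichment))
    utils::write.csv(res$enrichment, file.path(out_dir, "enrichment.csv"),
                     row.names = FALSE)
  write_effective_config(config, out_dir)
  invisible(res)
}

#' Fit all FRAP traces in a directory
#'
#' Reads every `*.csv` trace in `trace_dir` (format of
#' [read_frap_trace()]), normalizes, fits, and writes `frap_fits.csv`.
#'
#' @param config A [run_config()].
#' @param trace_dir Directory of trace CSVs.
#' @param out_dir Output directory.
#' @return The fit table, invisibly.
#' @export
run_frap <- function(config, trace_dir, out_dir) {
  files <- sort(list.files(trace_dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stopf("no trace CSVs in %s", trace_dir)
  rows <- lapply(files, function(f) {
    tr <- read_frap_trace(f)
    nt <- normalize_trace(tr)
    if (!nt$valid)
      return(data.frame(trace = basename(f), F0 = NA, A1 = NA, k1 = NA,
                        A2 = NA, k2 = NA, plateau = NA, T_half = NA,
                        residual_rms = NA, converged = FALSE,
                        single_component = NA))
    fit <- fit_recovery(nt)
    data.frame(trace = basename(f), F0 = fit$F0, A1 = fit$A1, k1 = fit$k1,
               A2 = fit$A2, k2 = fit$k2, plateau = fit$plateau,
               T_half = fit$T_half, residual_rms = fit$residual_rms,
               converged = fit$converged,
               single_component = fit$single_component)
  })
  out <- do.call(rbind, rows)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out, file.path(out_dir, "frap_fits.csv"), row.names = FALSE)
  write_effective_config(config, out_dir)
  invisible(out)
}

#' Simulate a set of fields to disk
#'
#' @param config A [run_config()] (its `seed` seeds the generator).
#' @param out_dir Output directory for TIFFs + manifest + truth CSVs.
#' @param n_fields Number of fields.
#' @param phenotype Passed to [phenotype_params()].
#' @return Manifest path, invisibly.
#' @export
run_simulate <- function(config, out_dir, n_fields = 4L,
                         phenotype = "normal") {
  fields <- lapply(seq_len(n_fields), function(i)
    generate_field(phenotype_params(phenotype = phenotype,
                                    seed = config$seed + i - 1L)))
  man <- write_field_set(fields, out_dir)
  write_effective_config(config, out_dir)
  invisible(man)
}

#' Apply the phosphosite filtering rules to a TSV
#'
#' @param config A [run_config()].
#' @param input_tsv Input table (see [filter_decreased_sites()]).
#' @param out_dir Output directory.
#' @param drugs Drug column suffixes.
#' @return The filtered table, invisibly.
#' @export
run_phospho <- function(config, input_tsv, out_dir, drugs) {
  rec <- read_phospho_table(input_tsv)
  out <- filter_decreased_sites(rec, drugs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_phospho_table(out, file.path(out_dir, "phospho_filtered.tsv"))
  write_effective_config(config, out_dir)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
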