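#' Per-cell compartment intensities
#'
#' For every nucleus, sums channel intensities over the whole nucleus and over
#' its nucleoli. The nucleoplasmic integrated intensity is defined by exact
#' subtraction, `I_nucleoplasm = I_nucleus - I_nucleolar`, so the two
#' compartments partition the nucleus for every channel. Intensities should be
#' measured on background-subtracted (but unblurred) channels: pass
#' `bg_radius` to subtract a rolling-ball background from each measured
#' channel, or `NULL` if the field is already background-free.
#'
#' @param field An [image_field()].
#' @param nuclei Nucleus [label_mask()].
#' @param nucleoli Nucleolus [label_mask()] with parent map into `nuclei`.
#' @param channels Channel names to measure; default all channels.
#' @param bg_radius Optional rolling-ball radius applied to each measured
#'   channel before summation.
#' @return A `cell_measurements` data frame with one row per nucleus:
#'   `nucleus_label`, `nucleus_area_px`, `nucleolar_area_px`, `n_nucleoli`,
#'   and per channel `I_nucleus_<ch>`, `I_nucleolar_<ch>`,
#'   `I_nucleoplasm_<ch>`.
#' @export
measure_cells <- function(field, nuclei, nucleoli, channels = NULL,
                          bg_radius = NULL) {
  stopifnot(inherits(field, "image_field"), inherits(nuclei, "label_mask"),
            inherits(nucleoli, "label_mask"))
  if (is.null(channels)) channels <- names(field$channels)
  K <- n_objects(nuclei)
  nl <- nuclei$labels
  ol <- nucleoli$labels
  if (!identical(dim(nl), dim(field))) stopf("mask/field dimension mismatch")
  out <- data.frame(nucleus_label = seq_len(K))
  out$nucleus_area_px <- tabulate(nl[nl > 0L], nbins = K)
  # nucleolar pixels grouped by parent nucleus
  o_idx <- which(ol > 0L)
  o_parent <- if (length(o_idx)) nucleoli$parent[ol[o_idx]] else integer(0)
  out$nucleolar_area_px <- tabulate(o_parent, nbins = K)
  out$n_nucleoli <- if (is.null(nucleoli$parent)) 0L else
    tabulate(nucleoli$parent, nbins = K)
  n_idx <- which(nl > 0L)
  n_lab <- nl[n_idx]
  for (ch in channels) {
    img <- get_channel(field, ch)
    if (!is.null(bg_radius)) img <- subtract_background(img, bg_radius)
    i_nuc <- rep(0, K)
    s <- rowsum(img[n_idx], group = n_lab)
    i_nuc[as.integer(rownames(s))] <- s[, 1L]
    i_no <- rep(0, K)
    if (length(o_idx)) {
      s2 <- rowsum(img[o_idx], group = o_parent)
      i_no[as.integer(rownames(s2))] <- s2[, 1L]
    }
    out[[paste0("I_nucleus_", ch)]] <- i_nuc
    out[[paste0("I_nucleolar_", ch)]] <- i_no
    out[[paste0("I_nucleoplasm_", ch)]] <- i_nuc - i_no
  }
  class(out) <- c("cell_measurements", "data.frame")
  out
}

meas_col <- function(meas, what, channel) {
  col <- paste0(what, "_", channel)
  if (!col %in% names(meas)) stopf("channel '%s' not measured", channel)
  meas[[col]]
}

#' Nucleolar normality score
#'
#' Per-cell score: the nucleolar/nucleoplasmic integrated-intensity ratio of
#' the granular-component (GC) marker divided by the same ratio for the
#' fibrillar-center (FC) marker,
#' \deqn{score = \frac{I^{GC}_{no}/I^{GC}_{np}}{I^{FC}_{no}/I^{FC}_{np}}.}
#' Under nucleolar stress the GC marker (nucleolin, NPM1) disperses into the
#' nucleoplasm while the FC marker (UBF) stays bound or condenses, so the
#' score decreases. The score is `NA` (undefined, excluded from aggregates)
#' for cells with no detected nucleoli, any non-positive nucleoplasmic
#' intensity, or zero FC nucleolar intensity.
#'
#' @param meas A [measure_cells()] table.
#' @param gc_channel,fc_channel Channel names of the GC and FC markers.
#' @return Numeric vector of scores, `NA` where undefined.
#' @export
normality_score <- function(meas, gc_channel, fc_channel) {
  no_g <- meas_col(meas, "I_nucleolar", gc_channel)
  np_g <- meas_col(meas, "I_nucleoplasm", gc_channel)
  no_f <- meas_col(meas, "I_nucleolar", fc_channel)
  np_f <- meas_col(meas, "I_nucleoplasm", fc_channel)
  score <- (no_g / np_g) / (no_f / np_f)
  bad <- meas$n_nucleoli == 0L | np_g <= 0 | np_f <= 0 | no_f <= 0
  score[bad] <- NA_real_
  score
}

#' Nucleolus/nucleoplasm intensity ratio for one channel
#'
#' Single-channel compartment ratio, e.g. for quantifying RNA Pol I (POLR1A)
#' retention in the nucleolus. Vehicle normalization happens at the plate
#' level, not here.
#'
#' @inheritParams normality_score
#' @param channel Channel name.
#' @return Numeric vector, `NA` where the nucleoplasmic intensity is
#'   non-positive.
#' @export
compartment_ratio <- function(meas, channel) {
  no <- meas_col(meas, "I_nucleolar", channel)
  np <- meas_col(meas, "I_nucleoplasm", channel)
  r <- no / np
  r[np <= 0] <- NA_real_
  r
}

#' Per-field intensity summaries
#'
#' Summarises per-cell integrated intensities (whole-nucleus or nucleolar) by
#' field, as used for transcription-labeling readouts (5-EU, Y10b) where the
#' unit of replication is the field of view. Fields with no cells are skipped
#' and counted.
#'
#' @param per_cell Data frame with a `field_id` column and measurement
#'   columns from [measure_cells()].
#' @param channel Channel name.
#' @param region `"nucleus"` (default) or `"nucleoli"`.
#' @return Data frame with `field_id`, `n_cells`, `mean`, `sd`; attribute
#'   `n_empty_fields` counts skipped fields.
#' @export
field_intensity_summary <- function(per_cell, channel,
                                    region = c("nucleus", "nucleoli")) {
  region <- match.arg(region)
  if (!"field_id" %in% names(per_cell)) stopf("`per_cell` needs a field_id column")
  what <- if (region == "nucleus") "I_nucleus" else "I_nucleolar"
  v <- meas_col(per_cell, what, channel)
  keep <- !is.na(v)
  n_empty <- 0L
  ids <- unique(per_cell$field_id)
  res <- lapply(ids, function(f) {
    vi <- v[keep & per_cell$field_id == f]
    if (!length(vi)) { n_empty <<- n_empty + 1L; return(NULL) }
    data.frame(field_id = f, n_cells = length(vi), mean = mean(vi),
               sd = if (length(vi) > 1L) stats::sd(vi) else 0)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(field_id = character(0), n_cells = integer(0),
                      mean = numeric(0), sd = numeric(0))
  if (n_empty > 0L) warning(sprintf("%d field(s) with no measurable cells skipped", n_empty))
  attr(out, "n_empty_fields") <- n_empty
  out
}

#' Normalize field summaries to the vehicle group
#'
#' Divides each field's mean by the mean of the vehicle fields' means, so the
#' vehicle group averages 1 (the standard DMSO normalization).
#'
#' @param summary A [field_intensity_summary()] result.
#' @param is_vehicle Logical vector marking vehicle rows of `summary`.
#' @return `summary` with added `norm_mean` column.
#' @export
normalize_to_vehicle <- function(summary, is_vehicle) {
  stopifnot(length(is_vehicle) == nrow(summary))
  if (!any(is_vehicle)) stopf("no vehicle fields to normalize to")
  ref <- mean(summary$mean[is_vehicle])
  if (ref <= 0) stopf("vehicle mean must be positive")
  summary$norm_mean <- summary$mean / ref
  summary
}
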