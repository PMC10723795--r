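#' Aggregate per-cell scores to wells
#'
#' Two-stage aggregation mirroring the screen's procedure: per-field means of
#' defined per-cell scores, then per-well means of the field means. Fields
#' with zero scored cells are excluded from the well mean and counted in a QC
#' column; cells with undefined (`NA`) scores are counted separately.
#'
#' @param per_cell Data frame with columns `well_id`, `field_id`, `score`.
#' @param layout Plate layout data frame with columns `well_id`,
#'   `compound_id`, `concentration_uM`, `is_vehicle` (and optionally
#'   `target_class`). Every imaged well must appear in the layout.
#' @return Data frame with one row per well: `well_id`, `compound_id`,
#'   `concentration_uM`, `is_vehicle`, `mean_score`, `cell_count`,
#'   `n_fields`, `n_empty_fields`, `n_unscored_cells`.
#' @export
aggregate_wells <- function(per_cell, layout) {
  need <- c("well_id", "field_id", "score")
  if (!all(need %in% names(per_cell)))
    stopf("`per_cell` needs columns: %s", paste(need, collapse = ", "))
  needl <- c("well_id", "compound_id", "concentration_uM", "is_vehicle")
  if (!all(needl %in% names(layout)))
    stopf("`layout` needs columns: %s", paste(needl, collapse = ", "))
  missing_wells <- setdiff(unique(per_cell$well_id), layout$well_id)
  if (length(missing_wells))
    stopf("wells present in measurements but absent from layout: %s",
          paste(utils::head(missing_wells, 5L), collapse = ", "))
  chunks <- split(per_cell[c("field_id", "score")],
                  factor(per_cell$well_id, levels = unique(per_cell$well_id)))
  rows <- lapply(names(chunks), function(w) {
    pc <- chunks[[w]]
    scored <- !is.na(pc$score)
    fm <- tapply(pc$score[scored], pc$field_id[scored], mean)
    lay <- layout[match(w, layout$well_id), ]
    data.frame(well_id = w,
               compound_id = lay$compound_id,
               concentration_uM = lay$concentration_uM,
               is_vehicle = lay$is_vehicle,
               mean_score = if (length(fm)) mean(fm) else NA_real_,
               cell_count = sum(scored),
               n_fields = length(fm),
               n_empty_fields = length(unique(pc$field_id)) - length(fm),
               n_unscored_cells = sum(!scored))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Vehicle-well statistics
#'
#' Sample mean and SD (n-1 denominator) of vehicle well scores. Vehicle
#' controls are pooled across plates by default, matching the screen's
#' observation that they were consistent plate to plate; per-plate pooling
#' (via a `plate_id` column) is available for robustness checks.
#'
#' @param wells A well table from [aggregate_wells()] (vehicle rows are
#'   selected by `is_vehicle`), or any data frame with `mean_score`.
#' @param pool `"all_plates"` (default) or `"per_plate"`.
#' @return For `"all_plates"`, a list with `mean`, `sd`, `n`; for
#'   `"per_plate"`, a data frame with one row per plate.
#' @export
vehicle_stats <- function(wells, pool = c("all_plates", "per_plate")) {
  pool <- match.arg(pool)
  v <- if ("is_vehicle" %in% names(wells)) wells[wells$is_vehicle, ] else wells
  if (pool == "per_plate") {
    if (!"plate_id" %in% names(v)) stopf("per-plate pooling needs a plate_id column")
    out <- do.call(rbind, lapply(split(v, v$plate_id), function(g) {
      if (nrow(g) < 2L) stopf("need >= 2 vehicle wells per plate (plate %s has %d)",
                              g$plate_id[1L], nrow(g))
      data.frame(plate_id = g$plate_id[1L], mean = mean(g$mean_score),
                 sd = stats::sd(g$mean_score), n = nrow(g))
    }))
    rownames(out) <- NULL
    return(out)
  }
  if (nrow(v) < 2L)
    stopf("need >= 2 vehicle wells to estimate the vehicle SD (got %d)", nrow(v))
  list(mean = mean(v$mean_score), sd = stats::sd(v$mean_score), n = nrow(v))
}

#' Call screen hits at a k-SD cutoff
#'
#' A well is a hit when its score deviates from the vehicle mean by more than
#' `k` vehicle SDs. The default is one-sided below (`score < mean - k*SD`):
#' nucleolar stress only lowers the normality score, and all screen hits were
#' below the control. `direction = "two_sided"` flags deviation in either
#' direction. The rule is invariant under common affine rescaling of scores
#' and vehicle statistics, so it may be applied to raw or vehicle-normalized
#' scores interchangeably.
#'
#' @param wells Well table (needs `mean_score`; typically from
#'   [aggregate_wells()]).
#' @param vehicle_mean,vehicle_sd Vehicle statistics (see [vehicle_stats()]);
#'   `vehicle_sd` must be positive.
#' @param k SD multiplier (default 2).
#' @param direction `"below"` (default) or `"two_sided"`.
#' @return `wells` with added `z_dev` (signed deviation in vehicle SDs) and
#'   `is_hit` columns.
#' @export
call_hits <- function(wells, vehicle_mean, vehicle_sd, k = 2,
                      direction = c("below", "two_sided")) {
  direction <- match.arg(direction)
  if (!is.numeric(vehicle_sd) || vehicle_sd <= 0)
    stopf("vehicle SD must be > 0 (got %s); identical vehicle wells cannot define a cutoff",
          format(vehicle_sd))
  z <- (wells$mean_score - vehicle_mean) / vehicle_sd
  wells$z_dev <- z
  wells$is_hit <- if (direction == "below") z < -k else abs(z) > k
  wells$is_hit[is.na(wells$is_hit)] <- FALSE
  wells
}

#' Compound-level hit categories across concentrations
#'
#' Combines per-concentration hit calls into the screen's compound categories:
#' hit at both concentrations, at the high concentration only, at the low
#' concentration only, or neither. The categories partition the compound set.
#'
#' @param calls A [call_hits()] result covering compound wells at two
#'   concentrations (vehicle rows are ignored).
#' @param conc_low,conc_high The two tested concentrations (default 1 and 10).
#' @return Data frame with `compound_id`, `hit_low`, `hit_high`, `category`
#'   (factor: `both`, `10_only`, `1_only`, `none`), and per-concentration
#'   `z_low`, `z_high`.
#' @export
hit_categories <- function(calls, conc_low = 1, conc_high = 10) {
  cc <- calls[!calls$is_vehicle, ]
  ids <- unique(cc$compound_id)
  pick <- function(id, conc, col) {
    r <- cc[cc$compound_id == id & cc$concentration_uM == conc, col]
    if (length(r) == 0L) NA else r[1L]
  }
  hit_low <- vapply(ids, pick, logical(1L), conc = conc_low, col = "is_hit")
  hit_high <- vapply(ids, pick, logical(1L), conc = conc_high, col = "is_hit")
  hl <- !is.na(hit_low) & hit_low
  hh <- !is.na(hit_high) & hit_high
  category <- ifelse(hl & hh, "both",
              ifelse(hh, "10_only", ifelse(hl, "1_only", "none")))
  data.frame(compound_id = ids,
             hit_low = hl, hit_high = hh,
             category = factor(category, levels = c("both", "10_only", "1_only", "none")),
             z_low = vapply(ids, pick, numeric(1L), conc = conc_low, col = "z_dev"),
             z_high = vapply(ids, pick, numeric(1L), conc = conc_high, col = "z_dev"),
             row.names = NULL)
}

#' Target-class enrichment among hits
#'
#' For each target class, compares its share among hit compounds to its share
#' in the screened library. Fold enrichment is
#' `(n_hits_class / n_hits) / (n_class / n_library)` and the p-value is the
#' hypergeometric upper tail: the probability of drawing at least
#' `n_hits_class` class members when drawing `n_hits` compounds from the
#' library without replacement (one-sided Fisher test). P-values are reported
#' raw by default, matching the screen's p < 0.05 / p < 0.001 tiers; set
#' `correct = TRUE` for Benjamini-Hochberg adjustment.
#'
#' @param hit_ids Character vector of hit compound ids.
#' @param library_annotation Data frame with `compound_id` and `target_class`
#'   covering the whole library; every hit must be annotated.
#' @param alpha Significance level for the `significant` flag.
#' @param correct Apply BH correction before flagging (default `FALSE`).
#' @return Data frame per target class: `target_class`, `n_library`,
#'   `n_hits`, `fold_enrichment`, `p_value`, `significant`.
#' @export
target_enrichment <- function(hit_ids, library_annotation, alpha = 0.05,
                              correct = FALSE) {
  need <- c("compound_id", "target_class")
  if (!all(need %in% names(library_annotation)))
    stopf("`library_annotation` needs columns: %s", paste(need, collapse = ", "))
  ann <- library_annotation
  unannotated <- setdiff(hit_ids, ann$compound_id)
  if (length(unannotated))
    stopf("hit compound(s) missing annotation: %s",
          paste(utils::head(unannotated, 5L), collapse = ", "))
  N <- nrow(ann)
  n_hits_total <- length(hit_ids)
  hit_class <- ann$target_class[match(hit_ids, ann$compound_id)]
  classes <- sort(unique(ann$target_class))
  n_lib <- as.integer(table(factor(ann$target_class, levels = classes)))
  n_hit <- as.integer(table(factor(hit_class, levels = classes)))
  fold <- if (n_hits_total > 0)
    (n_hit / n_hits_total) / (n_lib / N) else rep(NA_real_, length(classes))
  p <- stats::phyper(n_hit - 1L, n_lib, N - n_lib, n_hits_total,
                     lower.tail = FALSE)
  p_flag <- if (correct) stats::p.adjust(p, method = "BH") else p
  data.frame(target_class = classes, n_library = n_lib, n_hits = n_hit,
             fold_enrichment = fold, p_value = p,
             significant = p_flag < alpha, row.names = NULL)
}

#' Run the full plate-level screen analysis
#'
#' Convenience wrapper: aggregate per-cell scores to wells, compute vehicle
#' statistics, normalize well scores and cell counts to the vehicle mean,
#' call hits at both concentrations, derive compound categories, and (if the
#' layout carries `target_class`) compute target enrichment.
#'
#' @inheritParams aggregate_wells
#' @inheritParams call_hits
#' @param conc_low,conc_high Tested concentrations.
#' @return A `plate_result` list: `wells`, `vehicle` (mean/sd/n), `calls`,
#'   `categories`, `enrichment` (or `NULL`), and the parameters used.
#' @export
screen_plate <- function(per_cell, layout, k = 2,
                         direction = c("below", "two_sided"),
                         conc_low = 1, conc_high = 10) {
  direction <- match.arg(direction)
  wells <- aggregate_wells(per_cell, layout)
  veh <- vehicle_stats(wells)
  wells$normalized_score <- wells$mean_score / veh$mean
  mean_cells_veh <- mean(wells$cell_count[wells$is_vehicle])
  wells$normalized_cell_count <- if (mean_cells_veh > 0)
    wells$cell_count / mean_cells_veh else NA_real_
  calls <- call_hits(wells, veh$mean, veh$sd, k = k, direction = direction)
  cats <- hit_categories(calls, conc_low = conc_low, conc_high = conc_high)
  enr <- NULL
  if ("target_class" %in% names(layout)) {
    ann <- unique(layout[!layout$is_vehicle, c("compound_id", "target_class")])
    hit_ids <- cats$compound_id[cats$category != "none"]
    enr <- target_enrichment(hit_ids, ann)
  }
  structure(list(wells = wells, vehicle = veh, calls = calls,
                 categories = cats, enrichment = enr,
                 k = k, direction = direction),
            class = "plate_result")
}

#' @export
print.plate_result <- function(x, ...) {
  tab <- table(x$categories$category)
  cat(sprintf("<plate_result> %d wells, %d compounds; vehicle mean %.4g, SD %.4g (n=%d)\n",
              nrow(x$wells), nrow(x$categories), x$vehicle$mean, x$vehicle$sd,
              x$vehicle$n))
  cat(sprintf("hits (k=%g, %s): both=%d, 10_only=%d, 1_only=%d, none=%d\n",
              x$k, x$direction, tab[["both"]], tab[["10_only"]],
              tab[["1_only"]], tab[["none"]]))
  if (!is.null(x$enrichment)) {
    sig <- x$enrichment[x$enrichment$significant, "target_class"]
    cat("enriched targets (p<0.05):",
        if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  }
  invisible(x)
}
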