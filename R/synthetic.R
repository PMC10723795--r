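#' Phenotype parameters for synthetic fields
#'
#' Parameter bundle for the synthetic field generator, which renders the four
#' nucleolar stress states seen under drug treatment:
#' \describe{
#'   \item{normal}{round nucleolar cores, GC marker concentrated in nucleoli.}
#'   \item{canonical_stress}{small peripheral FC caps (RNA Pol I inhibition):
#'     FC condenses, recruiting part of the diffuse nucleoplasmic FC pool,
#'     while about half of the GC marker disperses to the nucleoplasm.}
#'   \item{metabolic}{shrunken nucleoli with reduced GC content and little
#'     dispersal (growth-pathway suppression).}
#'   \item{dissolution}{FC extended into thin curvilinear strings (random-walk
#'     polylines, 2 px wide) with near-total GC dispersal (CDK inhibition).}
#' }
#' Intensities are split per nucleus into a uniform nucleoplasmic baseline
#' plus a fixed total "excess" placed on the nucleolar structures; the
#' generator's bookkeeping returns the exact noiseless per-compartment sums
#' and the analytic normality score they imply. Noise is Poisson photon noise
#' plus additive Gaussian read noise on top of a constant extracellular
#' offset.
#'
#' @param phenotype One of `"normal"`, `"canonical_stress"`, `"metabolic"`,
#'   `"dissolution"`.
#' @param n_nuclei Nuclei per field.
#' @param field_dim Field dimensions in pixels (rows, cols).
#' @param nucleus_radius_px,nucleus_jitter_px Nucleus radius and uniform
#'   jitter.
#' @param nucleoli_per_nucleus,nucleolus_radius_px Nucleolar geometry (ignored
#'   for `dissolution`, which uses strings).
#' @param fc_string_steps Random-walk steps per string (dissolution).
#' @param gc_dispersal_frac Fraction `f` of the GC excess relocated uniformly
#'   to the nucleoplasm.
#' @param fc_recruit_frac Fraction of the nucleoplasmic FC baseline pool
#'   condensed into the nucleolar structures (canonical stress).
#' @param gc_total,fc_total Per-nucleus total excess intensity of the GC and
#'   FC markers (arbitrary units).
#' @param gc_total_scale Scaling of `gc_total` (metabolic suppression).
#' @param gc_np_per_px,fc_np_per_px,dna_per_px Per-pixel baselines.
#' @param offset Constant extracellular background offset.
#' @param poisson,read_sd Noise model: Poisson resampling of the intensity and
#'   Gaussian read noise SD (set `poisson = FALSE`, `read_sd = 0` for
#'   noiseless fields).
#' @param seed Integer seed; identical parameters including the seed give
#'   bit-identical fields.
#' @return A list of class `phenotype_params`.
#' @export
phenotype_params <- function(phenotype = c("normal", "canonical_stress",
                                           "metabolic", "dissolution"),
                             n_nuclei = 5L,
                             field_dim = c(256L, 256L),
                             nucleus_radius_px = 20,
                             nucleus_jitter_px = 2,
                             nucleoli_per_nucleus = NULL,
                             nucleolus_radius_px = NULL,
                             fc_string_steps = 25L,
                             gc_dispersal_frac = NULL,
                             fc_recruit_frac = NULL,
                             gc_total = 30000,
                             fc_total = 22500,
                             gc_total_scale = NULL,
                             gc_np_per_px = 20,
                             fc_np_per_px = 30,
                             dna_per_px = 120,
                             offset = 8,
                             poisson = TRUE,
                             read_sd = 3,
                             seed = 1L) {
  phenotype <- match.arg(phenotype)
  def <- switch(phenotype,
    normal           = list(nno = 3L, rno = 4, f = 0.00, rec = 0.0, gsc = 1.0),
    canonical_stress = list(nno = 2L, rno = 3, f = 0.50, rec = 0.3, gsc = 1.0),
    metabolic        = list(nno = 2L, rno = 3, f = 0.10, rec = 0.0, gsc = 0.6),
    dissolution      = list(nno = 1L, rno = 3, f = 0.95, rec = 0.0, gsc = 1.0))
  p <- list(phenotype = phenotype,
            n_nuclei = as.integer(n_nuclei),
            field_dim = as.integer(field_dim),
            nucleus_radius_px = nucleus_radius_px,
            nucleus_jitter_px = nucleus_jitter_px,
            nucleoli_per_nucleus = if (is.null(nucleoli_per_nucleus)) def$nno else as.integer(nucleoli_per_nucleus),
            nucleolus_radius_px = if (is.null(nucleolus_radius_px)) def$rno else nucleolus_radius_px,
            fc_string_steps = as.integer(fc_string_steps),
            gc_dispersal_frac = if (is.null(gc_dispersal_frac)) def$f else gc_dispersal_frac,
            fc_recruit_frac = if (is.null(fc_recruit_frac)) def$rec else fc_recruit_frac,
            gc_total = gc_total, fc_total = fc_total,
            gc_total_scale = if (is.null(gc_total_scale)) def$gsc else gc_total_scale,
            gc_np_per_px = gc_np_per_px, fc_np_per_px = fc_np_per_px,
            dna_per_px = dna_per_px, offset = offset,
            poisson = isTRUE(poisson), read_sd = read_sd,
            seed = as.integer(seed))
  stopifnot(p$gc_dispersal_frac >= 0, p$gc_dispersal_frac <= 1,
            p$nucleus_radius_px > 0, p$nucleolus_radius_px > 0,
            p$n_nuclei >= 1, all(p$field_dim >= 16L))
  class(p) <- "phenotype_params"
  p
}

#' Segmentation parameters matched to the synthetic field scale
#'
#' Rolling-ball radii are set to 3x and 2.5x the nucleus radius: the marker-
#' channel ball must exceed the nucleus diameter, otherwise the nucleoplasmic
#' plateau itself is classified as background and the intensity bookkeeping
#' the score relies on is destroyed.
#'
#' @param params A [phenotype_params()].
#' @param ... Overrides passed to [seg_params()].
#' @export
synthetic_seg_params <- function(params, ...) {
  r <- params$nucleus_radius_px
  args <- list(nucleus_bg_radius = 3 * r, nucleolus_bg_radius = 2.5 * r,
               nucleus_area_range_px = c(floor(0.4 * pi * r^2),
                                         ceiling(6 * pi * r^2)))
  args[names(list(...))] <- list(...)
  do.call(seg_params, args)
}

disk_pixels <- function(dim, center, radius) {
  rr <- pmax(1L, floor(center[1L] - radius)):pmin(dim[1L], ceiling(center[1L] + radius))
  cc <- pmax(1L, floor(center[2L] - radius)):pmin(dim[2L], ceiling(center[2L] + radius))
  g <- expand.grid(r = rr, c = cc)
  g <- g[(g$r - center[1L])^2 + (g$c - center[2L])^2 <= radius^2, ]
  cbind(g$r, g$c)
}

# Random-walk polyline within `max_r` of `center`, dilated to 2 px width.
string_pixels <- function(dim, center, max_r, steps) {
  pos <- round(center)
  pts <- matrix(pos, ncol = 2L)
  moves <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  moves <- moves[rowSums(abs(moves)) > 0L, ]
  for (s in seq_len(steps)) {
    repeat {
      mv <- moves[sample.int(nrow(moves), 1L), ]
      cand <- pos + mv
      if (sum((cand - center)^2) <= max_r^2) break
    }
    pos <- cand
    pts <- rbind(pts, pos)
  }
  # dilate: each path pixel plus right/down/diag neighbour -> 2 px wide
  px <- rbind(pts, sweep(pts, 2L, c(0L, 1L), `+`),
              sweep(pts, 2L, c(1L, 0L), `+`), sweep(pts, 2L, c(1L, 1L), `+`))
  px <- px[px[, 1L] >= 1L & px[, 1L] <= dim[1L] &
           px[, 2L] >= 1L & px[, 2L] <= dim[2L], , drop = FALSE]
  unique(px)
}

#' Generate a ground-truthed synthetic field
#'
#' Renders one multichannel field (`dapi` = DNA counterstain, `ubf` = FC
#' marker, `ncl` = GC marker) for the given phenotype, together with the
#' ground-truth nucleus and nucleolus masks and the exact noiseless
#' per-compartment integrated intensities and analytic normality score of
#' every cell.
#'
#' @param params A [phenotype_params()].
#' @return A list: `field` (an [image_field()], noisy unless noise is
#'   disabled), `truth` with `nuclei`, `nucleoli` ([label_mask()]s), and
#'   `cells` (a [measure_cells()]-shaped data frame of noiseless intensities
#'   plus `analytic_score`), and `params`.
#' @export
generate_field <- function(params = phenotype_params()) {
  stopifnot(inherits(params, "phenotype_params"))
  with_seed(params$seed, generate_field_impl(params))
}

generate_field_impl <- function(p) {
  d <- p$field_dim
  margin <- p$nucleus_radius_px + p$nucleus_jitter_px + 4
  if (2 * margin >= min(d)) stopf("field too small for the requested nuclei")
  centers <- matrix(NA_real_, 0L, 2L)
  radii <- numeric(0L)
  tries <- 0L
  while (nrow(centers) < p$n_nuclei) {
    tries <- tries + 1L
    if (tries > 2000L) stopf("could not place %d non-overlapping nuclei", p$n_nuclei)
    r <- p$nucleus_radius_px + stats::runif(1L, -p$nucleus_jitter_px, p$nucleus_jitter_px)
    ctr <- c(stats::runif(1L, margin, d[1L] - margin),
             stats::runif(1L, margin, d[2L] - margin))
    if (nrow(centers) == 0L ||
        all(sqrt(rowSums(sweep(centers, 2L, ctr)^2)) > radii + r + 4)) {
      centers <- rbind(centers, ctr)
      radii <- c(radii, r)
    }
  }

  nuc_lab <- matrix(0L, d[1L], d[2L])
  no_lab <- matrix(0L, d[1L], d[2L])
  parent <- integer(0L)
  n_no <- 0L
  for (k in seq_len(p$n_nuclei)) {
    px <- disk_pixels(d, centers[k, ], radii[k])
    nuc_lab[px] <- k
    if (p$phenotype == "dissolution") {
      for (s in seq_len(p$nucleoli_per_nucleus)) {
        start <- centers[k, ] + stats::runif(2L, -radii[k] / 3, radii[k] / 3)
        spx <- string_pixels(d, start, radii[k] - 3, p$fc_string_steps)
        n_no <- n_no + 1L
        no_lab[spx] <- n_no
        parent[n_no] <- k
      }
    } else {
      placed <- matrix(NA_real_, 0L, 2L)
      lo_r <- if (p$phenotype == "canonical_stress") 0.5 * radii[k] else 0
      hi_r <- radii[k] - p$nucleolus_radius_px - 2
      t2 <- 0L
      while (nrow(placed) < p$nucleoli_per_nucleus) {
        t2 <- t2 + 1L
        if (t2 > 500L) stopf("could not place nucleoli inside nucleus %d", k)
        rho <- stats::runif(1L, lo_r, hi_r)
        th <- stats::runif(1L, 0, 2 * pi)
        ctr <- centers[k, ] + rho * c(cos(th), sin(th))
        if (nrow(placed) == 0L ||
            all(sqrt(rowSums(sweep(placed, 2L, ctr)^2)) > 2 * p$nucleolus_radius_px + 1)) {
          placed <- rbind(placed, ctr)
          opx <- disk_pixels(d, ctr, p$nucleolus_radius_px)
          n_no <- n_no + 1L
          no_lab[opx] <- n_no
          parent[n_no] <- k
        }
      }
    }
  }
  no_lab[nuc_lab == 0L] <- 0L  # clip strings to their nucleus surroundings
  # drop any nucleolus that ended up outside its nucleus entirely
  keep <- which(tabulate(no_lab[no_lab > 0L], nbins = n_no) > 0L)
  map <- integer(n_no); map[keep] <- seq_along(keep)
  no_lab[no_lab > 0L] <- map[no_lab[no_lab > 0L]]
  parent <- parent[keep]

  # noiseless signal channels (offset excluded from truth bookkeeping)
  dna <- matrix(0, d[1L], d[2L])
  fc <- matrix(0, d[1L], d[2L])
  gc <- matrix(0, d[1L], d[2L])
  K <- p$n_nuclei
  cells <- data.frame(nucleus_label = seq_len(K))
  for (col in c("nucleus_area_px", "nucleolar_area_px", "n_nucleoli"))
    cells[[col]] <- 0L
  f <- p$gc_dispersal_frac
  rec <- p$fc_recruit_frac
  Eg <- p$gc_total * p$gc_total_scale
  Ef <- p$fc_total
  for (k in seq_len(K)) {
    in_nuc <- nuc_lab == k
    # structures were placed inside and clipped to their own nucleus
    in_no <- in_nuc & no_lab > 0L
    A_nuc <- sum(in_nuc); A_no <- sum(in_no); A_np <- A_nuc - A_no
    if (A_no == 0L || A_np == 0L) stopf("degenerate nucleus geometry (label %d)", k)
    dna[in_nuc] <- p$dna_per_px
    # FC: baseline everywhere in nucleus; excess on structures; optional
    # recruitment of the nucleoplasmic baseline pool into the structures
    moved <- rec * p$fc_np_per_px * A_np
    fc[in_nuc & !in_no] <- p$fc_np_per_px * (1 - rec)
    fc[in_no] <- p$fc_np_per_px + (Ef + moved) / A_no
    # GC: baseline plus retained/dispersed excess
    gc[in_nuc & !in_no] <- p$gc_np_per_px + f * Eg / A_np
    gc[in_no] <- p$gc_np_per_px + (1 - f) * Eg / A_no
    cells$nucleus_area_px[k] <- A_nuc
    cells$nucleolar_area_px[k] <- A_no
    cells$n_nucleoli[k] <- sum(parent == k)
    cells[k, c("I_nucleus_dapi", "I_nucleolar_dapi")] <-
      c(p$dna_per_px * A_nuc, p$dna_per_px * A_no)
    cells[k, c("I_nucleus_ubf", "I_nucleolar_ubf")] <-
      c(p$fc_np_per_px * A_no + Ef + moved + p$fc_np_per_px * (1 - rec) * A_np,
        p$fc_np_per_px * A_no + Ef + moved)
    cells[k, c("I_nucleus_ncl", "I_nucleolar_ncl")] <-
      c(p$gc_np_per_px * A_nuc + Eg,
        p$gc_np_per_px * A_no + (1 - f) * Eg)
  }
  for (ch in c("dapi", "ubf", "ncl"))
    cells[[paste0("I_nucleoplasm_", ch)]] <-
      cells[[paste0("I_nucleus_", ch)]] - cells[[paste0("I_nucleolar_", ch)]]
  cells$analytic_score <-
    (cells$I_nucleolar_ncl / cells$I_nucleoplasm_ncl) /
    (cells$I_nucleolar_ubf / cells$I_nucleoplasm_ubf)
  class(cells) <- c("cell_measurements", "data.frame")

  noisify <- function(sig) {
    im <- sig + p$offset
    if (p$poisson) im <- matrix(stats::rpois(length(im), im), d[1L], d[2L])
    if (p$read_sd > 0) im <- im + stats::rnorm(length(im), 0, p$read_sd)
    im[im < 0] <- 0
    im
  }
  field <- image_field(list(dapi = noisify(dna), ubf = noisify(fc),
                            ncl = noisify(gc)),
                       field_id = sprintf("synthetic_%s_seed%d", p$phenotype, p$seed))
  list(field = field,
       truth = list(nuclei = label_mask(nuc_lab),
                    nucleoli = label_mask(no_lab, parent = parent),
                    cells = cells),
       params = p)
}

#' Generate a synthetic screening plate
#'
#' Simulates well-level and per-cell normality scores for a two-concentration
#' compound screen with vehicle wells and planted hits. Vehicle and non-hit
#' compound wells draw their true well score from `Normal(1, sigma_vehicle^2)`;
#' planted hits are shifted down by `effect_size_sd * sigma_vehicle` at the
#' high concentration and, for the "both" category, at the low concentration
#' too. Per-cell scores scatter around the well score with SD `sigma_cell`
#' and are split across `fields_per_well` fields. Defaults mirror the
#' screen's scale: 1180 compounds with 83 both-concentration and 69
#' high-only hits.
#'
#' @param n_compounds Number of library compounds.
#' @param n_vehicle Number of vehicle wells.
#' @param n_hits_both,n_hits_high_only Planted hit counts by category.
#' @param effect_size_sd Hit shift in vehicle-SD units.
#' @param sigma_vehicle Well-to-well SD of the vehicle score (score units).
#' @param sigma_cell Per-cell score SD.
#' @param cells_per_well,fields_per_well Sampling depth.
#' @param conc_low,conc_high Concentration labels.
#' @param target_classes Character vector of target classes to assign;
#'   planted hits are biased toward the first two classes so enrichment has
#'   signal to find.
#' @param seed Integer seed.
#' @return A list: `per_cell` (well_id, field_id, score), `layout`, `truth`
#'   (compound_id, true category).
#' @export
generate_plate <- function(n_compounds = 1180L, n_vehicle = 64L,
                           n_hits_both = 83L, n_hits_high_only = 69L,
                           effect_size_sd = 6, sigma_vehicle = 0.05,
                           sigma_cell = 0.15, cells_per_well = 200L,
                           fields_per_well = 4L,
                           conc_low = 1, conc_high = 10,
                           target_classes = c("HSP90", "mTOR", "PI3K",
                                              "Topoisomerase", "CDK", "DHFR",
                                              "Proteasome", "EGFR", "VEGFR",
                                              "BCL2", "PARP", "Other"),
                           seed = 1L) {
  stopifnot(n_hits_both + n_hits_high_only <= n_compounds, n_vehicle >= 2L)
  with_seed(seed, {
    cmpd <- sprintf("C%04d", seq_len(n_compounds))
    cat_true <- rep("none", n_compounds)
    hit_idx <- sample_int(seq_len(n_compounds), n_hits_both + n_hits_high_only)
    cat_true[hit_idx[seq_len(n_hits_both)]] <- "both"
    if (n_hits_high_only > 0L)
      cat_true[hit_idx[n_hits_both + seq_len(n_hits_high_only)]] <- "10_only"
    is_hit <- cat_true != "none"
    n_cls <- length(target_classes)
    probs_hit <- c(rep(3, min(2L, n_cls)), rep(1, max(0L, n_cls - 2L)))
    cls <- ifelse(is_hit,
                  sample_int(target_classes, n_compounds, replace = TRUE, prob = probs_hit),
                  sample_int(target_classes, n_compounds, replace = TRUE))

    shift <- effect_size_sd * sigma_vehicle
    mk_wells <- function(conc, shift_mask) {
      data.frame(well_id = sprintf("%s_%guM", cmpd, conc),
                 compound_id = cmpd, target_class = cls,
                 concentration_uM = conc, is_vehicle = FALSE,
                 true_score = stats::rnorm(n_compounds, 1, sigma_vehicle) -
                   ifelse(shift_mask, shift, 0))
    }
    wells <- rbind(
      mk_wells(conc_low, cat_true == "both"),
      mk_wells(conc_high, cat_true %in% c("both", "10_only")),
      data.frame(well_id = sprintf("VEH_%03d", seq_len(n_vehicle)),
                 compound_id = "DMSO", target_class = NA_character_,
                 concentration_uM = 0, is_vehicle = TRUE,
                 true_score = stats::rnorm(n_vehicle, 1, sigma_vehicle)))

    n_wells <- nrow(wells)
    per_field <- diff(round(seq(0, cells_per_well, length.out = fields_per_well + 1L)))
    per_cell <- data.frame(
      well_id = rep(wells$well_id, each = cells_per_well),
      field_id = rep(rep(sprintf("f%02d", seq_len(fields_per_well)), times = per_field),
                     times = n_wells),
      score = stats::rnorm(n_wells * cells_per_well,
                           rep(wells$true_score, each = cells_per_well),
                           sigma_cell))
    layout <- wells[, c("well_id", "compound_id", "target_class",
                        "concentration_uM", "is_vehicle")]
    truth <- data.frame(compound_id = cmpd, category = cat_true,
                        target_class = cls)
    list(per_cell = per_cell, layout = layout, truth = truth,
         sigma_vehicle = sigma_vehicle, sigma_cell = sigma_cell)
  })
}

#' Generate a synthetic FRAP trace
#'
#' Forward-simulates raw ROI / whole-nucleus / background intensities whose
#' double normalization recovers the two-component recovery model exactly.
#' Acquisition photobleaching multiplies both the ROI and the whole-nucleus
#' signal, so the whole-nucleus correction cancels it by construction.
#'
#' @param A1,k1,A2,k2,F0 Recovery model parameters (defaults give a composite
#'   half-time near 4.6 s, the scale reported for GC-marker recovery).
#' @param n_pre,n_post Pre- and post-bleach frame counts.
#' @param dt Frame interval (s).
#' @param acquisition_bleach Fractional signal loss per frame.
#' @param noise_sd Gaussian noise SD on the normalized scale.
#' @param bg,S_roi,S_whole Raw background level and pre-bleach signal
#'   amplitudes.
#' @param seed Integer seed.
#' @return A [frap_trace()]; attribute `truth` holds the generating
#'   parameters and the analytic composite `T_half` (solved by bisection on
#'   the true model, independently of any fit).
#' @export
generate_frap_trace <- function(A1 = 0.35, k1 = 0.40, A2 = 0.35, k2 = 0.04,
                                F0 = 0.30, n_pre = 5L, n_post = 60L, dt = 0.5,
                                acquisition_bleach = 0.01, noise_sd = 0.02,
                                bg = 50, S_roi = 1000, S_whole = 1500,
                                seed = 1L) {
  stopifnot(k1 > 0, k2 > 0, A1 >= 0, A2 >= 0, n_pre >= 1L, n_post >= 5L)
  with_seed(seed, {
    n <- n_pre + n_post
    t <- (seq_len(n) - 1L) * dt
    tp <- c(rep(0, n_pre), (seq_len(n_post) - 1L) * dt)
    Fm <- c(rep(1, n_pre), frap_model((seq_len(n_post) - 1L) * dt, F0, A1, k1, A2, k2))
    B <- (1 - acquisition_bleach)^(seq_len(n) - 1L)
    eps <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else rep(0, n)
    F_roi <- bg + B * S_roi * (Fm + eps)
    F_whole <- bg + B * S_whole
    trace <- frap_trace(t, F_roi, rep(bg, n), F_whole, bleach_index = n_pre + 1L)
    th_true <- t_half_numeric(list(F0 = F0, A1 = A1, k1 = k1, A2 = A2, k2 = k2))
    attr(trace, "truth") <- list(A1 = A1, k1 = k1, A2 = A2, k2 = k2, F0 = F0,
                                 T_half = th_true)
    trace
  })
}

#' Write a set of synthetic fields to disk
#'
#' Writes each field as a multipage 16-bit TIFF plus a manifest CSV
#' (`field_id`, `well_id`, `path`) and a ground-truth per-cell CSV, the
#' directory layout the scoring pipeline consumes.
#'
#' @param fields List of [generate_field()] results.
#' @param dir Output directory (created if needed).
#' @param well_ids Optional well id per field (default "W01").
#' @return The manifest path, invisibly.
#' @export
write_field_set <- function(fields, dir, well_ids = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(well_ids)) well_ids <- rep("W01", length(fields))
  rows <- lapply(seq_along(fields), function(i) {
    fid <- sprintf("field_%03d", i)
    fn <- paste0(fid, ".tif")
    write_field(fields[[i]]$field, file.path(dir, fn))
    tr <- fields[[i]]$truth$cells
    tr$field_id <- fid
    utils::write.csv(tr, file.path(dir, paste0(fid, "_truth.csv")),
                     row.names = FALSE)
    data.frame(field_id = fid, well_id = well_ids[i], path = fn)
  })
  man <- do.call(rbind, rows)
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest, row.names = FALSE)
  invisible(manifest)
}
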