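#' Segmentation parameters
#'
#' Parameters of the two-stage segmentation: nuclei from the DNA counterstain,
#' then nucleoli from the fibrillar-center (FC) marker within each nucleus.
#' Defaults follow the published high-content procedure: nuclei are thresholded
#' at 10\% of the background-subtracted image maximum; the FC channel is
#' smoothed with a 0.7 px Gaussian and thresholded per nucleus at 40\% of the
#' min-to-max intensity span; objects under 4 px are discarded as noise.
#' Rolling-ball radii are "large" for the DNA channel and "small" for marker
#' channels; both are in pixels and must be matched to the image scale (a
#' marker-channel ball smaller than a nucleus treats nucleoplasmic signal as
#' background).
#'
#' @param nucleus_bg_radius Rolling-ball radius for the DNA channel (px).
#' @param nucleolus_bg_radius Rolling-ball radius for marker channels (px).
#' @param nucleus_threshold_frac Nucleus threshold as a fraction of the
#'   background-subtracted image maximum.
#' @param blur_sigma Gaussian blur SD (px) applied to the FC channel before
#'   nucleolar thresholding. Masks only; intensities are measured unblurred.
#' @param nucleolus_threshold_frac Per-nucleus threshold as a fraction of the
#'   (max - min) FC intensity span within that nucleus.
#' @param min_nucleolus_area_px Minimum nucleolus area in pixels.
#' @param nucleus_area_range_px Inclusive `[min, max]` nucleus area in pixels.
#' @param connectivity Pixel connectivity for component labeling, 4 or 8.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(nucleus_bg_radius = 50,
                       nucleolus_bg_radius = 10,
                       nucleus_threshold_frac = 0.10,
                       blur_sigma = 0.7,
                       nucleolus_threshold_frac = 0.40,
                       min_nucleolus_area_px = 4L,
                       nucleus_area_range_px = c(1000, 30000),
                       connectivity = 8L) {
  stopifnot(nucleus_threshold_frac > 0, nucleus_threshold_frac < 1,
            nucleolus_threshold_frac > 0, nucleolus_threshold_frac < 1,
            min_nucleolus_area_px >= 1,
            length(nucleus_area_range_px) == 2L,
            nucleus_area_range_px[1L] < nucleus_area_range_px[2L],
            connectivity %in% c(4L, 8L),
            nucleus_bg_radius >= 1, nucleolus_bg_radius >= 1,
            blur_sigma > 0)
  structure(list(nucleus_bg_radius = nucleus_bg_radius,
                 nucleolus_bg_radius = nucleolus_bg_radius,
                 nucleus_threshold_frac = nucleus_threshold_frac,
                 blur_sigma = blur_sigma,
                 nucleolus_threshold_frac = nucleolus_threshold_frac,
                 min_nucleolus_area_px = as.integer(min_nucleolus_area_px),
                 nucleus_area_range_px = nucleus_area_range_px,
                 connectivity = as.integer(connectivity)),
            class = "seg_params")
}

#' Label mask
#'
#' Integer label image (0 = background, k > 0 = object k, labels consecutive
#' from 1) with an optional `parent` map assigning each nucleolus label to its
#' nucleus label.
#'
#' @param labels Integer matrix of labels.
#' @param parent Optional integer vector, `parent[k]` = nucleus label of
#'   nucleolus k.
#' @export
label_mask <- function(labels, parent = NULL) {
  storage.mode(labels) <- "integer"
  u <- sort(unique(labels[labels > 0L]))
  if (length(u) && !identical(u, seq_along(u)))
    stopf("labels must be consecutive positive integers starting at 1")
  if (!is.null(parent)) {
    parent <- as.integer(parent)
    if (length(parent) != length(u))
      stopf("`parent` must have one entry per label")
  }
  structure(list(labels = labels, parent = parent), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px, %d object(s)%s\n",
              nrow(x$labels), ncol(x$labels), n_objects(x),
              if (is.null(x$parent)) "" else " (with parent map)"))
  invisible(x)
}

#' @rdname label_mask
#' @param x A `label_mask`.
#' @export
n_objects <- function(x) {
  l <- if (inherits(x, "label_mask")) x$labels else x
  max(0L, max(l))
}

# Connected-component labeling. EBImage::bwlabel is 4-connected; for
# 8-connectivity, diagonally adjacent 4-components are merged by union-find.
label_components <- function(mask, connectivity = 8L) {
  storage.mode(mask) <- "double"
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 8L && max(lab) > 1L) {
    n <- nrow(lab); m <- ncol(lab)
    a1 <- lab[-n, -m]; b1 <- lab[-1L, -1L]   # down-right diagonal
    a2 <- lab[-1L, -m]; b2 <- lab[-n, -1L]   # up-right diagonal
    pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                   cbind(as.vector(a2), as.vector(b2)))
    pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
    if (nrow(pairs)) {
      parent <- seq_len(max(lab))
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_along(parent), find, integer(1L))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  relabel_consecutive(lab)
}

# Relabel to consecutive 1..K preserving first-occurrence (column-major) order.
relabel_consecutive <- function(lab) {
  u <- unique(lab[lab > 0L])
  if (!length(u)) return(lab)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

#' Segment nuclei from the DNA counterstain
#'
#' Rolling-ball background subtraction, global threshold at
#' `nucleus_threshold_frac` of the subtracted image maximum (pixels equal to
#' the threshold are foreground), hole filling, removal of components touching
#' any image border or with area outside `nucleus_area_range_px`, and
#' consecutive relabeling. A constant image yields an explicit empty mask.
#'
#' @param dna_image Numeric matrix (DNA channel).
#' @param params A [seg_params()].
#' @return A [label_mask()] of nuclei.
#' @export
segment_nuclei <- function(dna_image, params = seg_params()) {
  stopifnot(inherits(params, "seg_params"))
  bg <- subtract_background(dna_image, params$nucleus_bg_radius)
  mx <- max(bg)
  if (mx <= 0) return(label_mask(matrix(0L, nrow(dna_image), ncol(dna_image))))
  fg <- bg >= params$nucleus_threshold_frac * mx
  lab <- label_components(fg, params$connectivity)
  if (max(lab) > 0L) {
    lab <- matrix(as.integer(EBImage::fillHull(lab)), nrow(lab), ncol(lab))
    border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
    border <- border[border > 0L]
    areas <- tabulate(lab, nbins = max(lab))
    drop <- union(border,
                  which(areas < params$nucleus_area_range_px[1L] |
                        areas > params$nucleus_area_range_px[2L]))
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab <- relabel_consecutive(lab)
  }
  label_mask(lab)
}

#' Segment nucleoli from the FC marker within each nucleus
#'
#' The marker channel is background-subtracted (small-radius rolling ball) and
#' smoothed with a Gaussian of SD `blur_sigma`. Within each nucleus
#' independently, pixels at or above `min + nucleolus_threshold_frac *
#' (max - min)` of that nucleus's smoothed intensities are foreground;
#' connected components are clipped to the nucleus and components smaller
#' than `min_nucleolus_area_px` are discarded. A nucleus with constant marker
#' signal simply contributes no nucleoli. The blurred image defines masks
#' only; measure intensities on the unblurred channel.
#'
#' @param fc_image Numeric matrix (FC marker channel).
#' @param nuclei A [label_mask()] from [segment_nuclei()].
#' @param params A [seg_params()].
#' @return A [label_mask()] with a `parent` map to nucleus labels.
#' @export
segment_nucleoli <- function(fc_image, nuclei, params = seg_params()) {
  stopifnot(inherits(nuclei, "label_mask"), inherits(params, "seg_params"))
  if (!identical(dim(fc_image), dim(nuclei$labels)))
    stopf("image and nucleus mask dimensions differ")
  img <- subtract_background(fc_image, params$nucleolus_bg_radius)
  img <- gaussian_blur(img, params$blur_sigma)
  nl <- nuclei$labels
  out <- matrix(0L, nrow(nl), ncol(nl))
  parent <- integer(0L)
  nxt <- 0L
  for (k in seq_len(n_objects(nuclei))) {
    inside <- nl == k
    v <- img[inside]
    lo <- min(v); hi <- max(v)
    if (hi <= lo) next
    thr <- lo + params$nucleolus_threshold_frac * (hi - lo)
    fg <- inside & img >= thr
    lab <- label_components(fg, params$connectivity)
    if (max(lab) == 0L) next
    areas <- tabulate(lab, nbins = max(lab))
    keep <- which(areas >= params$min_nucleolus_area_px)
    for (j in keep) {
      nxt <- nxt + 1L
      out[lab == j] <- nxt
      parent[nxt] <- k
    }
  }
  label_mask(out, parent = parent)
}

# Gaussian smoothing via EBImage (clamped to >= 0; filtering can produce tiny
# negative ringing at borders).
gaussian_blur <- function(image, sigma) {
  out <- EBImage::gblur(EBImage::Image(image), sigma = sigma)
  out <- matrix(EBImage::imageData(out), nrow(image), ncol(image))
  out[out < 0] <- 0
  out
}

#' Export per-object properties of a label mask
#'
#' @param mask A [label_mask()].
#' @return A data frame with `label`, `parent` (NA if no parent map),
#'   `area_px`, and 0-based centroid coordinates `centroid_row`,
#'   `centroid_col`.
#' @export
mask_table <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  K <- n_objects(mask)
  if (K == 0L)
    return(data.frame(label = integer(0), parent = integer(0),
                      area_px = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0)))
  l <- mask$labels
  idx <- which(l > 0L)
  lab <- l[idx]
  rows <- (idx - 1L) %% nrow(l)          # 0-based
  cols <- (idx - 1L) %/% nrow(l)
  data.frame(
    label = seq_len(K),
    parent = if (is.null(mask$parent)) NA_integer_ else mask$parent,
    area_px = tabulate(lab, nbins = K),
    centroid_row = as.numeric(tapply(rows, lab, mean)),
    centroid_col = as.numeric(tapply(cols, lab, mean)))
}
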