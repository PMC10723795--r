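#' Multichannel image field
#'
#' An `image_field` holds co-registered 2D intensity channels for one imaged
#' field of view: a DNA counterstain plus one or more nucleolar marker
#' channels. All downstream segmentation and scoring operates on this
#' container. Channels are numeric matrices indexed `[row, column]` (0-based
#' pixel coordinates are used only in exported tables); intensities must be
#' finite and non-negative.
#'
#' @param channels Named list of numeric matrices, all with identical
#'   dimensions.
#' @param pixel_size_um Optional physical pixel size in micrometres.
#' @param field_id,well_id Optional identifiers carried through to output
#'   tables.
#' @return An object of class `image_field`.
#' @examples
#' f <- image_field(list(dapi = matrix(0, 8, 8), ubf = matrix(1, 8, 8)))
#' dim(f)
#' @export
image_field <- function(channels, pixel_size_um = NULL, field_id = NULL,
                        well_id = NULL) {
  if (!is.list(channels) || length(channels) == 0L)
    stopf("`channels` must be a non-empty named list of matrices")
  nm <- names(channels)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stopf("channels must have unique non-empty names")
  channels <- lapply(channels, function(ch) {
    if (!is.matrix(ch) || !is.numeric(ch))
      stopf("each channel must be a numeric matrix")
    storage.mode(ch) <- "double"
    if (any(!is.finite(ch))) stopf("channel intensities must be finite")
    if (any(ch < 0)) stopf("channel intensities must be >= 0")
    ch
  })
  d <- dim(channels[[1L]])
  for (ch in channels) if (!identical(dim(ch), d))
    stopf("all channels must share identical dimensions")
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um,
         field_id = field_id, well_id = well_id),
    class = "image_field")
}

#' @export
dim.image_field <- function(x) dim(x$channels[[1L]])

#' @export
print.image_field <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_field%s> %d x %d px, channels: %s\n",
              if (is.null(x$field_id)) "" else paste0(" ", x$field_id),
              d[1L], d[2L], paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

get_channel <- function(field, name) {
  if (!name %in% names(field$channels))
    stopf("channel '%s' not present (have: %s)", name,
          paste(names(field$channels), collapse = ", "))
  field$channels[[name]]
}

#' Read a multichannel TIFF into an image field
#'
#' Reads a single- or multi-page TIFF and names the requested pages as
#' channels. Pixel values are rescaled back to integer counts (the `tiff`
#' package reads into \code{[0, 1]}).
#'
#' @param path Path to a TIFF file.
#' @param channel_map Named integer vector or list mapping channel name to
#'   1-based page index, e.g. `c(dapi = 1, ubf = 2, ncl = 3)`.
#' @param pixel_size_um,field_id,well_id Passed to [image_field()].
#' @return An [image_field()].
#' @export
read_field <- function(path, channel_map, pixel_size_um = NULL,
                       field_id = NULL, well_id = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  idx <- unlist(channel_map)
  if (is.null(names(idx)) || any(!nzchar(names(idx))))
    stopf("`channel_map` must be named (channel name -> page index)")
  if (any(idx < 1L | idx > length(pages)))
    stopf("channel_map index out of range: file has %d page(s)", length(pages))
  chans <- lapply(idx, function(i) {
    m <- pages[[i]]
    if (length(dim(m)) == 3L) m <- m[, , 1L]  # tolerate grayscale-as-RGB
    if (!is.numeric(m)) stopf("non-numeric pixel data in %s", path)
    m
  })
  names(chans) <- names(idx)
  image_field(chans, pixel_size_um = pixel_size_um,
              field_id = if (is.null(field_id)) basename(path) else field_id,
              well_id = well_id)
}

#' Write an image field as a multi-page 16-bit TIFF
#'
#' One page per channel, in channel order. Intensities are rounded and clamped
#' to the 16-bit range, so integer-valued fields round-trip bit-exactly
#' through [read_field()].
#'
#' @param field An [image_field()].
#' @param path Output path.
#' @return `path`, invisibly. The channel order defines the page order.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "image_field"))
  pages <- lapply(field$channels, function(ch) {
    m <- round(ch)
    m[m < 0] <- 0
    m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Project a z-stack to a single plane
#'
#' @param stack A 3D numeric array (row, column, plane) or a list of 2D
#'   matrices. A single-plane input is returned unchanged.
#' @param method `"sum"` (used for transcription-labeling readouts) or
#'   `"max"` (used for live-imaging stacks).
#' @return A 2D matrix.
#' @export
project_stack <- function(stack, method = c("sum", "max")) {
  method <- match.arg(method)
  if (is.list(stack)) {
    d <- dim(stack[[1L]])
    for (m in stack) if (!identical(dim(m), d))
      stopf("all planes must share dimensions")
    stack <- array(unlist(stack), dim = c(d, length(stack)))
  }
  if (is.matrix(stack)) return(stack)
  if (!(is.array(stack) && length(dim(stack)) == 3L))
    stopf("`stack` must be a 2D matrix, 3D array, or list of matrices")
  if (dim(stack)[3L] < 1L) stopf("empty stack")
  if (dim(stack)[3L] == 1L) return(stack[, , 1L])
  switch(method,
         sum = apply(stack, c(1L, 2L), sum),
         max = apply(stack, c(1L, 2L), max))
}

#' Read a manifest of fields
#'
#' Multi-field acquisitions are directories of TIFFs listed in a manifest CSV
#' with columns `field_id`, `well_id`, `path` (relative paths resolved against
#' the manifest's directory).
#'
#' @param manifest_path Path to the manifest CSV.
#' @param channel_map As in [read_field()].
#' @return A list of [image_field()] objects.
#' @export
read_manifest <- function(manifest_path, channel_map) {
  if (!file.exists(manifest_path)) stopf("manifest not found: %s", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("field_id", "well_id", "path")
  if (!all(need %in% names(man)))
    stopf("manifest must have columns: %s", paste(need, collapse = ", "))
  if (nrow(man) == 0L) stopf("manifest is empty: %s", manifest_path)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    read_field(p, channel_map, field_id = man$field_id[i],
               well_id = man$well_id[i])
  })
}
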