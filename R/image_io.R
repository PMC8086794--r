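#' Multi-channel fluorescence image
#'
#' Container for a single 2-D multi-channel micrograph: one integer intensity
#' matrix per named channel, plus the physical pixel size. This is the unit
#' every stage of the pipeline consumes. Pixels are indexed `(row, col)` with
#' the origin at the top-left.
#'
#' @param channels Named list of numeric matrices (intensities, typically
#'   16-bit integers). All matrices must share dimensions; names must be
#'   unique (e.g. `"laminin"`, `"igg"`, `"dapi"`).
#' @param pixel_size_um Positive scalar, micrometres per pixel (square pixels).
#' @param source_name Text identifier used as `image_name` in result tables.
#' @return An object of class `mc_image`.
#' @examples
#' img <- mc_image(list(laminin = matrix(0L, 8, 8), igg = matrix(0L, 8, 8)),
#'                 pixel_size_um = 0.346, source_name = "demo")
#' dim(get_channel(img, "igg"))
#' @export
mc_image <- function(channels, pixel_size_um, source_name = "image") {
  if (!is.list(channels) || length(channels) == 0 ||
      is.null(names(channels)) || any(names(channels) == "")) {
    abort("`channels` must be a non-empty named list of matrices.")
  }
  if (anyDuplicated(names(channels))) abort("channel names must be unique.")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1)))) {
    abort("every channel must be a matrix.")
  }
  d0 <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, d0), logical(1)))) {
    abort("all channels must share identical height x width.")
  }
  if (any(vapply(channels, function(m) any(m < 0), logical(1)))) {
    abort("intensities must be non-negative.")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a positive scalar.")
  }
  structure(
    list(channels = channels, pixel_size_um = as.numeric(pixel_size_um),
         source_name = as.character(source_name)),
    class = "mc_image"
  )
}

#' @export
print.mc_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<mc_image> %s: %d x %d px, %.4g um/px, channels: %s\n",
              x$source_name, d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.mc_image <- function(x) dim(x$channels[[1]])

#' Extract one channel of a multi-channel image
#'
#' @param image An [mc_image].
#' @param channel Channel name.
#' @return The intensity matrix of that channel.
#' @export
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "mc_image"))
  if (!channel %in% names(image$channels)) {
    abort(sprintf("channel '%s' not present (have: %s).", channel,
                  paste(names(image$channels), collapse = ", ")))
  }
  image$channels[[channel]]
}

#' Z-stack of multi-channel images
#'
#' @param slices List of [mc_image] objects with identical geometry and
#'   channel names, ordered by z.
#' @param z_step_um Positive scalar, micrometres between consecutive slices.
#' @return An object of class `zstack`.
#' @export
zstack <- function(slices, z_step_um = 1) {
  if (!is.list(slices) || length(slices) < 1) abort("need at least one slice.")
  if (!all(vapply(slices, inherits, logical(1), "mc_image"))) {
    abort("all slices must be mc_image objects.")
  }
  nm <- names(slices[[1]]$channels)
  d0 <- dim(slices[[1]])
  ok <- vapply(slices, function(s)
    identical(names(s$channels), nm) && identical(dim(s), d0), logical(1))
  if (!all(ok)) abort("slices must be channel- and geometry-compatible.")
  if (!is.numeric(z_step_um) || z_step_um <= 0) {
    abort("`z_step_um` must be positive.")
  }
  structure(list(slices = slices, z_step_um = z_step_um), class = "zstack")
}

#' Maximum-intensity projection of a z-stack
#'
#' Flattens a 3-D acquisition to 2-D: each output pixel, per channel, is the
#' maximum over z of that pixel. Metadata (pixel size, source name) is carried
#' from the first slice.
#'
#' @param stack A [zstack].
#' @return An [mc_image].
#' @export
max_intensity_projection <- function(stack) {
  stopifnot(inherits(stack, "zstack"))
  first <- stack$slices[[1]]
  chans <- lapply(names(first$channels), function(ch) {
    Reduce(pmax, lapply(stack$slices, function(s) s$channels[[ch]]))
  })
  names(chans) <- names(first$channels)
  mc_image(chans, first$pixel_size_um, first$source_name)
}

#' Read a multi-channel TIFF image
#'
#' Reads a single- or multi-page TIFF in which pages are channels, in the
#' order given by `channel_names`. Original bit depth is preserved (pixel
#' values are returned as the integers stored in the file). Physical pixel
#' size is supplied by the caller, not parsed from vendor metadata.
#'
#' @param path Path to a TIFF file.
#' @param channel_names Character vector naming the pages, in file order.
#' @param pixel_size_um Micrometres per pixel (square pixels).
#' @param source_name Identifier for result tables; defaults to the file name.
#' @return An [mc_image].
#' @export
read_image <- function(path, channel_names, pixel_size_um,
                       source_name = basename(path)) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) != length(channel_names)) {
    abort(sprintf("file has %d page(s) but %d channel name(s) were declared.",
                  length(pages), length(channel_names)))
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # tolerate grey stored as RGB
    p
  })
  names(pages) <- channel_names
  mc_image(pages, pixel_size_um, source_name)
}

#' Read a z-stack from a multi-page TIFF
#'
#' Pages must contain `n_z * length(channel_names)` planes. Two page layouts
#' occur in the wild; both are supported via `order`.
#'
#' @inheritParams read_image
#' @param n_z Number of z-slices.
#' @param z_step_um Micrometres between slices.
#' @param order `"z_then_channel"` (default): all z of channel 1, then all z
#'   of channel 2, ... `"channel_then_z"`: all channels of slice 1, then
#'   slice 2, ...
#' @return A [zstack].
#' @export
read_zstack <- function(path, channel_names, pixel_size_um, n_z,
                        z_step_um = 1,
                        order = c("z_then_channel", "channel_then_z"),
                        source_name = basename(path)) {
  order <- match.arg(order)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  nc <- length(channel_names)
  if (length(pages) != n_z * nc) {
    abort(sprintf("file has %d page(s); expected n_z * n_channels = %d.",
                  length(pages), n_z * nc))
  }
  page_at <- function(z, c) {
    if (order == "z_then_channel") pages[[(c - 1) * n_z + z]]
    else pages[[(z - 1) * nc + c]]
  }
  slices <- lapply(seq_len(n_z), function(z) {
    chans <- lapply(seq_len(nc), function(c) page_at(z, c))
    names(chans) <- channel_names
    mc_image(chans, pixel_size_um, source_name)
  })
  zstack(slices, z_step_um)
}

#' Write a multi-channel image as a multi-page 16-bit TIFF
#'
#' @param image An [mc_image].
#' @param path Output path.
#' @param bits Bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 16L) {
  stopifnot(inherits(image, "mc_image"))
  scale <- 2^bits - 1
  pages <- lapply(image$channels, function(m) clamp(m, 0, scale) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Sparse annotation maps
#'
#' A sparse label map is an integer matrix over `{0, 1, 2}`: 0 = unlabeled,
#' 1 = object (vessel), 2 = background. For training, at least one pixel of
#' each of classes 1 and 2 must be present somewhere in the training set.
#' Maps are stored on disk as single-channel 8-bit TIFFs with the same code.
#'
#' @param labels Integer matrix over `{0, 1, 2}`.
#' @return The validated matrix, classed `label_map`.
#' @export
label_map <- function(labels) {
  if (!is.matrix(labels)) abort("`labels` must be a matrix.")
  if (!all(labels %in% c(0L, 1L, 2L))) {
    abort("label values must be in {0 = unlabeled, 1 = object, 2 = background}.")
  }
  storage.mode(labels) <- "integer"
  structure(labels, class = c("label_map", "matrix", "array"))
}

#' @rdname label_map
#' @param path TIFF path.
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  label_map(m)
}

#' @rdname label_map
#' @param labels,path Label matrix and output TIFF path.
#' @export
write_label_map <- function(labels, path) {
  labels <- label_map(unclass(labels))
  tiff::writeTIFF(labels / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write and read measurement tables
#'
#' One header row plus one row per image; numeric cells are written
#' unformatted (no thousands separators) so the file round-trips exactly.
#'
#' @param records A data frame of measurement records (see [analyze_image]).
#' @param path CSV path.
#' @return `path` invisibly (write) or a tibble (read).
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
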