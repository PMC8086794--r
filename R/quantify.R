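#' Analysis configuration
#'
#' Settings for turning a class map plus the IgG channel into masks and
#' measurements. The defaults reproduce the documented workflow exactly:
#' vessel class hole-filled; extravascular class eroded by 1 px (a one-pixel
#' buffer around vessels, not hole-filled); IgG smoothed with a 3 x 3 mean
#' filter, cut at the configured intensity threshold with 0% tolerance;
#' regions below about 5 square micrometres discarded as unspecific signal.
#'
#' @param igg_threshold Intensity threshold for extravascular IgG, in the
#'   units of the IgG channel (see [select_threshold] for the recommended
#'   midpoint rule, e.g. 3,500 for background <= 2,000 and signal ~5,000).
#' @param threshold_tolerance_pct Percentage by which the effective threshold
#'   is relaxed downward; 0 (default) is an exact cut.
#' @param erode_count Erosion iterations applied to the extravascular class
#'   (3 x 3 square element); default 1 — the perivascular buffer.
#' @param lowpass_size Odd size of the uniform mean filter applied to the
#'   IgG channel before thresholding; 1 disables smoothing.
#' @param min_region_area_um2 Minimum connected-region area kept in the IgG
#'   mask, in square micrometres; converted to pixels by
#'   `ceiling(area / pixel_size^2)`.
#' @param igg_channel,laminin_channel Channel names.
#' @param smoothness Potts pairwise weight handed to [regularize] when a
#'   model prediction is regularized inside [analyze_image].
#' @param intensity_source `"raw"` (default) sums the unsmoothed IgG channel
#'   over the IgG mask so reported intensities remain physical;
#'   `"smoothed"` sums the low-passed channel instead.
#' @return An `analysis_config`.
#' @export
analysis_config <- function(igg_threshold = 3500,
                            threshold_tolerance_pct = 0,
                            erode_count = 1L,
                            lowpass_size = 3L,
                            min_region_area_um2 = 5,
                            igg_channel = "igg",
                            laminin_channel = "laminin",
                            smoothness = 1.0,
                            intensity_source = c("raw", "smoothed")) {
  intensity_source <- match.arg(intensity_source)
  lowpass_size <- as.integer(lowpass_size)
  if (lowpass_size < 1L || lowpass_size %% 2L == 0L) {
    abort("`lowpass_size` must be odd and >= 1.")
  }
  if (erode_count < 0) abort("`erode_count` must be non-negative.")
  if (min_region_area_um2 < 0) abort("`min_region_area_um2` must be >= 0.")
  structure(list(igg_threshold = igg_threshold,
                 threshold_tolerance_pct = threshold_tolerance_pct,
                 erode_count = as.integer(erode_count),
                 lowpass_size = lowpass_size,
                 min_region_area_um2 = min_region_area_um2,
                 igg_channel = igg_channel, laminin_channel = laminin_channel,
                 smoothness = smoothness,
                 intensity_source = intensity_source),
            class = "analysis_config")
}

#' Midpoint threshold selection
#'
#' The recommended rule for choosing the IgG intensity threshold from a line
#' profile: halfway between the maximum background intensity and the typical
#' IgG signal intensity. With background never exceeding 2,000 and signal
#' around 5,000 this gives 3,500.
#'
#' @param background_max Maximum background intensity observed.
#' @param signal_typical Typical IgG signal intensity.
#' @return The midpoint `(background_max + signal_typical) / 2`.
#' @examples
#' select_threshold(2000, 5000)  # 3500
#' @export
select_threshold <- function(background_max, signal_typical) {
  if (background_max < 0) abort("`background_max` must be >= 0.")
  if (signal_typical < background_max) {
    abort("`signal_typical` must be >= `background_max`.")
  }
  (background_max + signal_typical) / 2
}

#' Morphological mask operations
#'
#' `fill_holes()` sets to foreground every background component (4-connected)
#' that does not touch the frame border; foreground is never altered.
#' `erode_mask()` applies `count` iterations of erosion with a 3 x 3 square
#' structuring element, treating pixels outside the frame as background.
#'
#' @param mask Logical matrix.
#' @return Logical matrix.
#' @export
fill_holes <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  fill_holes_cpp(mask)
}

#' @rdname fill_holes
#' @param count Non-negative number of erosion iterations.
#' @export
erode_mask <- function(mask, count = 1L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  count <- as.integer(count)
  if (count < 0) abort("`count` must be non-negative.")
  if (count == 0) return(mask)
  erode_cpp(mask, count)
}

#' Threshold the IgG channel within the extravascular compartment
#'
#' Smooths the IgG channel (uniform `lowpass_size` mean filter), keeps pixels
#' at or above the effective threshold that lie inside the extravascular
#' mask, then removes 8-connected regions smaller than
#' `ceiling(min_region_area_um2 / pixel_size_um^2)` pixels.
#'
#' @param igg_channel Intensity matrix.
#' @param extravascular_mask Logical matrix, same geometry.
#' @param config An [analysis_config].
#' @param pixel_size_um Micrometres per pixel.
#' @return Logical IgG mask.
#' @export
segment_igg <- function(igg_channel, extravascular_mask, config,
                        pixel_size_um) {
  stopifnot(inherits(config, "analysis_config"),
            identical(dim(igg_channel), dim(extravascular_mask)))
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be positive.")
  }
  smoothed <- lowpass(igg_channel, config$lowpass_size)
  thr <- config$igg_threshold * (1 - config$threshold_tolerance_pct / 100)
  mask <- (smoothed >= thr) & extravascular_mask
  min_px <- as.integer(ceiling(config$min_region_area_um2 / pixel_size_um^2))
  if (min_px > 1L && any(mask)) {
    lab <- label_components_cpp(mask, 8L)
    sizes <- tabulate(lab[lab > 0L])
    keep <- sizes >= min_px
    mask <- mask & matrix(lab > 0L & keep[pmax(lab, 1L)],
                          nrow(mask), ncol(mask))
  }
  mask
}

#' Quantify one image given a class map
#'
#' The measurement core, separated from classification so that it can also
#' run on ground-truth class maps. Masks follow the documented analysis
#' design: `vessel_mask` is the hole-filled object class; the
#' `extravascular_mask` is the background class eroded `erode_count` times
#' (no hole filling), leaving a buffer rim that belongs to neither mask;
#' `igg_mask` is the thresholded, region-filtered IgG subset of the
#' extravascular compartment. Intensity sums are taken over the raw IgG
#' channel by default.
#'
#' @param image An [mc_image] with the configured channels.
#' @param cmap A [class_map] for the vessel stain.
#' @param config An [analysis_config].
#' @return List with `result` (a `segmentation_result`: `vessel_mask`,
#'   `extravascular_mask`, `igg_mask`) and `record` (one-row tibble with
#'   `image_name`, `vessel_area_um2`, `vessel_area_pct`, `frame_area_um2`,
#'   `igg_intensity_sum`, `igg_pixel_count`).
#' @export
quantify_classmap <- function(image, cmap, config = analysis_config()) {
  stopifnot(inherits(image, "mc_image"), inherits(cmap, "class_map"),
            inherits(config, "analysis_config"))
  if (!identical(dim(image), dim(unclass(cmap)))) {
    abort("class map geometry does not match the image.")
  }
  obj <- object_mask(cmap)
  vessel_mask <- fill_holes(obj)
  extravascular_mask <- erode_mask(!obj, config$erode_count)
  igg <- get_channel(image, config$igg_channel)
  igg_mask <- segment_igg(igg, extravascular_mask, config,
                          image$pixel_size_um)
  px_area <- image$pixel_size_um^2
  frame_area <- length(igg) * px_area
  src <- if (config$intensity_source == "raw") igg
         else lowpass(igg, config$lowpass_size)
  record <- tibble(
    image_name = image$source_name,
    vessel_area_um2 = sum(vessel_mask) * px_area,
    vessel_area_pct = 100 * sum(vessel_mask) / length(igg),
    frame_area_um2 = frame_area,
    igg_intensity_sum = sum(src[igg_mask]),
    igg_pixel_count = sum(igg_mask))
  result <- structure(
    list(vessel_mask = vessel_mask, extravascular_mask = extravascular_mask,
         igg_mask = igg_mask,
         provenance = list(config = config, image = image$source_name)),
    class = "segmentation_result")
  list(result = result, record = record)
}

#' Segment and quantify one image
#'
#' The full per-image pipeline: classify the vessel-stain channel with the
#' trained model, regularize into a class map, then measure vessel area and
#' extravascular IgG via [quantify_classmap].
#'
#' @param image An [mc_image] containing both configured channels.
#' @param model A trained `segmenter_model`.
#' @param config An [analysis_config].
#' @return As [quantify_classmap].
#' @export
analyze_image <- function(image, model, config = analysis_config()) {
  stopifnot(inherits(model, "segmenter_model"))
  pred <- predict(model, image, channel = config$laminin_channel)
  cmap <- regularize(pred$prob, smoothness = config$smoothness)
  out <- quantify_classmap(image, cmap, config)
  out$result$provenance$model_seed <- model$training_seed
  out$result$prob <- pred$prob
  out$result$confidence <- pred$confidence
  out
}

#' Batch analysis over many images
#'
#' Runs [analyze_image] over a list of images or TIFF paths, order-preserving.
#' A failure on one image is caught, logged with a warning, and reported in
#' the `failures` attribute; the remaining images are still analyzed.
#'
#' @param images List of [mc_image] objects, or a character vector of TIFF
#'   paths (read with `channel_names` and `pixel_size_um`).
#' @param model A trained `segmenter_model`.
#' @param config An [analysis_config].
#' @param channel_names,pixel_size_um Used only when `images` are paths.
#' @return A tibble with one row per successfully analyzed image, with a
#'   `failures` attribute (tibble of `image`, `error`).
#' @export
batch_analyze <- function(images, model, config = analysis_config(),
                          channel_names = c("laminin", "igg"),
                          pixel_size_um = 0.346) {
  if (length(images) == 0) abort("empty image manifest.")
  if (inherits(images, "mc_image")) images <- list(images)
  rows <- list()
  fails <- list()
  for (i in seq_along(images)) {
    item <- images[[i]]
    nm <- if (is.character(item)) item
          else item$source_name
    rec <- tryCatch({
      img <- if (is.character(item)) {
        read_image(item, channel_names, pixel_size_um)
      } else item
      analyze_image(img, model, config)$record
    }, error = function(e) {
      warn(sprintf("image '%s' failed: %s", nm, conditionMessage(e)))
      fails[[length(fails) + 1L]] <<- tibble(image = nm,
                                             error = conditionMessage(e))
      NULL
    })
    if (!is.null(rec)) rows[[length(rows) + 1L]] <- rec
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    tibble(image_name = character(), vessel_area_um2 = numeric(),
           vessel_area_pct = numeric(), frame_area_um2 = numeric(),
           igg_intensity_sum = numeric(), igg_pixel_count = integer())
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else
    tibble(image = character(), error = character())
  out
}

#' Coefficient of variation, in percent
#'
#' The reproducibility statistic: 100 times the sample standard deviation
#' (n - 1 denominator) divided by the mean, reported to two decimals.
#'
#' @param values Numeric vector of at least two replicate measurements with
#'   positive mean.
#' @return CV in percent, rounded to 2 decimals.
#' @examples
#' compute_cv(c(32891194, 29474127, 32067765))  # 5.67
#' @export
compute_cv <- function(values) {
  if (length(values) < 2) abort("need at least two values.")
  m <- mean(values)
  if (m <= 0) abort("mean must be positive.")
  round(100 * sd(values) / m, 2)
}
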