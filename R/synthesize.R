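#' Specification for a synthetic two-channel micrograph
#'
#' Defines the study conditions the simulator emulates: capillary-scale
#' tubular vessels rendered into a basement-membrane (laminin-like) channel,
#' and an IgG channel holding intravascular plasma signal plus optional
#' extravasated leak plumes, all over mixed Poisson-Gaussian camera noise.
#' Intensity scales follow the documented regime on a 16-bit range: IgG
#' background around 1,000 (never exceeding ~2,000 with noise), IgG signal
#' around 5,000, so the midpoint threshold 3,500 separates them. The default
#' frame is 512 x 512 px at 0.346 um/px (the package's benchmark problem
#' size; see the methods vignette).
#'
#' Leak severity presets (overridable field by field):
#' `none` — no plumes; `mild` — 4 plumes, amplitude 3,500-5,000 over
#' background, radius 4-7 um; `severe` — 12 plumes, amplitude 5,000-9,000,
#' radius 5-10 um.
#'
#' @param width,height Frame size in pixels.
#' @param pixel_size_um Micrometres per pixel.
#' @param n_vessels Number of vessel centerlines.
#' @param vessel_radius_um Range of vessel radii (capillary scale).
#' @param vessel_intensity Range of peak laminin intensities.
#' @param laminin_background Laminin channel background level.
#' @param igg_intravascular_intensity Intravascular IgG level.
#' @param igg_background IgG channel background level.
#' @param leak_severity `"none"`, `"mild"` or `"severe"`.
#' @param n_leaks,leak_amplitude,leak_radius_um Leak plume count, amplitude
#'   range (above background) and radius range; `NULL` takes the severity
#'   preset.
#' @param noise_gaussian_sd Additive Gaussian read-noise sigma (intensity
#'   units); Poisson shot noise with gain 1 is always applied.
#' @param truth_threshold Threshold used to define the ground-truth leak
#'   mask/sum — the same value the analysis is expected to use.
#' @param buffer_px Perivascular buffer assumed by the ground truth (matches
#'   the analysis `erode_count`).
#' @param seed Integer seed; the whole image is reproducible from it.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(width = 512L, height = 512L,
                           pixel_size_um = 0.346,
                           n_vessels = 5L,
                           vessel_radius_um = c(2, 5),
                           vessel_intensity = c(4000, 7000),
                           laminin_background = 300,
                           igg_intravascular_intensity = 5000,
                           igg_background = 1000,
                           leak_severity = c("mild", "none", "severe"),
                           n_leaks = NULL,
                           leak_amplitude = NULL,
                           leak_radius_um = NULL,
                           noise_gaussian_sd = 100,
                           truth_threshold = 3500,
                           buffer_px = 1L,
                           seed = 1L) {
  leak_severity <- match.arg(leak_severity)
  preset <- switch(leak_severity,
    none = list(n_leaks = 0L, leak_amplitude = c(0, 0),
                leak_radius_um = c(0, 0)),
    mild = list(n_leaks = 4L, leak_amplitude = c(3500, 5000),
                leak_radius_um = c(4, 7)),
    severe = list(n_leaks = 12L, leak_amplitude = c(5000, 9000),
                  leak_radius_um = c(5, 10)))
  spec <- list(width = as.integer(width), height = as.integer(height),
               pixel_size_um = pixel_size_um, n_vessels = as.integer(n_vessels),
               vessel_radius_um = vessel_radius_um,
               vessel_intensity = vessel_intensity,
               laminin_background = laminin_background,
               igg_intravascular_intensity = igg_intravascular_intensity,
               igg_background = igg_background,
               leak_severity = leak_severity,
               n_leaks = if (is.null(n_leaks)) preset$n_leaks
                         else as.integer(n_leaks),
               leak_amplitude = if (is.null(leak_amplitude))
                 preset$leak_amplitude else leak_amplitude,
               leak_radius_um = if (is.null(leak_radius_um))
                 preset$leak_radius_um else leak_radius_um,
               noise_gaussian_sd = noise_gaussian_sd,
               truth_threshold = truth_threshold,
               buffer_px = as.integer(buffer_px),
               seed = as.integer(seed))
  bad <- vapply(spec[c("laminin_background", "igg_background",
                       "igg_intravascular_intensity", "noise_gaussian_sd")],
                function(v) any(v < 0), logical(1))
  if (any(bad)) abort("intensity scales and noise must be non-negative.")
  if (max(spec$vessel_radius_um) / pixel_size_um > min(width, height) / 2) {
    abort("vessel radius exceeds the frame.")
  }
  structure(spec, class = "synthetic_spec")
}

# correlated random-walk centerline clipped to the frame; returns (row, col)
walk_centerline <- function(h, w) {
  margin <- 4
  pos <- c(runif(1, margin, h - margin), runif(1, margin, w - margin))
  heading <- runif(1, 0, 2 * pi)
  n_steps <- as.integer(1.5 * max(h, w))
  pts <- matrix(NA_real_, n_steps, 2)
  for (i in seq_len(n_steps)) {
    heading <- heading + rnorm(1, 0, 0.12)  # curvature bound
    pos <- pos + c(sin(heading), cos(heading))
    if (pos[1] < 1 || pos[1] > h || pos[2] < 1 || pos[2] > w) break
    pts[i, ] <- pos
  }
  pts[stats::complete.cases(pts), , drop = FALSE]
}

# Euclidean distance of every pixel to a point set, via EBImage distmap on
# the rasterized points
dist_to_points <- function(h, w, pts) {
  m <- matrix(1L, h, w)
  idx <- cbind(pmin(pmax(round(pts[, 1]), 1), h),
               pmin(pmax(round(pts[, 2]), 1), w))
  m[idx] <- 0L
  EBImage::distmap(m)
}

#' Simulate a two-channel micrograph with ground truth
#'
#' Vessels are correlated-random-walk centerlines rendered as tubes with a
#' Gaussian cross-section via a distance transform; the IgG channel carries
#' intravascular signal inside the true vessel mask plus flat-core Gaussian
#' leak plumes seeded just outside the vessel wall. Mixed Poisson (gain 1)
#' plus additive Gaussian noise is applied to both channels. Everything is
#' deterministic given `spec$seed`; the ground truth is computed from the
#' noise-free fields.
#'
#' The ground-truth leak accounting mirrors the analysis definition so that
#' recovery is well-posed: `leak_mask_true` contains the noise-free IgG
#' pixels at or above `truth_threshold` that lie outside the true vessel
#' mask dilated by `buffer_px`, in 8-connected regions of at least
#' 5 square micrometres; `leak_sum_true` is the noise-free IgG sum over it.
#'
#' @param spec A [synthetic_spec].
#' @return List with `image` (an [mc_image] with channels `laminin`, `igg`)
#'   and `truth` (list: `vessel_mask_true`, `leak_mask_true`,
#'   `leak_sum_true`, `leaks` tibble of centers/amplitudes/radii,
#'   `clean_igg`, `clean_laminin`).
#' @export
simulate_image <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  h <- spec$height; w <- spec$width; ps <- spec$pixel_size_um
  stain <- matrix(0.0, h, w)   # laminin signal above background
  for (v in seq_len(spec$n_vessels)) {
    pts <- walk_centerline(h, w)
    if (nrow(pts) < 5) next
    r_um <- runif(1, spec$vessel_radius_um[1], spec$vessel_radius_um[2])
    r_px <- r_um / ps
    amp <- runif(1, spec$vessel_intensity[1], spec$vessel_intensity[2])
    d <- dist_to_points(h, w, pts)
    # Gaussian cross-section rendered off the centerline distance transform
    stain <- stain + amp * exp(-0.5 * (1.5 * d / r_px)^2)
  }
  # the true vessel mask is where stain is detectably above background, so
  # the segmentation target coincides with what the image actually shows
  stain_floor <- 500
  vessel_mask <- stain >= stain_floor
  laminin <- spec$laminin_background + stain

  igg <- matrix(spec$igg_background + 0.0, h, w)
  igg[vessel_mask] <- igg[vessel_mask] + spec$igg_intravascular_intensity
  leaks <- tibble(row = numeric(), col = numeric(),
                  amplitude = numeric(), radius_um = numeric())
  if (spec$n_leaks > 0 && any(vessel_mask)) {
    # distance of every extravascular pixel to the true vessel wall
    dist_out <- EBImage::distmap((!vessel_mask) * 1L)
    for (l in seq_len(spec$n_leaks)) {
      r_um <- runif(1, spec$leak_radius_um[1], spec$leak_radius_um[2])
      r_px <- r_um / ps
      amp <- runif(1, spec$leak_amplitude[1], spec$leak_amplitude[2])
      # anchor the plume on a ring just outside the wall: extravasated
      # protein pools perivascularly, and keeping the above-threshold core
      # clear of the 1-px buffer makes ground-truth recovery well-posed
      # under pixel-scale segmentation jitter
      ring_r <- 0.9 * r_px + 2
      cand <- which(abs(dist_out - ring_r) <= 1 & !vessel_mask)
      if (length(cand) == 0) next
      at <- cand[sample.int(length(cand), 1)]
      ctr <- c((at - 1) %% h + 1, (at - 1) %/% h + 1)
      rc <- 0.6 * r_px               # flat core
      s <- 0.25 * r_px               # Gaussian skirt
      win <- ceiling(rc + 4 * s)
      ri <- max(1, floor(ctr[1] - win)):min(h, ceiling(ctr[1] + win))
      ci <- max(1, floor(ctr[2] - win)):min(w, ceiling(ctr[2] + win))
      dd <- sqrt(outer((ri - ctr[1])^2, (ci - ctr[2])^2, `+`))
      plume <- amp * exp(-0.5 * (pmax(dd - rc, 0) / s)^2)
      igg[ri, ci] <- igg[ri, ci] + plume
      leaks <- rbind(leaks, tibble(row = ctr[1], col = ctr[2],
                                   amplitude = amp, radius_um = r_um))
    }
  }

  clean_laminin <- clamp(laminin, 0, 65535)
  clean_igg <- clamp(igg, 0, 65535)

  # ground truth from the noise-free IgG field, analysis-consistent
  outside <- if (spec$buffer_px > 0) {
    !dilate_cpp(vessel_mask, spec$buffer_px)
  } else !vessel_mask
  leak_mask <- (clean_igg >= spec$truth_threshold) & outside
  min_px <- as.integer(ceiling(5 / ps^2))
  if (any(leak_mask) && min_px > 1L) {
    lab <- label_components_cpp(leak_mask, 8L)
    sizes <- tabulate(lab[lab > 0L])
    keep <- sizes >= min_px
    leak_mask <- leak_mask & matrix(lab > 0L & keep[pmax(lab, 1L)], h, w)
  }
  leak_sum <- sum(clean_igg[leak_mask])

  noisify <- function(m) {
    n <- length(m)
    shot <- rpois(n, lambda = as.vector(m))
    read <- rnorm(n, 0, spec$noise_gaussian_sd)
    matrix(clamp(round(shot + read), 0, 65535), nrow(m), ncol(m))
  }
  img <- mc_image(list(laminin = noisify(clean_laminin),
                       igg = noisify(clean_igg)),
                  pixel_size_um = ps,
                  source_name = sprintf("synthetic_seed%d", spec$seed))
  list(image = img,
       truth = list(vessel_mask_true = vessel_mask,
                    leak_mask_true = leak_mask,
                    leak_sum_true = leak_sum,
                    leaks = leaks,
                    clean_igg = clean_igg,
                    clean_laminin = clean_laminin))
}

#' Sample sparse training labels from ground truth
#'
#' Emulates sparse brush annotation: `n_per_class` pixels are drawn from the
#' true vessel mask (class object) and from its complement eroded by 3 px
#' (class background), with sampling probability biased toward class
#' boundaries — mirroring the advice to label carefully along
#' vessel/background boundaries.
#'
#' @param truth The `truth` element returned by [simulate_image].
#' @param n_per_class Number of labeled pixels per class (>= 1).
#' @param seed Integer seed.
#' @return A [label_map].
#' @export
make_training_labels <- function(truth, n_per_class = 500L, seed = 1L) {
  if (n_per_class < 1) abort("`n_per_class` must be >= 1.")
  vm <- truth$vessel_mask_true
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  bg_ok <- erode_cpp(!vm, 3L)
  if (sum(vm) < n_per_class || sum(bg_ok) < n_per_class) {
    abort("masks too small to sample the requested labels.")
  }
  d_obj <- EBImage::distmap(vm * 1L)        # object px: distance to boundary
  d_bg <- EBImage::distmap((!vm) * 1L)      # background px: same
  lab <- matrix(0L, nrow(vm), ncol(vm))
  pick <- function(cand, d) {
    idx <- which(cand)
    wgt <- exp(-as.vector(d)[idx] / 4)
    idx[sample.int(length(idx), n_per_class, prob = wgt)]
  }
  lab[pick(vm, d_obj)] <- 1L
  lab[pick(bg_ok, d_bg)] <- 2L
  label_map(lab)
}
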