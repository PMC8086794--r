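#' Filter-bank feature configuration
#'
#' Configuration of the per-pixel feature stack the pixel classifier is
#' trained on: an ilastik-style bank of Gaussian-family filters computed at
#' several scales. The default — raw intensity plus, for each
#' `sigma` in `{0.7, 1.0, 1.6, 3.5}` px, Gaussian smoothing, gradient
#' magnitude, Laplacian of Gaussian, difference of Gaussians (versus
#' `0.66 * sigma`), the two structure-tensor eigenvalues and the two Hessian
#' eigenvalues — yields exactly 33 feature planes
#' (`1 + 4 scales x 8 features`).
#'
#' @param sigmas Ordered vector of positive Gaussian scales in pixels.
#' @param families Ordered subset of
#'   `c("gaussian_smoothing", "gradient_magnitude", "laplacian_of_gaussian",
#'      "difference_of_gaussians", "structure_tensor_eigenvalues",
#'      "hessian_eigenvalues")`.
#' @param include_raw Include the raw intensity as a feature plane?
#' @return An object of class `feature_config`.
#' @examples
#' n_features(feature_config())  # 33
#' @export
feature_config <- function(sigmas = c(0.7, 1.0, 1.6, 3.5),
                           families = c("gaussian_smoothing",
                                        "gradient_magnitude",
                                        "laplacian_of_gaussian",
                                        "difference_of_gaussians",
                                        "structure_tensor_eigenvalues",
                                        "hessian_eigenvalues"),
                           include_raw = TRUE) {
  all_fam <- c("gaussian_smoothing", "gradient_magnitude",
               "laplacian_of_gaussian", "difference_of_gaussians",
               "structure_tensor_eigenvalues", "hessian_eigenvalues")
  families <- match.arg(families, all_fam, several.ok = TRUE)
  if (length(sigmas) == 0 || any(!is.finite(sigmas)) || any(sigmas <= 0)) {
    abort("`sigmas` must be positive and finite.")
  }
  structure(list(sigmas = as.numeric(sigmas), families = families,
                 include_raw = isTRUE(include_raw)),
            class = "feature_config")
}

fam_width <- function(fam) {
  ifelse(fam %in% c("structure_tensor_eigenvalues", "hessian_eigenvalues"),
         2L, 1L)
}

#' @rdname feature_config
#' @param config A `feature_config`.
#' @export
n_features <- function(config) {
  stopifnot(inherits(config, "feature_config"))
  as.integer(config$include_raw) +
    length(config$sigmas) * sum(fam_width(config$families))
}

#' @rdname feature_config
#' @export
feature_names <- function(config) {
  stopifnot(inherits(config, "feature_config"))
  short <- c(gaussian_smoothing = "gauss", gradient_magnitude = "gradmag",
             laplacian_of_gaussian = "log", difference_of_gaussians = "dog",
             structure_tensor_eigenvalues = "st_eig",
             hessian_eigenvalues = "hess_eig")
  nm <- if (config$include_raw) "raw" else character()
  for (s in config$sigmas) {
    for (fam in config$families) {
      base <- sprintf("%s_s%g", short[[fam]], s)
      nm <- c(nm, if (fam_width(fam) == 2L) paste0(base, c("_1", "_2"))
              else base)
    }
  }
  nm
}

# --- discrete kernels (correlation convention; symmetric support) ---------

gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_deriv1_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  -x / sigma^2 * g  # odd: sums to zero exactly
}

gaussian_deriv2_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- (x^2 / sigma^4 - 1 / sigma^2) * g
  k - mean(k)  # zero response to constants despite discretization
}

#' Separable filtering with reflected borders
#'
#' Internal workhorses, exported because the quantitation module and tests
#' use them directly. `gaussian_filter()` smooths; `lowpass()` is the
#' size x size uniform mean filter the IgG channel is denoised with.
#' Borders are handled by half-sample reflection.
#'
#' @param channel Numeric matrix.
#' @param sigma Positive Gaussian scale (px).
#' @return Real-valued matrix of the same size.
#' @export
gaussian_filter <- function(channel, sigma) {
  stopifnot(is.matrix(channel), sigma > 0)
  k <- gaussian_kernel(sigma)
  sep_convolve_cpp(channel, k, k)
}

#' @rdname gaussian_filter
#' @param size Odd window size, >= 1.
#' @export
lowpass <- function(channel, size = 3L) {
  stopifnot(is.matrix(channel))
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) abort("`size` must be odd and >= 1.")
  if (size == 1L) return(channel + 0.0)
  k <- rep(1 / size, size)
  sep_convolve_cpp(channel, k, k)
}

sym_eig <- function(axx, ayy, axy) {
  tr2 <- (axx + ayy) / 2
  disc <- sqrt(((axx - ayy) / 2)^2 + axy^2)
  list(e1 = tr2 + disc, e2 = tr2 - disc)  # e1 >= e2 pointwise
}

#' Compute a per-pixel feature stack
#'
#' Applies the configured filter bank to one channel. Deterministic; feature
#' values depend only on the channel and the configuration. All filters are
#' separable Gaussian-family kernels evaluated in floating point with
#' reflected borders; no normalization is applied (the downstream forest
#' learner is scale-free, and keeping raw units preserves threshold
#' interpretability).
#'
#' @param channel Numeric matrix of intensities.
#' @param config A [feature_config].
#' @return A `feature_stack`: list with `values` (height x width x
#'   n_features array), `feature_names`, `source_channel`.
#' @export
compute_feature_stack <- function(channel, config = feature_config(),
                                  source_channel = NA_character_) {
  stopifnot(inherits(config, "feature_config"))
  if (!is.matrix(channel) || length(channel) == 0) {
    abort("`channel` must be a non-empty matrix.")
  }
  if (any(!is.finite(channel))) abort("`channel` must be finite.")
  channel <- channel + 0.0
  h <- nrow(channel); w <- ncol(channel)
  nm <- feature_names(config)
  vals <- array(0.0, dim = c(h, w, length(nm)))
  i <- 0L
  put <- function(m) {
    i <<- i + 1L
    vals[, , i] <<- m
  }
  if (config$include_raw) put(channel)
  for (s in config$sigmas) {
    g <- gaussian_kernel(s)
    d1 <- gaussian_deriv1_kernel(s)
    d2 <- gaussian_deriv2_kernel(s)
    need_grad <- any(c("gradient_magnitude", "structure_tensor_eigenvalues")
                     %in% config$families)
    need_hess <- any(c("laplacian_of_gaussian", "hessian_eigenvalues")
                     %in% config$families)
    if (need_grad) {
      ix <- sep_convolve_cpp(channel, g, d1)   # horizontal derivative
      iy <- sep_convolve_cpp(channel, d1, g)   # vertical derivative
    }
    if (need_hess) {
      ixx <- sep_convolve_cpp(channel, g, d2)
      iyy <- sep_convolve_cpp(channel, d2, g)
      ixy <- sep_convolve_cpp(channel, d1, d1)
    }
    for (fam in config$families) {
      switch(fam,
        gaussian_smoothing = put(sep_convolve_cpp(channel, g, g)),
        gradient_magnitude = put(sqrt(ix^2 + iy^2)),
        laplacian_of_gaussian = put(ixx + iyy),
        difference_of_gaussians = {
          g2 <- gaussian_kernel(0.66 * s)
          put(sep_convolve_cpp(channel, g2, g2) -
                sep_convolve_cpp(channel, g, g))
        },
        structure_tensor_eigenvalues = {
          jxx <- sep_convolve_cpp(ix * ix, g, g)
          jyy <- sep_convolve_cpp(iy * iy, g, g)
          jxy <- sep_convolve_cpp(ix * iy, g, g)
          e <- sym_eig(jxx, jyy, jxy)
          put(e$e1); put(e$e2)
        },
        hessian_eigenvalues = {
          e <- sym_eig(ixx, iyy, ixy)
          put(e$e1); put(e$e2)
        })
    }
  }
  structure(list(values = vals, feature_names = nm,
                 source_channel = source_channel),
            class = "feature_stack")
}

# flatten a feature stack to an (n_pixels x n_features) matrix, column-major
# pixel order (matching R matrix indexing)
feature_matrix <- function(stack) {
  stopifnot(inherits(stack, "feature_stack"))
  d <- dim(stack$values)
  m <- matrix(stack$values, nrow = d[1] * d[2], ncol = d[3])
  colnames(m) <- stack$feature_names
  m
}
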