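#' Train a pixel classifier from sparse labels
#'
#' Fits a bagged decision-forest probabilistic classifier (100 trees,
#' seed-controlled) on the filter-bank feature vectors of the labeled pixels
#' only. Sparse brush annotations on the vessel-stain channel are all that is
#' needed; unlabeled pixels do not enter training. Retraining with the same
#' inputs and seed reproduces the model exactly.
#'
#' @param images List of [mc_image] objects (or a single one).
#' @param labels List of [label_map] matrices, geometry-matched 1:1 with
#'   `images`; values 0 = unlabeled, 1 = object (vessel), 2 = background.
#'   Both classes must be represented somewhere in the set.
#' @param channel Name of the channel to train on (e.g. `"laminin"`).
#' @param config A [feature_config].
#' @param seed Integer seed controlling forest construction.
#' @param n_trees Number of trees in the bagged forest.
#' @return A `segmenter_model`.
#' @export
train_segmenter <- function(images, labels, channel,
                            config = feature_config(), seed = 1L,
                            n_trees = 100L) {
  if (inherits(images, "mc_image")) images <- list(images)
  if (is.matrix(labels)) labels <- list(labels)
  if (length(images) < 1) abort("need at least one training image.")
  if (length(images) != length(labels)) {
    abort("`images` and `labels` must have equal length.")
  }
  xs <- vector("list", length(images))
  ys <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    lab <- label_map(unclass(labels[[i]]))
    if (!identical(dim(lab), dim(img))) {
      abort(sprintf("label map %d does not match its image geometry.", i))
    }
    ch <- get_channel(img, channel)
    sel <- which(lab != 0L)
    if (length(sel) == 0) next
    fm <- feature_matrix(compute_feature_stack(ch, config, channel))
    xs[[i]] <- fm[sel, , drop = FALSE]
    ys[[i]] <- ifelse(lab[sel] == 1L, "object", "background")
  }
  x <- do.call(rbind, xs)
  y <- unlist(ys)
  if (is.null(x) || !all(c("object", "background") %in% y)) {
    abort("training labels must include both 'object' and 'background' pixels.")
  }
  y <- factor(y, levels = c("object", "background"))
  set.seed(as.integer(seed))
  learner <- randomForest::randomForest(x = x, y = y, ntree = as.integer(n_trees))
  structure(
    list(learner = learner, feature_config = config,
         class_names = c("object", "background"),
         training_seed = as.integer(seed),
         training_summary = c(object = sum(y == "object"),
                              background = sum(y == "background")),
         format_version = "bbbleak-model-1"),
    class = "segmenter_model")
}

#' @export
print.segmenter_model <- function(x, ...) {
  cat(sprintf(
    "<segmenter_model> %d trees, %d features, trained on %d object + %d background px (seed %d)\n",
    x$learner$ntree, n_features(x$feature_config),
    x$training_summary[["object"]], x$training_summary[["background"]],
    x$training_seed))
  invisible(x)
}

#' Predict class probabilities and a confidence map
#'
#' Applies the trained pixel classifier to one image (any geometry). Class
#' probabilities are normalized per pixel; the confidence map is the
#' max-class probability rescaled from `[1/n_classes, 1]` to `[0, 1]`, so 0
#' marks a pixel the classifier is indifferent about and 1 a certain one.
#' Low-confidence regions are the ones worth relabeling in the iterative
#' brush-train-inspect loop.
#'
#' @param object A `segmenter_model`.
#' @param image An [mc_image].
#' @param channel Channel to classify; defaults to the vessel stain used in
#'   training workflows.
#' @param ... Unused.
#' @return List with `prob` (named list of per-class probability matrices)
#'   and `confidence` (matrix in `[0, 1]`).
#' @export
predict.segmenter_model <- function(object, image, channel = "laminin", ...) {
  stopifnot(inherits(object, "segmenter_model"))
  if (is.null(object$learner)) abort("model has no trained learner.")
  ch <- get_channel(image, channel)
  fm <- feature_matrix(
    compute_feature_stack(ch, object$feature_config, channel))
  p <- predict(object$learner, fm, type = "prob")
  d <- dim(ch)
  p_obj <- matrix(p[, "object"], d[1], d[2])
  p_bg <- 1 - p_obj
  n_cls <- 2
  conf <- (pmax(p_obj, p_bg) - 1 / n_cls) / (1 - 1 / n_cls)
  list(prob = list(object = p_obj, background = p_bg), confidence = conf)
}

#' Class maps
#'
#' A class map assigns every pixel to exactly one of `object` (vessel) or
#' `background`. Internally an integer matrix: 1 = object, 2 = background.
#'
#' @param object_mask Logical matrix, TRUE where the pixel is object.
#' @return A `class_map`.
#' @export
class_map <- function(object_mask) {
  stopifnot(is.logical(object_mask), is.matrix(object_mask))
  m <- matrix(2L, nrow(object_mask), ncol(object_mask))
  m[object_mask] <- 1L
  structure(m, class = c("class_map", "matrix", "array"),
            class_names = c("object", "background"))
}

#' @rdname class_map
#' @param x A `class_map`.
#' @export
object_mask <- function(x) {
  stopifnot(inherits(x, "class_map"))
  unclass(x) == 1L
}

#' Spatially regularize probability maps into a class map
#'
#' Minimizes the 2-class Potts energy
#' \deqn{E(L) = \sum_p -\log p(L_p) + \lambda \sum_{(p,q)\ 4-adj} [L_p \ne L_q]}
#' combining per-pixel class evidence with a neighbor-agreement term — the
#' conditional-random-field style post-processing step that removes
#' salt-and-pepper misclassifications. `method = "graphcut"` (default) solves
#' the minimization exactly by s-t min-cut; `"icm"` runs iterated conditional
#' modes (raster sweeps from the pointwise argmax until no change, at most 50
#' sweeps) to a local optimum. With `smoothness = 0` both reduce to the
#' pointwise argmax. Ties are broken to background: the pipeline never
#' invents vessel where the evidence is absent.
#'
#' @param prob Named list with `object` and `background` probability
#'   matrices (e.g. `predict(model, image)$prob`).
#' @param smoothness Non-negative pairwise weight \eqn{\lambda}.
#' @param method `"graphcut"` or `"icm"`.
#' @return A [class_map].
#' @export
regularize <- function(prob, smoothness = 1.0,
                       method = c("graphcut", "icm")) {
  method <- match.arg(method)
  if (!is.list(prob) || !all(c("object", "background") %in% names(prob))) {
    abort("`prob` must be a named list with 'object' and 'background'.")
  }
  if (!is.numeric(smoothness) || length(smoothness) != 1 ||
      !is.finite(smoothness) || smoothness < 0) {
    abort("`smoothness` must be a non-negative scalar.")
  }
  p_obj <- prob$object
  p_bg <- prob$background
  stopifnot(identical(dim(p_obj), dim(p_bg)))
  argmax <- p_obj > p_bg  # ties -> background
  if (smoothness == 0) return(class_map(argmax))
  c_obj <- -log(clamp(p_obj, 1e-10, 1))
  c_bg <- -log(clamp(p_bg, 1e-10, 1))
  obj <- switch(method,
    graphcut = graphcut_potts_cpp(c_obj, c_bg, smoothness),
    icm = icm_potts_cpp(c_obj, c_bg, smoothness, argmax, 50L))
  class_map(obj)
}

#' Potts energy of a labeling
#'
#' The objective [regularize] minimizes; exposed for inspection and testing.
#'
#' @param cmap A [class_map].
#' @param prob As in [regularize].
#' @param smoothness Pairwise weight.
#' @return Scalar energy.
#' @export
potts_energy <- function(cmap, prob, smoothness) {
  obj <- object_mask(cmap)
  p <- ifelse(obj, prob$object, prob$background)
  unary <- sum(-log(clamp(p, 1e-10, 1)))
  lab <- unclass(cmap)
  h <- nrow(lab); w <- ncol(lab)
  pair <- 0L
  if (h > 1) pair <- pair + sum(lab[-h, ] != lab[-1, ])
  if (w > 1) pair <- pair + sum(lab[, -w] != lab[, -1])
  unary + smoothness * pair
}

#' Persist and restore a trained segmenter
#'
#' The model file is a single serialized artifact holding the learner, the
#' feature configuration, class names, the training seed and a format
#' version; reloading yields bit-identical predictions.
#'
#' @param model A `segmenter_model`.
#' @param path File path (conventionally `.rds`).
#' @return `path` invisibly (save) / the model (load).
#' @export
save_segmenter <- function(model, path) {
  stopifnot(inherits(model, "segmenter_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  m <- readRDS(path)
  if (!inherits(m, "segmenter_model")) abort("not a segmenter model file.")
  m
}

#' Tidy a trained segmenter
#'
#' `tidy()` returns per-feature importance (mean decrease in Gini impurity);
#' `glance()` a one-row model summary including the out-of-bag error.
#'
#' @param x A `segmenter_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.segmenter_model <- function(x, ...) {
  imp <- randomForest::importance(x$learner)
  tibble(feature = rownames(imp), importance = as.numeric(imp[, 1]))
}

#' @rdname tidy.segmenter_model
#' @export
glance.segmenter_model <- function(x, ...) {
  tibble(
    n_trees = x$learner$ntree,
    n_features = n_features(x$feature_config),
    n_object_px = unname(x$training_summary[["object"]]),
    n_background_px = unname(x$training_summary[["background"]]),
    oob_error = as.numeric(utils::tail(x$learner$err.rate[, "OOB"], 1)),
    training_seed = x$training_seed)
}
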