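# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# A small two-band image that is trivially separable by raw intensity:
# a horizontal band of "vessel-like" bright signal on dim background.
band_image <- function(h = 64, w = 64, hi = 5000, lo = 1000, noise_sd = 50,
                       seed = 7) {
  set.seed(seed)
  lam <- matrix(lo, h, w) + rnorm(h * w, 0, noise_sd)
  band <- (h %/% 4):(2 * h %/% 4)
  lam[band, ] <- hi + rnorm(length(band) * w, 0, noise_sd)
  lam <- pmax(round(lam), 0)
  igg <- matrix(lo, h, w)
  mc_image(list(laminin = lam, igg = igg), pixel_size_um = 0.346,
           source_name = "band")
}

band_truth_mask <- function(h = 64, w = 64) {
  m <- matrix(FALSE, h, w)
  m[(h %/% 4):(2 * h %/% 4), ] <- TRUE
  m
}

band_labels <- function(h = 64, w = 64, n = 200, seed = 3) {
  set.seed(seed)
  truth <- band_truth_mask(h, w)
  lab <- matrix(0L, h, w)
  lab[sample(which(truth), n)] <- 1L
  lab[sample(which(!truth), n)] <- 2L
  label_map(lab)
}

# Default-spec synthetic benchmark: training images + labels + a trained
# model, reused by the heavier tests.
bench_training <- function() {
  cached("bench_training", {
    sims <- lapply(901:903, function(s) simulate_image(synthetic_spec(seed = s)))
    labels <- lapply(seq_along(sims), function(i)
      make_training_labels(sims[[i]]$truth, 500L, seed = 40 + i))
    list(images = lapply(sims, `[[`, "image"), labels = labels)
  })
}

bench_model <- function(train_seed = 101L) {
  key <- paste0("bench_model_", train_seed)
  cached(key, {
    tr <- bench_training()
    train_segmenter(tr$images, tr$labels, "laminin", seed = train_seed)
  })
}

iou <- function(a, b) sum(a & b) / sum(a | b)
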