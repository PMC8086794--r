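test_that("the midpoint threshold rule reproduces the documented example", {
  expect_equal(select_threshold(2000, 5000), 3500)
  expect_equal(select_threshold(7, 7), 7)
  expect_equal(select_threshold(0, 7000), 3500)
  expect_error(select_threshold(5000, 2000), ">=")
  expect_error(select_threshold(-1, 10), ">=")
})

test_that("compute_cv reproduces the published reproducibility values", {
  # three-trial IgG intensity sums for replicate analyses of single images
  expect_equal(compute_cv(c(32891194, 29474127, 32067765)), 5.67)
  expect_equal(compute_cv(c(195e6, 186e6, 193e6)), 2.47)
  expect_equal(compute_cv(c(4492003, 3670690, 4518946)), 11.41)
  expect_equal(compute_cv(c(5, 5, 5)), 0)
  expect_error(compute_cv(7), "two")
  expect_error(compute_cv(c(-1, 1)), "positive")
})

test_that("compute_cv is scale-invariant", {
  withr::local_seed(31)
  for (rep in 1:10) {
    v <- runif(sample(2:8, 1), 1, 100)
    k <- runif(1, 0.01, 1e6)
    expect_equal(compute_cv(k * v), compute_cv(v), tolerance = 0.011)
  }
})

test_that("fill_holes closes enclosed background and is idempotent", {
  ring <- matrix(FALSE, 9, 9)
  ring[3:7, 3:7] <- TRUE
  ring[4:6, 4:6] <- FALSE  # the hole
  filled <- fill_holes(ring)
  solid <- matrix(FALSE, 9, 9); solid[3:7, 3:7] <- TRUE
  expect_identical(filled, solid)
  expect_identical(fill_holes(solid), solid)
  withr::local_seed(32)
  for (rep in 1:20) {
    m <- random_mask(sample(5:20, 1), sample(5:20, 1), runif(1, 0.3, 0.7))
    expect_identical(fill_holes(m), oracle_fill_holes(m))
  }
})

test_that("erode_mask matches an iterated 3x3 minimum filter", {
  sq <- matrix(FALSE, 5, 5); sq[2:4, 2:4] <- TRUE
  e1 <- erode_mask(sq, 1)
  expect_equal(sum(e1), 1)
  expect_true(e1[3, 3])
  expect_identical(erode_mask(sq, 0), sq)
  expect_error(erode_mask(sq, -1), "non-negative")
  withr::local_seed(33)
  for (rep in 1:20) {
    m <- random_mask(sample(5:16, 1), sample(5:16, 1), 0.8)
    cnt <- sample(0:2, 1)
    expect_identical(erode_mask(m, cnt), oracle_erode(m, cnt))
  }
})

test_that("lowpass is the uniform mean filter with reflected borders", {
  expect_equal(lowpass(matrix(42, 7, 7), 3), matrix(42, 7, 7))
  imp <- matrix(0, 7, 7); imp[4, 4] <- 9
  got <- lowpass(imp, 3)
  expect_equal(got[3:5, 3:5], matrix(1, 3, 3))
  expect_equal(sum(got), 9)
  expect_error(lowpass(imp, 4), "odd")
  withr::local_seed(34)
  for (rep in 1:15) {
    m <- matrix(runif(12 * 9, 0, 100), 12, 9)
    sz <- sample(c(1, 3, 5), 1)
    expect_equal(lowpass(m, sz), oracle_mean_filter(m, sz), tolerance = 1e-10)
  }
})

test_that("segment_igg thresholds within the compartment and filters regions", {
  cfg <- analysis_config(igg_threshold = 3500, lowpass_size = 1,
                         min_region_area_um2 = 5)
  # uniform sub-threshold field -> empty
  ev <- matrix(TRUE, 20, 20)
  expect_equal(sum(segment_igg(matrix(1000, 20, 20), ev, cfg, 0.346)), 0)
  # a 10x10 plateau of 5000 on 1000 background is fully recovered
  igg <- matrix(1000, 20, 20); igg[6:15, 6:15] <- 5000
  got <- segment_igg(igg, ev, cfg, 0.346)
  expect_identical(got, igg >= 3500)
  # a single above-threshold pixel (0.12 um2 < 5 um2) is removed
  spot <- matrix(1000, 20, 20); spot[4, 4] <- 6000
  expect_equal(sum(segment_igg(spot, ev, cfg, 0.346)), 0)
  # pixels outside the compartment never count
  ev2 <- ev; ev2[6:15, 6:15] <- FALSE
  expect_equal(sum(segment_igg(igg, ev2, cfg, 0.346)), 0)
})

test_that("segment_igg agrees with the per-pixel brute-force oracle", {
  withr::local_seed(35)
  for (rep in 1:15) {
    h <- sample(8:24, 1); w <- sample(8:24, 1)
    igg <- matrix(runif(h * w, 0, 6000), h, w)
    ev <- random_mask(h, w, 0.8)
    sz <- sample(c(1, 3), 1)
    ps <- 0.5
    cfg <- analysis_config(igg_threshold = 3000, lowpass_size = sz,
                           min_region_area_um2 = 2)
    got <- segment_igg(igg, ev, cfg, ps)
    want <- oracle_segment_igg(igg, ev, 3000, sz, ceiling(2 / ps^2))
    expect_identical(got, want)
  }
})

test_that("raising the threshold or area floor never increases the IgG mask", {
  withr::local_seed(36)
  igg <- matrix(runif(40 * 40, 0, 6000), 40, 40)
  igg[5:20, 5:20] <- igg[5:20, 5:20] + 2000
  ev <- matrix(TRUE, 40, 40)
  prev_px <- Inf; prev_sum <- Inf
  for (thr in c(2000, 3000, 4000, 5000)) {
    cfg <- analysis_config(igg_threshold = thr)
    m <- segment_igg(igg, ev, cfg, 0.346)
    expect_lte(sum(m), prev_px)
    expect_lte(sum(igg[m]), prev_sum)
    prev_px <- sum(m); prev_sum <- sum(igg[m])
  }
  prev_px <- Inf
  for (area in c(0, 2, 5, 20)) {
    cfg <- analysis_config(igg_threshold = 3000, min_region_area_um2 = area)
    expect_lte(sum(segment_igg(igg, ev, cfg, 0.346)), prev_px)
    prev_px <- sum(segment_igg(igg, ev, cfg, 0.346))
  }
})

test_that("quantify_classmap enforces the documented mask algebra", {
  spec <- synthetic_spec(seed = 71, width = 256L, height = 256L)
  sim <- simulate_image(spec)
  cm <- class_map(sim$truth$vessel_mask_true)
  out <- quantify_classmap(sim$image, cm)
  res <- out$result
  obj <- object_mask(cm)
  # the extravascular compartment never touches the object class, and the
  # hole-filled vessel mask contains it entirely
  expect_equal(sum(obj & res$extravascular_mask), 0)
  expect_true(all(res$vessel_mask[obj]))
  expect_true(all(res$extravascular_mask[res$igg_mask]))
  # buffer: every IgG pixel at Chebyshev distance >= 1 from the object class
  near_vessel <- !erode_mask(!obj, 1)
  expect_equal(sum(res$igg_mask & near_vessel), 0)
  # record consistency
  expect_equal(out$record$igg_pixel_count, sum(res$igg_mask))
  expect_equal(out$record$vessel_area_um2,
               sum(res$vessel_mask) * 0.346^2)
  # with zero tolerance the smoothed-channel sum obeys the threshold bound
  cfg_sm <- analysis_config(intensity_source = "smoothed")
  rec_sm <- quantify_classmap(sim$image, cm, cfg_sm)$record
  expect_gte(rec_sm$igg_intensity_sum,
             3500 * rec_sm$igg_pixel_count - 1e-6)
})

test_that("frame area follows pixel size and frame geometry", {
  img <- mc_image(list(laminin = matrix(0L, 1000, 1000),
                       igg = matrix(0L, 1000, 1000)), 0.346, "frame")
  cm <- class_map(matrix(FALSE, 1000, 1000))
  rec <- quantify_classmap(img, cm)$record
  expect_equal(rec$frame_area_um2, 346^2, tolerance = 1e-9)
  expect_equal(rec$vessel_area_pct, 0)
  expect_equal(rec$igg_intensity_sum, 0)
})

test_that("batch analysis preserves order, isolates failures, and is deterministic", {
  model <- bench_model(101L)
  spec <- synthetic_spec(seed = 72, width = 256L, height = 256L)
  img <- simulate_image(spec)$image
  out <- suppressWarnings(batch_analyze(list(img, img, img), model))
  expect_equal(nrow(out), 3)
  expect_equal(length(unique(out$igg_intensity_sum)), 1L)
  # one unreadable path among real images
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.tif"); write_image(img, p1)
  out2 <- suppressWarnings(
    batch_analyze(c(p1, file.path(dir, "missing.tif"), p1), model,
                  channel_names = c("laminin", "igg"),
                  pixel_size_um = 0.346))
  expect_equal(nrow(out2), 2)
  fails <- attr(out2, "failures")
  expect_equal(nrow(fails), 1)
  expect_match(fails$image, "missing.tif")
  expect_error(batch_analyze(list(), model), "empty")
})
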