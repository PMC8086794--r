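test_that("mc_image validates geometry, names and intensities", {
  m <- matrix(0L, 4, 5)
  expect_s3_class(mc_image(list(a = m, b = m), 0.346), "mc_image")
  expect_error(mc_image(list(m, m), 0.346), "named")
  expect_error(mc_image(list(a = m, a = m), 0.346), "unique")
  expect_error(mc_image(list(a = m, b = matrix(0L, 5, 4)), 0.346), "identical")
  expect_error(mc_image(list(a = m - 1L), 0.346), "non-negative")
  expect_error(mc_image(list(a = m), 0), "positive")
  expect_error(get_channel(mc_image(list(a = m), 1), "zzz"), "not present")
})

test_that("16-bit TIFF round-trips are bit-exact, including multi-channel", {
  withr::local_seed(1)
  img <- mc_image(list(laminin = matrix(sample(0:65535, 32 * 40, TRUE), 32, 40),
                       igg = matrix(sample(0:65535, 32 * 40, TRUE), 32, 40)),
                  pixel_size_um = 0.346, source_name = "rt")
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(img, path)
  back <- read_image(path, c("laminin", "igg"), 0.346, source_name = "rt")
  expect_identical(back$channels$laminin, img$channels$laminin)
  expect_identical(back$channels$igg, img$channels$igg)
  expect_equal(back$pixel_size_um, 0.346)

  expect_error(read_image(path, c("one"), 0.346), "channel name")
  expect_error(read_image("no/such/file.tif", "a", 1), "not found")

  # 1x1 single-channel identity
  one <- mc_image(list(a = matrix(7L, 1, 1)), 1)
  p1 <- withr::local_tempfile(fileext = ".tif")
  write_image(one, p1)
  expect_equal(read_image(p1, "a", 1)$channels$a, matrix(7L, 1, 1))
})

test_that("label maps validate and round-trip through 8-bit TIFF", {
  withr::local_seed(2)
  lab <- label_map(matrix(sample(0:2, 30 * 20, TRUE), 30, 20))
  path <- withr::local_tempfile(fileext = ".tif")
  write_label_map(lab, path)
  expect_identical(unclass(read_label_map(path)), unclass(lab))
  expect_error(label_map(matrix(3L, 2, 2)), "label values")
})

test_that("maximum-intensity projection equals the per-pixel max over z", {
  withr::local_seed(3)
  mk <- function() mc_image(
    list(a = matrix(sample(0:100, 48, TRUE), 6, 8),
         b = matrix(sample(0:100, 48, TRUE), 6, 8)), 0.5, "s")
  slices <- replicate(5, mk(), simplify = FALSE)
  st <- zstack(slices, z_step_um = 1)
  mip <- max_intensity_projection(st)
  orc <- oracle_mip(list(a = lapply(slices, function(s) s$channels$a),
                         b = lapply(slices, function(s) s$channels$b)))
  expect_equal(mip$channels$a, orc$a)
  expect_equal(mip$channels$b, orc$b)
  # explicit per-pixel case: (1, 5, 3) -> 5
  tri <- zstack(list(
    mc_image(list(a = matrix(1, 1, 1)), 1),
    mc_image(list(a = matrix(5, 1, 1)), 1),
    mc_image(list(a = matrix(3, 1, 1)), 1)))
  expect_equal(max_intensity_projection(tri)$channels$a[1, 1], 5)
})

test_that("projection is idempotent and commutes with channel selection", {
  withr::local_seed(4)
  slices <- replicate(3, mc_image(
    list(a = matrix(sample(0:9, 12, TRUE), 3, 4),
         b = matrix(sample(0:9, 12, TRUE), 3, 4)), 1), simplify = FALSE)
  mip <- max_intensity_projection(zstack(slices))
  again <- max_intensity_projection(zstack(list(mip)))
  expect_identical(again$channels, mip$channels)
  # projecting then selecting a channel == selecting then projecting
  sel_first <- max_intensity_projection(zstack(lapply(slices, function(s)
    mc_image(list(a = s$channels$a), s$pixel_size_um))))$channels$a
  expect_equal(get_channel(mip, "a"), sel_first)
})

test_that("z-stack page order dialects read consistently", {
  withr::local_seed(5)
  pages <- replicate(6, matrix(sample(0:255, 16, TRUE), 4, 4),
                     simplify = FALSE)  # 3 z x 2 channels
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(pages, function(p) p / 255), path,
                  bits.per.sample = 8L)
  # interpret as z-then-channel: channel1 = pages 1:3, channel2 = pages 4:6
  st1 <- read_zstack(path, c("c1", "c2"), 1, n_z = 3)
  expect_identical(st1$slices[[2]]$channels$c1, pages[[2]])
  expect_identical(st1$slices[[2]]$channels$c2, pages[[5]])
  # channel-then-z: slice2 = pages 3,4
  st2 <- read_zstack(path, c("c1", "c2"), 1, n_z = 3, order = "channel_then_z")
  expect_identical(st2$slices[[2]]$channels$c1, pages[[3]])
  expect_identical(st2$slices[[2]]$channels$c2, pages[[4]])
  expect_error(read_zstack(path, c("c1", "c2"), 1, n_z = 4), "expected")
})

test_that("results tables round-trip with full numeric precision", {
  withr::local_seed(6)
  recs <- tibble::tibble(
    image_name = sprintf("img%02d", 1:10),
    vessel_area_um2 = runif(10, 0, 1e4),
    vessel_area_pct = runif(10, 0, 100),
    frame_area_um2 = rep(119716, 10),
    igg_intensity_sum = runif(10, 0, 7e8),
    igg_pixel_count = sample.int(1e5, 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_table(recs, path)
  back <- read_results_table(path)
  expect_equal(as.data.frame(back), as.data.frame(recs), tolerance = 1e-12)
  # empty record list -> header only
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_results_table(recs[0, ], p2)
  expect_length(readLines(p2), 1L)
  write_results_table(recs[1, ], p2)
  expect_length(readLines(p2), 2L)
})
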