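test_that("segmentation pipeline recovers coverage from synthetic scenes", {
  # conventions at the extremes
  expect_equal(segment_coverage(matrix(20, 64, 64))$coverage, 0)  # constant+otsu
  expect_equal(segment_coverage(matrix(80, 64, 64), method = "fixed",
                                threshold = 50)$coverage, 100)
  expect_error(segment_coverage(1:10), "matrix")
  expect_error(segment_coverage(matrix(1, 4, 4), method = "fixed"),
               "threshold")

  # noise-free scenes: exact; default noise: within 1% absolute
  for (s in 1:5) {
    sc <- gen_scene(30, dim = c(128L, 128L), area_meanlog = log(50),
                    noise_sd = 0, seed = s)
    expect_equal(segment_coverage(sc$pixel_grid)$coverage,
                 100 * sc$truth_coverage)
    scn <- gen_scene(30, dim = c(128L, 128L), area_meanlog = log(50),
                     seed = 100 + s)
    expect_lt(abs(segment_coverage(scn$pixel_grid)$coverage -
                    100 * scn$truth_coverage), 1)
  }
})

test_that("connected-component areas agree with a flood-fill oracle", {
  expect_identical(feature_areas(matrix(0L, 8, 8))$N, 0L)
  two <- matrix(0L, 10, 10); two[2:4, 2:4] <- 1L; two[7:9, 7:9] <- 1L
  expect_equal(feature_areas(two)$areas, c(9, 9))

  # diagonal touch: one component at 8-connectivity, two at 4
  diag2 <- matrix(0L, 6, 6); diag2[2, 2] <- 1L; diag2[3, 3] <- 1L
  expect_identical(feature_areas(diag2, 8L)$N, 1L)
  expect_identical(feature_areas(diag2, 4L)$N, 2L)

  set.seed(42)
  for (i in 1:30) {
    m <- matrix(as.integer(runif(32 * 32) < 0.35), 32, 32)
    for (conn in c(4L, 8L)) {
      oracle <- flood_fill_label(m, conn)
      fs <- feature_areas(m, conn)
      expect_identical(fs$areas, sort(as.numeric(tabulate(oracle[oracle > 0]))))
    }
    expect_lte(feature_areas(m, 8L)$N, feature_areas(m, 4L)$N)
    # EBImage's 4-connective labeller as an independent cross-check
    eb <- EBImage::bwlabel(m)
    expect_identical(feature_areas(m, 4L)$N, as.integer(max(eb)))
  }

  # physical units
  fs_um <- feature_areas(two, pixel_size = 0.5)
  expect_equal(fs_um$areas, c(9, 9) * 0.25)
  expect_identical(fs_um$unit, "um2")
})

test_that("integrated feature size equals direct summation and obeys bounds", {
  expect_equal(integrated_feature_size(5), 5)
  expect_equal(integrated_feature_size(numeric(0)), 0)
  expect_equal(integrated_feature_size(c(1, 2, 3)), 14 / 6)
  expect_error(integrated_feature_size(c(3, -1)), "positive")

  set.seed(7)
  for (i in 1:50) {
    f <- sample.int(500, sample.int(30, 1), replace = TRUE)
    direct <- 0
    for (a in f) direct <- direct + a^2
    expect_identical(integrated_feature_size(f), direct / sum(f))
    ifs <- integrated_feature_size(f)
    expect_gte(ifs, min(f)); expect_lte(ifs, max(f))
    # equal areas: IFS is exactly that area
    expect_equal(integrated_feature_size(rep(f[1L], 5)), f[1L])
    # merging two features never decreases IFS
    if (length(f) >= 2) {
      merged <- c(f[-(1:2)], f[1L] + f[2L])
      expect_gte(integrated_feature_size(merged), ifs)
    }
  }
})

test_that("morphological score follows the rubric on constructed fields", {
  blank <- matrix(0L, 64, 64)
  expect_identical(morphological_score(blank), 0L)

  put <- function(m, r, c, h, w) { m[r:(r + h - 1), c:(c + w - 1)] <- 1L; m }
  # a few single platelets: sparse coverage, all features below 50 px -> 1
  sparse <- put(put(put(blank, 2, 2, 3, 3), 10, 10, 3, 3), 20, 20, 3, 3)
  expect_identical(morphological_score(sparse), 1L)
  # extensive single-platelet coverage (>10%) -> 2
  dense <- blank
  for (r in seq(1, 61, 8)) for (c in seq(1, 61, 8)) dense <- put(dense, r, c, 4, 4)
  expect_identical(morphological_score(dense), 2L)
  # small aggregate (<= 500 px largest) -> 3
  expect_identical(morphological_score(put(blank, 5, 5, 10, 10)), 3L)
  # intermediate aggregate -> 4
  expect_identical(morphological_score(put(blank, 5, 5, 25, 25)), 4L)
  # a full-thrombus aggregate above the large-aggregate cut -> 5
  expect_identical(morphological_score(put(blank, 5, 5, 48, 48)), 5L)

  expect_error(score_calibration(single_platelet_px = 600,
                                 small_aggregate_px = 500),
               "increasing")
})

test_that("stable adhesion measures the persistent pixel population", {
  sc <- gen_scene(30, dim = c(128L, 128L), area_meanlog = log(55),
                  noise_sd = 0, seed = 21)
  # static series: stable adhesion equals total coverage
  st <- gen_series(sc, stable_fraction = 1, seed = 22)
  expect_equal(stable_adhesion(st), 100 * sc$truth_coverage)
  # fully transient series: nothing persists
  fl <- gen_series(sc, stable_fraction = 0, seed = 22)
  expect_equal(stable_adhesion(fl), 0)
  # half-stable series: measured value matches the generator truth closely
  hf <- gen_series(sc, stable_fraction = 0.5, seed = 23)
  truth_pct <- 100 * sum(hf$stable_mask) / length(hf$stable_mask)
  expect_lt(abs(stable_adhesion(hf) - truth_pct), 0.5)

  expect_error(stable_adhesion(list(matrix(0, 4, 4), matrix(0, 5, 5))),
               "identical dimensions")
  expect_error(stable_adhesion(list(matrix(0, 4, 4))), "two frames")
})

test_that("thrombus volume per area matches analytic and generated truth", {
  # uniform block: 10 fully occupied slices at 0.5 um spacing -> 5 um3/um2
  block <- replicate(10, matrix(80, 32, 32), simplify = FALSE)
  expect_equal(thrombus_volume(block, slice_spacing = 0.5, pixel_size = 0.2,
                               threshold = 50), 5)
  # empty stack
  empty <- replicate(4, matrix(20, 32, 32), simplify = FALSE)
  expect_equal(thrombus_volume(empty, slice_spacing = 0.5, threshold = 50), 0)
  expect_equal(thrombus_volume(empty, slice_spacing = 0.5), 0)  # otsu on constant

  for (s in 1:3) {
    sc <- gen_scene(25, dim = c(128L, 128L), area_meanlog = log(50),
                    seed = 30 + s)
    st <- gen_stack(sc, n_slices = 10L, seed = 40 + s)
    v <- thrombus_volume(st)
    expect_equal(v, st$truth_volume_per_area,
                 tolerance = 0.02 * max(st$truth_volume_per_area, 1))
  }
  expect_error(thrombus_volume(block, slice_spacing = 0), "positive")
  expect_error(thrombus_volume(block[1L], slice_spacing = 0.5), "two slices")
})

test_that("marker coverage applies the non-specific label correction", {
  blank <- matrix(0, 64, 64)
  expect_equal(marker_coverage(blank, method = "fixed", threshold = 50), 0)

  sig <- blank; sig[1:16, 1:31] <- 200   # 496/4096 px
  cov <- marker_coverage(sig, method = "fixed", threshold = 100,
                         morphology = FALSE)
  expect_equal(cov, 100 * 496 / 4096)
  expect_equal(marker_coverage(sig, nonspecific_control = 2,
                               method = "fixed", threshold = 100,
                               morphology = FALSE), cov - 2)
  # control image route and the floor at zero
  ctrl <- blank; ctrl[1:32, 1:40] <- 200
  expect_equal(marker_coverage(sig, nonspecific_control = ctrl,
                               method = "fixed", threshold = 100,
                               morphology = FALSE), 0)
  expect_error(marker_coverage(sig, nonspecific_control = 120), "100")
})
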