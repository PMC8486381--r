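test_that("Yen threshold separates a two-level image", {
  x <- matrix(c(rep(0, 60), rep(255, 40)), 10, 10)
  thr <- yen_threshold(x)
  expect_true(thr > 0 && thr < 255)
  expect_equal(sum(x > thr), 40)
})

test_that("Yen threshold equals brute-force criterion maximization", {
  for (seed in 1:12) {
    x <- two_mode_image(seed)
    expect_equal(yen_threshold(x), yen_bruteforce(x), tolerance = 1e-12)
  }
})

test_that("constant images have no threshold", {
  expect_error(yen_threshold(matrix(7, 5, 5)), "constant")
})

test_that("particle analysis measures a disk as near-circular", {
  m <- disk_mask(21, c(11, 11), 5)
  ps <- analyze_particles(m, pixel_size_um = 0.1)
  expect_equal(nrow(ps$records), 1L)
  expect_gte(ps$records$circularity, 0.85)
  expect_lte(ps$records$circularity, 1)
  expect_equal(ps$records$n_px, sum(m))
  # centroid of a symmetric disk is its centre, pixel-centre convention
  expect_equal(ps$records$centroid_x_um, (11 - 0.5) * 0.1)
  expect_equal(ps$records$centroid_y_um, (11 - 0.5) * 0.1)
})

test_that("a thin line fails the default circularity filter", {
  m <- matrix(FALSE, 40, 40)
  m[20, 5:34] <- TRUE                      # 1 px x 30 px
  ps <- analyze_particles(m, pixel_size_um = 0.1)
  expect_equal(nrow(ps$records), 0L)
  expect_equal(ps$n_discarded, 1L)
  ps_all <- analyze_particles(m, pixel_size_um = 0.1, circularity_range = c(0, 1))
  expect_lt(ps_all$records$circularity, 0.5)
})

test_that("empty masks give empty PunctaSets and components are 8-connected", {
  empty <- analyze_particles(matrix(FALSE, 10, 10), 0.1)
  expect_equal(nrow(empty$records), 0L)
  diagpair <- matrix(FALSE, 6, 6)
  diagpair[2, 2] <- TRUE; diagpair[3, 3] <- TRUE
  ps <- analyze_particles(diagpair, 0.1, circularity_range = c(0, 1))
  expect_equal(nrow(ps$records), 1L)      # one object under 8-connectivity
})

test_that("particle analysis is idempotent on its own rendered mask", {
  set.seed(3)
  m <- matrix(runif(3600) > 0.92, 60, 60)
  ps <- analyze_particles(m, 0.1, circularity_range = c(0, 1))
  ps2 <- analyze_particles(puncta_mask(ps), 0.1, circularity_range = c(0, 1))
  expect_equal(ps2$records$area_um2, ps$records$area_um2)
  expect_equal(ps2$records$centroid_x_um, ps$records$centroid_x_um)
  expect_identical(ps2$label_map, ps$label_map)
})

test_that("retained plus discarded counts equal total component count", {
  set.seed(9)
  m <- matrix(runif(4900) > 0.9, 70, 70)
  total <- nrow(analyze_particles(m, 0.1, circularity_range = c(0, 1))$records)
  filt <- analyze_particles(m, 0.1, size_range_um2 = c(0.02, 0.1),
                            circularity_range = c(0.5, 1))
  expect_equal(nrow(filt$records) + filt$n_discarded, total)
  expect_true(all(filt$records$area_um2 >= 0.02 & filt$records$area_um2 <= 0.1))
  expect_true(all(filt$records$circularity >= 0.5 & filt$records$circularity <= 1))
})

test_that("size bins follow the printed boundary conventions", {
  areas <- c(0.11, 0.12, 0.24, 0.2401, 0.50, 0.499)
  ps <- structure(list(
    label_map = matrix(0L, 1, 1),
    records = data.frame(id = seq_along(areas), n_px = 1L, area_um2 = areas,
                         centroid_x_um = 0, centroid_y_um = 0,
                         circularity = 1, mean_intensity = NA_real_),
    pixel_size_um = 0.1, n_discarded = 0L), class = "PunctaSet")
  cl <- classify_size(ps)$records
  expect_equal(as.character(cl$bin), c("B1", "B2", "B2", "B3", "B3", "B3"))
  expect_equal(cl$large, c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
})

test_that("segment_puncta restricted to a cell mask ignores outside pixels", {
  sc <- make_scene(scene_spec(seed = 21, n_puncta = 10))
  seg <- segment_puncta(sc$images[[1]], sc$cell_mask)
  inside <- sc$cell_mask$pixels
  expect_true(all(seg$label_map[!inside] == 0L))
  expect_gt(nrow(seg$records), 0L)
})
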