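test_that("identical masks colocalize fully and disjoint masks not at all", {
  a <- squares_mask(60, 5)
  res <- percent_colocalization(a, a)
  expect_equal(res$percent, 100)
  expect_equal(res$count_A, 5L)
  b <- matrix(FALSE, 60, 60); b[55:58, 55:58] <- TRUE
  expect_equal(percent_colocalization(a, b)$percent, 0)
})

test_that("the printed formula is reproduced on a constructed 4-of-10 case", {
  a <- squares_mask(80, 10, size = 3L, step = 14L)
  # one B square overlapping each of the first four A objects
  b <- matrix(FALSE, 80, 80)
  ps <- analyze_particles(a, 1, circularity_range = c(0, 1))
  for (i in 1:4) {
    r <- round(ps$records$centroid_y_um[i] + 0.5)
    c <- round(ps$records$centroid_x_um[i] + 0.5)
    b[r:(r + 2), c:(c + 2)] <- TRUE
  }
  res <- percent_colocalization(a, b)
  expect_equal(res$count_A, 10L)
  expect_equal(res$count_AND, 4L)
  expect_equal(res$percent, 40)
  # brute-force oracle: pixelwise AND plus component count must agree
  expect_equal(res$count_AND, max(erpuncta:::cc_label8(a & b)))
})

test_that("and_count can exceed 100 percent and is flagged; object_hit cannot", {
  a <- matrix(FALSE, 20, 20); a[5:15, 10] <- TRUE          # one long A object
  b <- matrix(FALSE, 20, 20); b[6, 10] <- TRUE; b[12, 10] <- TRUE
  res <- percent_colocalization(a, b, mode = "and_count")
  expect_equal(res$percent, 200)
  expect_true(res$over_100)
  hit <- percent_colocalization(a, b, mode = "object_hit")
  expect_equal(hit$percent, 100)
  expect_false(hit$over_100)
})

test_that("AND count is symmetric but the percent is not", {
  set.seed(4)
  a <- matrix(runif(900) > 0.8, 30, 30)
  b <- matrix(runif(900) > 0.6, 30, 30)
  ab <- percent_colocalization(a, b)
  ba <- percent_colocalization(b, a)
  expect_equal(ab$count_AND, ba$count_AND)
  expect_false(isTRUE(all.equal(ab$percent, ba$percent)))
})

test_that("an empty A channel yields an undefined percent, not zero", {
  res <- percent_colocalization(matrix(FALSE, 10, 10), squares_mask(10, 1))
  expect_true(res$undefined)
  expect_true(is.na(res$percent))
  expect_error(percent_colocalization(matrix(FALSE, 5, 5), matrix(FALSE, 6, 6)),
               "congruent")
})

test_that("size-stratified percents use per-bin denominators", {
  sc <- make_scene(scene_spec(seed = 31, channels = c("A", "B"), n_puncta = 40,
                              coloc_fraction = 0.5,
                              bin_weights = c(B1 = 1, B2 = 0, B3 = 0, large = 0)))
  segA <- classify_size(segment_puncta(sc$images$A, sc$cell_mask))
  maskB <- puncta_mask(segment_puncta(sc$images$B, sc$cell_mask))
  strat <- size_stratified_colocalization(segA, maskB)
  expect_equal(strat$bin, c("B1", "B2", "B3"))
  # single populated bin: stratified percent equals the unstratified one
  one_bin <- strat[strat$n_A > 0, ]
  if (nrow(one_bin) == 1L) {
    overall <- percent_colocalization(puncta_mask(segA), maskB)
    expect_equal(one_bin$percent, overall$percent, tolerance = 1e-9)
  }
  expect_true(all(is.na(strat$percent[strat$n_A == 0])))
})

test_that("area overlap fraction follows pixel arithmetic", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE        # 100 px
  b <- matrix(FALSE, 20, 20); b[1:10, 1:3] <- TRUE         # 30 px overlap
  expect_equal(area_overlap_fraction(a, b), 0.30)
  expect_equal(area_overlap_fraction(b, a), 1.0)           # B inside A
  expect_equal(area_overlap_fraction(a, !a), 0)
  expect_error(area_overlap_fraction(matrix(FALSE, 5, 5), matrix(TRUE, 5, 5)),
               "empty")
})

test_that("estimated colocalization tracks the programmed fraction", {
  est <- vapply(1:3, function(s) {
    sc <- make_scene(scene_spec(seed = 400 + s, channels = c("A", "B"),
                                n_puncta = 40, coloc_fraction = 0.5,
                                bin_weights = c(B1 = 0.5, B2 = 0.3, B3 = 0.2,
                                                large = 0)))
    percent_colocalization(
      puncta_mask(segment_puncta(sc$images$A, sc$cell_mask)),
      puncta_mask(segment_puncta(sc$images$B, sc$cell_mask)))$percent
  }, 0)
  expect_lt(abs(mean(est) - 50), 12)
})
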