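test_that("site intensity is background-subtracted mean intensity", {
  px <- matrix(10, 20, 20)
  px[5:8, 5:8] <- 50
  img <- calibrated_image(px, 0.1)
  sites <- region_mask(px == 50, kind = "site")
  bg <- matrix(FALSE, 20, 20); bg[15:18, 15:18] <- TRUE
  res <- site_intensity(img, sites, region_mask(bg, kind = "background"))
  expect_equal(res$corrected_AU, 40)
  expect_false(res$negative_flag)
  # site at background level measures zero
  dim_sites <- matrix(FALSE, 20, 20); dim_sites[1:2, 1:2] <- TRUE
  res0 <- site_intensity(img, region_mask(dim_sites, "site"),
                         region_mask(bg, "background"))
  expect_equal(res0$corrected_AU, 0)
  expect_error(site_intensity(img, region_mask(matrix(FALSE, 20, 20), "site"),
                              region_mask(bg, "background")), "empty")
})

test_that("site intensity is invariant to a constant offset and flags negatives", {
  set.seed(5)
  px <- matrix(runif(400, 10, 30), 20, 20)
  sites <- matrix(FALSE, 20, 20); sites[2:5, 2:5] <- TRUE
  bg <- matrix(FALSE, 20, 20); bg[15:19, 15:19] <- TRUE
  r1 <- site_intensity(calibrated_image(px, 0.1), region_mask(sites, "site"),
                       region_mask(bg, "background"))
  r2 <- site_intensity(calibrated_image(px + 100, 0.1),
                       region_mask(sites, "site"), region_mask(bg, "background"))
  expect_equal(r1$corrected_AU, r2$corrected_AU, tolerance = 1e-12)
  px2 <- px; px2[bg] <- 100
  r3 <- site_intensity(calibrated_image(px2, 0.1), region_mask(sites, "site"),
                       region_mask(bg, "background"))
  expect_true(r3$negative_flag)
  expect_lt(r3$corrected_AU, 0)
})

test_that("relative intensity normalizes the control to exactly 1", {
  res <- relative_intensity(c(40, 40, 20, 20), c("ctrl", "ctrl", "kd", "kd"), "ctrl")
  expect_equal(res$relative[res$condition == "ctrl"], 1.0)
  expect_equal(res$relative[res$condition == "kd"], 0.5)
  only <- relative_intensity(c(7, 9), c("ctrl", "ctrl"), "ctrl")
  expect_equal(only$relative, 1.0)
  expect_error(relative_intensity(1:3, rep("a", 3), "ctrl"), "no values")
  expect_error(relative_intensity(c(0, 0, 5), c("c", "c", "t"), "c"), "positive")
})

test_that("relative intensity matches independent arithmetic and is scale-invariant", {
  vals <- c(12, 18, 30, 36, 5, 10)
  cond <- c("a", "a", "b", "b", "c", "c")
  res <- relative_intensity(vals, cond, "a")
  # spreadsheet-style oracle
  expect_equal(res$relative[res$condition == "b"], mean(c(30, 36)) / mean(c(12, 18)))
  expect_equal(res$relative[res$condition == "c"], mean(c(5, 10)) / mean(c(12, 18)))
  scaled <- relative_intensity(vals * 3.7, cond, "a")
  expect_equal(scaled$relative, res$relative, tolerance = 1e-12)
})

test_that("fold overexpression divides by the non-transfected mean", {
  expect_equal(fold_overexpression(20, c(10, 10)), 2.0)
  expect_equal(fold_overexpression(10, c(10, 10)), 1.0)
  # stable-line-like range: 4.4- and 5.5-fold
  expect_equal(fold_overexpression(c(44, 55), c(8, 12)), c(4.4, 5.5))
  expect_error(fold_overexpression(5, numeric(0)), "at least one")
  expect_error(fold_overexpression(5, c(0, 0)), "positive")
})
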