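test_that("scenes are bit-identical under a fixed seed", {
  sp <- scene_spec(seed = 5, n_puncta = 15, channels = c("A", "B"),
                   coloc_fraction = 0.4)
  sc1 <- make_scene(sp)
  sc2 <- make_scene(sp)
  expect_identical(sc1$images$A$pixels, sc2$images$A$pixels)
  expect_identical(sc1$images$B$pixels, sc2$images$B$pixels)
  expect_identical(sc1$truth$puncta, sc2$truth$puncta)
})

test_that("the programmed colocalization fraction is honoured in truth", {
  full <- make_scene(scene_spec(seed = 2, channels = c("A", "B"), n_puncta = 20,
                                coloc_fraction = 1))
  expect_equal(nrow(full$truth$coloc_pairs), 20L)
  trA <- full$truth$puncta[full$truth$puncta$channel == "A", ]
  trB <- full$truth$puncta[full$truth$puncta$channel == "B", ]
  # every pair co-centred within one pixel
  for (k in seq_len(nrow(full$truth$coloc_pairs))) {
    pa <- trA[trA$id == full$truth$coloc_pairs$idA[k], ]
    pb <- trB[trB$id == full$truth$coloc_pairs$idB[k], ]
    expect_lte(sqrt((pa$row_px - pb$row_px)^2 + (pa$col_px - pb$col_px)^2), 1)
  }
  none <- make_scene(scene_spec(seed = 2, channels = c("A", "B"), n_puncta = 20,
                                coloc_fraction = 0))
  expect_equal(nrow(none$truth$coloc_pairs), 0L)
  half <- make_scene(scene_spec(seed = 2, channels = c("A", "B"), n_puncta = 20,
                                coloc_fraction = 0.5))
  expect_equal(nrow(half$truth$coloc_pairs), 10L)
})

test_that("rendered footprints match requested areas within one pixel", {
  sc <- make_scene(scene_spec(seed = 13, n_puncta = 25))
  px2 <- sc$images[[1]]$pixel_size_um^2
  dev_px <- (sc$truth$puncta$area_um2 - sc$truth$puncta$req_area_um2) / px2
  expect_true(all(abs(dev_px) <= 1 + 1e-9))
})

test_that("impossible puncta densities raise a placement error", {
  sp <- scene_spec(image_shape = c(48L, 48L), n_puncta = 200, seed = 1)
  expect_error(make_scene(sp), "density")
})

test_that("time-lapse truth encodes the programmed motion", {
  sp <- scene_spec(image_shape = c(128L, 128L), n_puncta = 3, seed = 9)
  still <- make_timelapse(sp, n_frames = 5, frame_interval_s = 1,
                          speeds_um_s = 0, motion = "directed")
  traj <- still$truth$trajectories
  for (p in unique(traj$punctum)) {
    tp <- traj[traj$punctum == p, ]
    expect_equal(diff(tp$x_um), rep(0, 4))
    expect_equal(diff(tp$y_um), rep(0, 4))
  }
  mv <- make_timelapse(sp, n_frames = 6, frame_interval_s = 0.5,
                       speeds_um_s = 0.3, motion = "directed")
  tj <- mv$truth$trajectories
  for (p in unique(tj$punctum)) {
    tp <- tj[tj$punctum == p, ]
    steps <- sqrt(diff(tp$x_um)^2 + diff(tp$y_um)^2)
    if (!mv$truth$clipped[p]) {
      expect_equal(steps, rep(0.15, 5), tolerance = 1e-9)   # speed x interval
    }
  }
  rw1 <- make_timelapse(sp, 6, 0.5, 0.2, motion = "random_walk")
  rw2 <- make_timelapse(sp, 6, 0.5, 0.2, motion = "random_walk")
  expect_identical(rw1$truth$trajectories, rw2$truth$trajectories)
})

test_that("FRAP traces follow the programmed recovery model", {
  tr <- make_frap_trace(0.5, 13)
  truth <- attr(tr, "truth")
  expect_equal(truth$plateau, 0.1 + 0.5 * 0.9)
  n <- normalize_frap(tr)$norm
  expect_equal(n[tr$t_s < 0], rep(1, 6), tolerance = 1e-12)
  # full-recovery limit
  lim <- make_frap_trace(1, 2)
  nl <- normalize_frap(lim)$norm
  expect_equal(nl[length(nl)], 1, tolerance = 1e-3)
})

test_that("empirical truth colocalization converges to f", {
  fr <- vapply(1:6, function(s) {
    sc <- make_scene(scene_spec(seed = 600 + s, channels = c("A", "B"),
                                n_puncta = 60, coloc_fraction = 0.25))
    nrow(sc$truth$coloc_pairs) / 60
  }, 0)
  expect_equal(mean(fr), 0.25, tolerance = 0.02)
})
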