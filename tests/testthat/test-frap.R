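test_that("the default acquisition schedule matches the protocol", {
  s <- default_frap_schedule()
  expect_equal(sum(s < 0), 6L)                       # six pre-bleach frames
  expect_equal(diff(s[s < 0]), rep(0.5, 5))          # two frames per second
  fast <- s[s >= 0 & s <= 30.3]
  expect_equal(unique(diff(fast)), 0.5)              # continuous for 30 s
  slow <- s[s > 30.3]
  expect_equal(unique(diff(slow)), 2)                # then 2 s intervals
  expect_gt(max(s), 149)                             # ... for two minutes
})

test_that("double normalization is the identity on clean traces", {
  t <- default_frap_schedule()
  # no bleach, no monitor decay: everything at pre-bleach level
  tr <- frap_trace(t, bleach = rep(100, length(t)), whole_cell = rep(510, length(t)),
                   background = rep(10, length(t)))
  expect_equal(normalize_frap(tr)$norm, rep(1, length(t)), tolerance = 1e-12)
  # whole-cell decays 10% linearly and the bleach ROI tracks it exactly
  decay <- seq(1, 0.9, length.out = length(t))
  tr2 <- frap_trace(t, bleach = 10 + 90 * decay, whole_cell = 10 + 500 * decay,
                    background = rep(10, length(t)))
  expect_equal(normalize_frap(tr2)$norm, rep(1, length(t)), tolerance = 1e-12)
})

test_that("normalization inverts the forward model and ignores global gain", {
  tr <- make_frap_trace(0.7, 9, bleach_depth = 0.15, monitor_bleach_rate = 0.002)
  truth <- attr(tr, "truth")
  t <- tr$t_s
  expected <- ifelse(t < 0, 1, 0.15 + 0.7 * 0.85 * (1 - exp(-t * log(2) / 9)))
  expect_equal(normalize_frap(tr)$norm, expected, tolerance = 1e-9)
  gained <- frap_trace(tr$t_s, tr$bleach * 3.2, tr$whole_cell * 3.2,
                       tr$background * 3.2)
  expect_equal(normalize_frap(gained)$norm, normalize_frap(tr)$norm,
               tolerance = 1e-12)
})

test_that("generated traces honour the half-time definition", {
  tr <- make_frap_trace(0.8, 10)
  n <- normalize_frap(tr)$norm
  t <- tr$t_s
  expect_equal(mean(n[t < 0]), 1)
  # value at t = half_time: exactly half the recoverable range above b0
  at_half <- 0.1 + 0.8 * 0.9 * 0.5
  expect_equal(stats::approx(t[t >= 0], n[t >= 0], xout = 10)$y, at_half,
               tolerance = 1e-3)
  # immobile punctum: flat at bleach depth
  flat <- make_frap_trace(0, 10)
  nf <- normalize_frap(flat)$norm
  expect_equal(nf[flat$t_s >= 0], rep(0.1, sum(flat$t_s >= 0)), tolerance = 1e-12)
})

test_that("noiseless fits recover the generating parameters exactly", {
  for (M in c(0.2, 0.6, 0.9)) {
    for (tau in c(5, 13, 40)) {
      fit <- fit_frap(normalize_frap(make_frap_trace(M, tau)))
      expect_equal(fit$mobile_fraction, M, tolerance = 1e-6)
      expect_equal(fit$half_time_s, tau, tolerance = 1e-6)
    }
  }
})

test_that("an immobile trace yields zero mobile fraction with undefined half-time", {
  fit <- fit_frap(normalize_frap(make_frap_trace(0, 13)))
  expect_equal(fit$mobile_fraction, 0)
  expect_false(fit$half_time_defined)
  expect_true(is.na(fit$half_time_s))
})

test_that("fitted plateau stays within the data range plus noise", {
  set.seed(2)
  for (s in 1:10) {
    tr <- make_frap_trace(0.6, 13, noise_sd_frac = 0.02, seed = s)
    nt <- normalize_frap(tr)
    fit <- fit_frap(nt)
    expect_lte(fit$plateau, max(nt$norm) + 3 * 0.02)
  }
})

test_that("noisy Monte-Carlo fits centre on the generated mobile fraction", {
  fits <- vapply(1:40, function(s) {
    fit_frap(normalize_frap(make_frap_trace(0.6, 13, noise_sd_frac = 0.02,
                                            seed = s)))$mobile_fraction
  }, 0)
  expect_lt(abs(mean(fits) - 0.6), 0.05)
})

test_that("degenerate traces are rejected", {
  expect_error(make_frap_trace(0.5, -1), "positive")
  t <- default_frap_schedule()
  expect_error(frap_trace(t[1:6], 1:6, 1:6, 1:6), "post-bleach")
  tr <- make_frap_trace(0.5, 10)
  tr$whole_cell[10] <- tr$background[10] - 1
  expect_error(normalize_frap(tr), "exceed background")
})
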