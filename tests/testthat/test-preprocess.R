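# Binning, ring selection, detrending, frame splitting.

test_that("binning sums blocks, drops remainders, and conserves counts", {
  st <- frame_stack(array(1L, c(6, 6, 3)), 0.05)
  b3 <- bin_pixels(st, 3)
  expect_equal(dim(b3$counts), c(2L, 2L, 3L))
  expect_true(all(b3$counts == 9L))

  expect_identical(bin_pixels(st, 1), st)

  set.seed(5)
  a <- array(sample(0:9, 7 * 7 * 2, TRUE), c(7, 7, 2))
  b2 <- bin_pixels(frame_stack(a, 0.05), 2)
  expect_equal(dim(b2$counts), c(3L, 3L, 2L))
  brute <- array(0L, c(3, 3, 2))
  for (f in 1:2) for (i in 1:3) for (j in 1:3)
    brute[i, j, f] <- sum(a[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), f])
  expect_equal(b2$counts, brute, ignore_attr = TRUE)
  # count conservation over the covered region, per frame
  for (f in 1:2)
    expect_identical(sum(b2$counts[, , f]), sum(a[1:6, 1:6, f]))

  expect_error(bin_pixels(st, 4), class = "dxb_parameter_error")
})

test_that("a binned pixel is valid only when all constituents are valid", {
  m <- matrix(TRUE, 6, 6); m[2, 2] <- FALSE
  st <- frame_stack(array(0L, c(6, 6, 2)), 0.05, mask = m)
  b2 <- bin_pixels(st, 2)
  expect_false(b2$mask[1, 1])
  expect_equal(sum(!b2$mask), 1L)
})

test_that("binning commutes with frame splitting", {
  mv <- tiny_movie(n_spots = 5L, n_frames = 40L, shape = c(48L, 48L),
                   radius = 16)
  a <- lapply(split_frames(bin_pixels(mv$stack, 2), 4), function(s) s$counts)
  b <- lapply(split_frames(mv$stack, 4), function(s) bin_pixels(s, 2)$counts)
  expect_identical(a, b)
})

test_that("ring selection matches flat-detector trigonometry per pixel", {
  geom <- detector_geometry(1.54, 60, 172, beam_center = c(0, 0))
  roi <- ring_roi(12.59, 0.5)
  sel <- select_ring_pixels(geom, roi, bin_size = 1L, shape = c(160L, 160L))
  r_c <- 60 * tan(12.59 * pi / 180) / 0.172
  expect_equal(r_c, 77.9, tolerance = 1e-3)
  r_lo <- 60 * tan(12.09 * pi / 180) / 0.172
  r_hi <- 60 * tan(13.09 * pi / 180) / 0.172
  rad <- sqrt(sel$row^2 + sel$col^2)
  expect_true(all(rad >= r_lo & rad <= r_hi))
  expect_gt(nrow(sel), 0)

  # monotone in halfwidth: larger halfwidth selects a superset
  sel2 <- select_ring_pixels(geom, ring_roi(12.59, 1.0), bin_size = 1L,
                             shape = c(160L, 160L))
  expect_true(all(paste(sel$row, sel$col) %in% paste(sel2$row, sel2$col)))

  # degenerate halfwidth: all selected pixels within ~1 px of the circle
  sel0 <- select_ring_pixels(geom, ring_roi(12.59, 0.005), bin_size = 1L,
                             shape = c(160L, 160L))
  expect_true(all(abs(sqrt(sel0$row^2 + sel0$col^2) - r_c) < 1))

  # ROI entirely off-detector: empty selection with a warning
  expect_warning(
    off <- select_ring_pixels(geom, ring_roi(80, 0.1), bin_size = 1L,
                              shape = c(20L, 20L)),
    "no pixels")
  expect_equal(nrow(off), 0L)
})

test_that("masked pixels are excluded from ring selection", {
  geom <- detector_geometry(1.54, 60, 172, beam_center = c(0, 0))
  roi <- ring_roi(12.59, 0.5)
  mask <- matrix(TRUE, 160, 160)
  sel <- select_ring_pixels(geom, roi, mask, bin_size = 1L)
  mask[sel$row[1] + 1, sel$col[1] + 1] <- FALSE
  sel_m <- select_ring_pixels(geom, roi, mask, bin_size = 1L)
  expect_equal(nrow(sel_m), nrow(sel) - 1L)
})

test_that("detrending removes a linear ramp and preserves the mean", {
  # exact ramp -> constant at its mean
  tr <- pixel_trace(2 + 0.3 * (0:99))
  dt <- detrend_trace(tr, "always")
  expect_equal(dt$intensities, rep(mean(tr$intensities), 100))
  expect_true(dt$detrended)

  # zero-slope series unchanged under every policy
  set.seed(1)
  flat <- pixel_trace(rpois(200, 5))
  for (pol in c("auto", "never"))
    expect_equal(detrend_trace(flat, pol)$intensities, flat$intensities)

  # mean preserved to machine precision
  set.seed(2)
  y <- rpois(500, 10) + 0.02 * (0:499)
  td <- detrend_trace(pixel_trace(y), "always")
  expect_equal(mean(td$intensities), mean(y), tolerance = 1e-12)

  # auto removes a clear trend, leaves white noise alone
  set.seed(3)
  noisy_ramp <- pixel_trace(rpois(1000, 20) + 0.05 * (0:999))
  expect_true(detrend_trace(noisy_ramp, "auto")$detrended)
  white <- pixel_trace(rpois(1000, 20))
  expect_false(detrend_trace(white, "auto")$detrended)
})

test_that("detrending rescues the decay constant under a drift", {
  # paired simulation: 3x3-binned spot traces with and without a slow
  # beam drift; detrending restores the ramp-free decay constant
  set.seed(4)
  s <- simulate_telegraph_states(0.3, 0.3, 2000, 0.05, 20, seed = 9)
  pair <- vapply(1:20, function(i) {
    base <- rpois(2000, 45 * s[i, ] + 18)
    ramped <- base + 0.01 * (0:1999)
    c(classify_and_fit(detrend_trace(pixel_trace(base), "never"))$gamma,
      classify_and_fit(detrend_trace(pixel_trace(ramped), "always"))$gamma)
  }, numeric(2))
  expect_equal(stats::median(pair[2, ]), stats::median(pair[1, ]),
               tolerance = 0.10)
})

test_that("frame splitting yields contiguous equal blocks", {
  mv <- tiny_movie(n_spots = 0L, n_frames = 2000L, shape = c(8L, 8L),
                   radius = 3, background = 1)
  parts <- split_frames(mv$stack, 10)
  expect_length(parts, 10L)
  expect_true(all(vapply(parts, function(s) dim(s$counts)[3], numeric(1)) == 200))
  expect_identical(parts[[1]]$counts[, , 1], mv$stack$counts[, , 1])
  expect_identical(parts[[10]]$counts[, , 200], mv$stack$counts[, , 2000])

  one <- split_frames(mv$stack, 1)
  expect_identical(one[[1]]$counts, mv$stack$counts)

  # odd frame count: tail frame dropped
  st <- frame_stack(array(0L, c(2, 2, 2001)), 0.05)
  two <- split_frames(st, 2)
  expect_equal(vapply(two, function(s) dim(s$counts)[3], numeric(1)), c(1000, 1000))
  expect_error(split_frames(st, 5000), class = "dxb_parameter_error")
})
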