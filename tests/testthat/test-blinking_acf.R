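# The ACF estimator, constrained exponential fitting, acceptance logic,
# and direction classification.

test_that("compute_acf matches hand-computable cases", {
  # constant positive trace: ACF identically 1
  tr <- pixel_trace(rep(4, 64))
  a <- compute_acf(tr)
  expect_true(all(a$values == 1))
  expect_equal(a$lags, seq_len(16) * 0.05)

  # alternating 0,2,0,2,...: odd-lag products vanish, even lags give 2
  tr2 <- pixel_trace(rep(c(0, 2), 500))
  a2 <- compute_acf(tr2, max_lag_fraction = 0.01)
  expect_equal(a2$values[1], 0)
  expect_equal(a2$values[2], 2)

  expect_error(compute_acf(pixel_trace(rep(0, 64))),
               class = "dxb_normalization_error")
  expect_error(compute_acf(pixel_trace(c(1, 2, 3))),
               class = "dxb_parameter_error")
})

test_that("compute_acf agrees with the naive double loop to machine precision", {
  set.seed(10)
  for (n in c(17, 33, 64)) {
    tr <- pixel_trace(rpois(n, 6))
    fast <- compute_acf(tr)
    slow <- dxblink:::compute_acf_naive(tr)
    expect_equal(fast$values, slow$values, tolerance = 1e-14)
  }
})

test_that("the estimator is exactly scale- and reversal-invariant", {
  set.seed(11)
  x <- rpois(512, 7)
  base <- compute_acf(pixel_trace(x))$values
  # power-of-two integer scalings are bit-exact; others to near machine eps
  for (c in c(2, 8))
    expect_identical(compute_acf(pixel_trace(c * x))$values, base)
  for (c in c(3, 0.5))
    expect_equal(compute_acf(pixel_trace(c * x))$values, base,
                 tolerance = 1e-12)
  # reversal: the set of lag-m products is unchanged; integer sums are exact
  expect_identical(compute_acf(pixel_trace(rev(x)))$values, base)
})

test_that("estimator matches the telegraph closed form on a long trace", {
  s <- as.numeric(simulate_telegraph_states(1, 1, 1e5, 0.05, 1, seed = 12))
  a <- compute_acf(pixel_trace(s), max_lag_fraction = 20 / 1e5)
  theo <- expected_normalized_acf(1, 1, 1, 0, a$lags)
  expect_lt(max(abs(a$values / theo - 1)), 0.02)
})

test_that("fit_acf recovers the printed model exactly on noiseless data", {
  ac <- model_acf_curve(A = 0.080, gamma = 0.243, y = 0.841)
  f <- fit_acf(ac)
  expect_true(f$accepted)
  expect_equal(f$A, 0.080, tolerance = 1e-6)
  expect_equal(f$gamma, 0.243, tolerance = 1e-6)
  expect_equal(f$y, 0.841, tolerance = 1e-6)
  expect_lt(f$residual, 1e-12)
})

test_that("fit_acf rejects flat curves and handles noise", {
  flat <- structure(list(lags = seq(0.05, 5, 0.05),
                         values = rep(1, 100), n_frames_used = 400L),
                    class = "acf_curve")
  f <- fit_acf(flat)
  expect_false(f$accepted)

  # Gamma recovered within 10% (median over seeded replicates) at sigma 0.01
  set.seed(13)
  gs <- replicate(100, {
    ac <- model_acf_curve(0.080, 0.243, 0.841, noise_sd = 0.01)
    fit_acf(ac)$gamma
  })
  expect_lt(abs(stats::median(gs) / 0.243 - 1), 0.10)
})

test_that("acceptance rule implements the four printed conditions", {
  set.seed(14)
  for (i in 1:200) {
    A <- stats::runif(1, -0.5, 0.5)
    g <- stats::runif(1, -1, 2)
    y <- stats::runif(1, -0.5, 1.5)
    r <- stats::runif(1, 0, 2)
    expect_identical(fit_accepted(A, g, y, r),
                     A > 0 && y > 0 && g > 0 && r < 1.0)
  }
})

test_that("direction classification fits decay and growth consistently", {
  dec <- model_acf_curve(0.080, 0.243, 0.841, direction = "decay")
  fd <- classify_and_fit(pixel_trace(rpois(64, 5)))  # exercises trace path
  expect_s3_class(fd, "exp_fit")

  f1 <- dxblink:::fit_classified(dec)
  expect_equal(f1$direction, "decay")
  expect_equal(f1$gamma, 0.243, tolerance = 1e-6)

  # mirrored curve: growth direction, same decay constant
  gro <- model_acf_curve(0.080, 0.243, 0.841, direction = "growth")
  f2 <- dxblink:::fit_classified(gro)
  expect_equal(f2$direction, "growth")
  expect_equal(f2$gamma, 0.243, tolerance = 1e-6)
  expect_true(f2$accepted)
})

test_that("pixel ensembles split into both directions and recover the rate", {
  # simulated telegraph pixels plus signal-free neighbours: blinking pixels
  # decay (a stationary trace's sample ACF starts at its maximum), while
  # noise-dominated pixels scatter into both direction classes
  set.seed(15)
  n <- 120; R <- 0.6
  s <- simulate_telegraph_states(R / 2, R / 2, 2000, 0.05, n, seed = 16)
  fits <- lapply(seq_len(n), function(i)
    classify_and_fit(pixel_trace(rpois(2000, 45 * s[i, ] + 18))))
  noise <- lapply(seq_len(60), function(i)
    classify_and_fit(pixel_trace(rpois(2000, 18))))
  acc <- vapply(fits, function(f) isTRUE(f$accepted), logical(1))
  gam <- vapply(fits, function(f) f$gamma, numeric(1))
  dirs <- vapply(c(fits, noise), function(f) f$direction, character(1))
  expect_gt(sum(dirs == "decay"), 0)
  expect_gt(sum(dirs == "growth"), 0)
  expect_lt(abs(stats::median(gam[acc]) / R - 1), 0.15)
})

test_that("analyze_stack tables every pixel with acceptance bookkeeping", {
  mv <- tiny_movie(n_spots = 8L, n_frames = 500L, seed = 17)
  tab <- analyze_stack(mv$stack, verbose = FALSE)
  expect_equal(nrow(tab), 64 * 64)
  expect_true(all(c("row", "col", "direction", "A", "gamma", "y", "residual",
                    "accepted", "reason") %in% names(tab)))
  expect_true(all(!tab$accepted | !is.na(tab$gamma)))
  # rejected pixels carry a named violation
  rej <- tab[!tab$accepted, ]
  expect_true(all(!is.na(rej$reason)))

  # empty ROI: empty table with a warning
  expect_warning(
    empty <- analyze_stack(mv$stack, pixels = data.frame(row = integer(),
                                                         col = integer())),
    "empty ROI")
  expect_equal(nrow(empty), 0L)
})

test_that("a static noiseless spot yields a flat ACF and is rejected", {
  counts <- array(0L, c(16, 16, 200))
  counts[8, 8, ] <- 50L
  st <- frame_stack(counts, 0.05)
  tab <- analyze_stack(st, pixels = data.frame(row = 7L, col = 7L),
                       verbose = FALSE)
  expect_false(any(tab$accepted))
})
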