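# Synthetic blinking-movie simulator.
#
# Diffraction spots on a Debye-Scherrer ring switch between a diffracting
# ("on") and non-diffracting ("off") state. Two kinetic models are provided:
# a two-state telegraph process (the analytic workhorse: its state
# autocovariance decays as exp(-(k_on + k_off) * tau), so the decay constant
# recovered by the ACF analysis has a known ground truth) and a discretized
# rotational Brownian walk through a finite angular acceptance window.
# Rendered movies add Poisson photon noise and an optional linear drift.

#' Simulation configuration for synthetic blinking movies
#'
#' @param n_spots Number of diffraction spots on the ring.
#' @param k_on Entry rate into the diffracting state (s^-1).
#' @param k_off Exit rate out of the diffracting state (s^-1).
#' @param on_intensity Expected photons per frame emitted by one "on" spot
#'   (spread over its point-spread footprint).
#' @param background Expected background photons per pixel per frame.
#' @param psf_size Odd integer; spots occupy a `psf_size x psf_size` uniform
#'   square footprint (default 3, the typical observed spot extent).
#' @param n_frames Number of frames.
#' @param frame_interval Frame interval in seconds (default 0.05).
#' @param exposure Exposure per frame in seconds (default 0.042); metadata
#'   only — counts represent the full interval.
#' @param drift_slope Linear intensity drift in counts/frame added at spot
#'   pixels (default 0).
#' @param seed Integer seed; identical seed and config give a bit-identical
#'   movie.
#' @param mode `"telegraph"` or `"angular_diffusion"`.
#' @param angular List with `diffusion` (rad^2/s), `halfwidth` (rad) and
#'   optionally `range` (rad, default `5 * halfwidth`); used only in
#'   angular-diffusion mode.
#' @param shape Detector dimensions `c(rows, cols)` in pixels.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_spots, k_on, k_off, on_intensity, background,
                       psf_size = 3L, n_frames = 2000L, frame_interval = 0.05,
                       exposure = 0.042, drift_slope = 0, seed = NULL,
                       mode = c("telegraph", "angular_diffusion"),
                       angular = NULL, shape = c(192L, 192L)) {
  mode <- match.arg(mode)
  if (!is_count(n_spots)) stop_parameter("n_spots must be a non-negative integer")
  if (!is_scalar_num(k_on) || k_on <= 0) stop_parameter("k_on must be > 0")
  if (!is_scalar_num(k_off) || k_off <= 0) stop_parameter("k_off must be > 0")
  if (!is_scalar_num(on_intensity) || on_intensity < 0)
    stop_parameter("on_intensity must be >= 0")
  if (!is_scalar_num(background) || background < 0)
    stop_parameter("background must be >= 0")
  if (!is_count(psf_size) || psf_size < 1 || psf_size %% 2 == 0)
    stop_parameter("psf_size must be an odd integer >= 1")
  if (!is_count(n_frames) || n_frames < 2) stop_parameter("n_frames must be >= 2")
  if (!is_scalar_num(frame_interval) || frame_interval <= 0)
    stop_parameter("frame_interval must be > 0")
  if (mode == "angular_diffusion") {
    if (is.null(angular) || !is_scalar_num(angular$diffusion) ||
        !is_scalar_num(angular$halfwidth) ||
        angular$diffusion <= 0 || angular$halfwidth <= 0)
      stop_parameter("angular mode needs positive 'diffusion' and 'halfwidth'")
    if (is.null(angular$range)) angular$range <- 5 * angular$halfwidth
  }
  structure(list(
    n_spots = as.integer(n_spots), k_on = k_on, k_off = k_off,
    on_intensity = on_intensity, background = background,
    psf_size = as.integer(psf_size), n_frames = as.integer(n_frames),
    frame_interval = frame_interval, exposure = exposure,
    drift_slope = drift_slope, seed = seed, mode = mode, angular = angular,
    shape = as.integer(shape)
  ), class = "sim_config")
}

#' Simulate stationary two-state telegraph trajectories
#'
#' Continuous-time two-state Markov chain ("off" -> "on" at rate `k_on`,
#' "on" -> "off" at rate `k_off`) sampled at the frame times using the exact
#' two-state master-equation propagator over one interval, so transition
#' probabilities are unbiased at any frame interval. The initial state of
#' each spot is drawn from the stationary distribution
#' `P(on) = k_on / (k_on + k_off)`.
#'
#' @param k_on,k_off Transition rates (s^-1), both > 0.
#' @param n_frames Number of frames (>= 2).
#' @param frame_interval Sampling interval (s).
#' @param n_spots Number of independent trajectories.
#' @param seed Optional integer seed (local to this call).
#' @return Integer 0/1 matrix, `n_spots` rows by `n_frames` columns.
#' @export
simulate_telegraph_states <- function(k_on, k_off, n_frames,
                                      frame_interval = 0.05, n_spots = 1L,
                                      seed = NULL) {
  if (!is_scalar_num(k_on) || k_on <= 0) stop_parameter("k_on must be > 0")
  if (!is_scalar_num(k_off) || k_off <= 0) stop_parameter("k_off must be > 0")
  if (!is_count(n_frames) || n_frames < 2) stop_parameter("n_frames must be >= 2")
  if (!is_count(n_spots) || n_spots < 1) stop_parameter("n_spots must be >= 1")
  R <- k_on + k_off
  p_on <- k_on / R
  decay <- exp(-R * frame_interval)
  # Exact propagator over one interval:
  #   P(on -> on)  = p_on + (1 - p_on) * decay
  #   P(off -> on) = p_on * (1 - p_on -> ...) = p_on * (1 - decay)
  p_on_given_on <- p_on + (1 - p_on) * decay
  p_on_given_off <- p_on * (1 - decay)
  with_seed(seed, {
    s <- matrix(0L, n_spots, n_frames)
    s[, 1L] <- as.integer(stats::runif(n_spots) < p_on)
    for (t in 2L:n_frames) {
      prev <- s[, t - 1L]
      p <- ifelse(prev == 1L, p_on_given_on, p_on_given_off)
      s[, t] <- as.integer(stats::runif(n_spots) < p)
    }
    s
  })
}

#' Closed-form expected normalized ACF of a single-spot telegraph pixel
#'
#' For a pixel whose expected intensity is `on_intensity * state + background`
#' with a stationary telegraph `state`, the normalized autocorrelation
#' `<I(t) I(t+tau)> / <I>^2` equals
#' `1 + (Var[I] / E[I]^2) * exp(-(k_on + k_off) * tau)`.
#' Serves as the independent oracle for the estimator.
#'
#' @param k_on,k_off Telegraph rates (s^-1).
#' @param on_intensity Intensity added in the "on" state.
#' @param background Constant baseline intensity.
#' @param tau Lag time(s) in seconds, >= 0 (vectorized).
#' @return Expected normalized ACF value(s).
#' @export
expected_normalized_acf <- function(k_on, k_off, on_intensity, background, tau) {
  if (!is_scalar_num(k_on) || k_on <= 0) stop_parameter("k_on must be > 0")
  if (!is_scalar_num(k_off) || k_off <= 0) stop_parameter("k_off must be > 0")
  if (any(tau < 0)) stop_parameter("tau must be >= 0")
  p <- k_on / (k_on + k_off)
  mu <- on_intensity * p + background
  if (mu <= 0) stop_normalization("mean intensity is zero; Eq.-1 normalization undefined")
  v <- on_intensity^2 * p * (1 - p)
  1 + (v / mu^2) * exp(-(k_on + k_off) * tau)
}

#' Simulate on/off states from rotational diffusion through a Bragg window
#'
#' Each spot's orientation angle performs a discretized Brownian walk
#' (per-frame increment sd `sqrt(2 * diffusion * frame_interval)`) with
#' reflecting boundaries at `+/- range`; the spot diffracts ("on") while
#' `|angle| < halfwidth`. Angles start uniform over the full range, so the
#' stationary on-fraction is `halfwidth / range`.
#'
#' @param diffusion Rotational diffusion coefficient (rad^2/s), > 0.
#' @param halfwidth Angular acceptance half-width (rad), > 0.
#' @param n_frames,frame_interval,n_spots,seed As in
#'   [simulate_telegraph_states()].
#' @param range Reflecting boundary (rad); default `5 * halfwidth`.
#' @return Integer 0/1 matrix, `n_spots` rows by `n_frames` columns.
#' @export
simulate_angular_diffusion_states <- function(diffusion, halfwidth, n_frames,
                                              frame_interval = 0.05,
                                              n_spots = 1L, seed = NULL,
                                              range = 5 * halfwidth) {
  if (!is_scalar_num(diffusion) || diffusion <= 0)
    stop_parameter("diffusion must be > 0")
  if (!is_scalar_num(halfwidth) || halfwidth <= 0)
    stop_parameter("halfwidth must be > 0")
  if (!is_scalar_num(range) || range <= 0) stop_parameter("range must be > 0")
  if (!is_count(n_frames) || n_frames < 2) stop_parameter("n_frames must be >= 2")
  if (!is_count(n_spots) || n_spots < 1) stop_parameter("n_spots must be >= 1")
  sd_step <- sqrt(2 * diffusion * frame_interval)
  with_seed(seed, {
    ang <- stats::runif(n_spots, -range, range)
    s <- matrix(0L, n_spots, n_frames)
    s[, 1L] <- as.integer(abs(ang) < halfwidth)
    for (t in 2L:n_frames) {
      ang <- ang + stats::rnorm(n_spots, sd = sd_step)
      # reflect at +/- range by folding onto the period-4*range sawtooth
      y <- (ang + range) %% (4 * range)
      ang <- ifelse(y > 2 * range, 3 * range - y, y - range)
      s[, t] <- as.integer(abs(ang) < halfwidth)
    }
    s
  })
}

#' Ring geometry for the simulator, in pixel units
#'
#' @param center `c(row, col)` beam/ring center, 0-based pixel coordinates.
#' @param radius Ring radius in pixels.
#' @param width Radial width of the annulus in pixels (>= 0); spots are
#'   placed at radii `radius +/- width/2`, matching the finite width of a
#'   real Debye-Scherrer ring. Default 0 (exact circle).
#' @return A `sim_ring` list.
#' @export
sim_ring <- function(center, radius, width = 0) {
  if (length(center) != 2L || !all(is.finite(center)))
    stop_parameter("center must be c(row, col)")
  if (!is_scalar_num(radius) || radius <= 0) stop_parameter("radius must be > 0")
  if (!is_scalar_num(width) || width < 0) stop_parameter("width must be >= 0")
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 width = as.numeric(width)),
            class = "sim_ring")
}

# Rejection-sample spot centers on the annulus, >= min_sep pixels apart
# (Chebyshev distance, so psf footprints never overlap) and with the full
# footprint inside the detector.
place_spots <- function(n_spots, ring, shape, psf_size, max_tries = 20000L) {
  if (n_spots == 0L) return(data.frame(row = integer(), col = integer()))
  half <- (psf_size - 1L) %/% 2L
  rows <- integer(0); cols <- integer(0)
  tries <- 0L
  while (length(rows) < n_spots && tries < max_tries) {
    tries <- tries + 1L
    a <- stats::runif(1, 0, 2 * pi)
    w <- if (is.null(ring$width)) 0 else ring$width
    rho <- ring$radius + stats::runif(1, -w / 2, w / 2)
    r <- round(ring$center[1] + rho * sin(a))
    c <- round(ring$center[2] + rho * cos(a))
    if (r - half < 0 || c - half < 0 ||
        r + half > shape[1] - 1L || c + half > shape[2] - 1L) next
    if (length(rows) > 0 &&
        any(pmax(abs(rows - r), abs(cols - c)) < psf_size)) next
    rows <- c(rows, r); cols <- c(cols, c)
  }
  if (length(rows) < n_spots)
    stop_parameter(
      "could not place %d non-overlapping spots on the ring (placed %d)",
      n_spots, length(rows))
  data.frame(row = as.integer(rows), col = as.integer(cols))
}

#' Render a blinking diffraction movie from spot state trajectories
#'
#' Per frame, the expected count at each pixel is `background`, plus
#' `on_intensity / psf_size^2` at every footprint pixel of each "on" spot,
#' plus `drift_slope * frame_index` (0-based) at spot-footprint pixels.
#' Realized counts are independent Poisson draws with that expectation.
#'
#' @param states Integer 0/1 matrix (spots x frames) from a `simulate_*`
#'   function, or `NULL` to simulate according to `config$mode`.
#' @param ring A [sim_ring()] giving the annulus on which spots sit.
#' @param config A [sim_config()].
#' @return A list with `stack` (a [frame_stack()]), `truth` (data frame of
#'   spot positions and the generating rates) and `spots` (positions only).
#' @export
render_movie <- function(states = NULL, ring, config) {
  stopifnot(inherits(config, "sim_config"), inherits(ring, "sim_ring"))
  seed <- config$seed
  with_seed(if (is.null(seed)) NULL else sub_seed(seed, "render"), {
    if (is.null(states) && config$n_spots > 0L) {
      states <- switch(config$mode,
        telegraph = simulate_telegraph_states(
          config$k_on, config$k_off, config$n_frames, config$frame_interval,
          config$n_spots),
        angular_diffusion = simulate_angular_diffusion_states(
          config$angular$diffusion, config$angular$halfwidth, config$n_frames,
          config$frame_interval, config$n_spots, range = config$angular$range))
    }
    n_spots <- if (is.null(states)) 0L else nrow(states)
    if (n_spots != config$n_spots)
      stop_parameter("states has %d rows but config$n_spots = %d",
                     n_spots, config$n_spots)
    shape <- config$shape
    spots <- place_spots(config$n_spots, ring, shape, config$psf_size)
    half <- (config$psf_size - 1L) %/% 2L
    per_px <- config$on_intensity / config$psf_size^2
    n_frames <- config$n_frames

    # linear index sets of each spot's footprint (1-based, column-major)
    foot <- vector("list", n_spots)
    if (n_spots > 0L) {
      offs <- expand.grid(dr = -half:half, dc = -half:half)
      for (k in seq_len(n_spots)) {
        rr <- spots$row[k] + offs$dr + 1L
        cc <- spots$col[k] + offs$dc + 1L
        foot[[k]] <- rr + (cc - 1L) * shape[1]
      }
    }
    all_foot <- unique(unlist(foot))

    counts <- array(0L, dim = c(shape[1], shape[2], n_frames))
    base <- matrix(config$background, shape[1], shape[2])
    for (f in seq_len(n_frames)) {
      lam <- base
      if (length(all_foot) && config$drift_slope != 0)
        lam[all_foot] <- lam[all_foot] + config$drift_slope * (f - 1L)
      if (n_spots > 0L) {
        on <- which(states[, f] == 1L)
        for (k in on) lam[foot[[k]]] <- lam[foot[[k]]] + per_px
      }
      counts[, , f] <- stats::rpois(length(lam), lam)
    }
    truth <- cbind(spots,
                   data.frame(spot = seq_len(max(n_spots, 0L)),
                              mode = rep(config$mode, n_spots),
                              k_on = rep(config$k_on, n_spots),
                              k_off = rep(config$k_off, n_spots))[,
                     c("spot", "mode", "k_on", "k_off"), drop = FALSE])
    list(
      stack = frame_stack(counts, frame_interval = config$frame_interval,
                          exposure = config$exposure),
      truth = truth, spots = spots)
  })
}
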