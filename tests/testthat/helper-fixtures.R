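# Shared fixtures: small synthetic movies and ACF curves built in code.

# An acf_curve from the three-parameter exponential model.
model_acf_curve <- function(A, gamma, y, dt = 0.05, t_max = 25,
                            direction = c("decay", "growth"), noise_sd = 0) {
  direction <- match.arg(direction)
  lags <- seq(dt, t_max, by = dt)
  v <- if (direction == "decay") A * exp(-gamma * lags) + y else
    y + A * (1 - exp(-gamma * lags))
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), sd = noise_sd)
  structure(list(lags = lags, values = v, n_frames_used = length(lags) * 4L),
            class = "acf_curve")
}

# A tiny blinking movie with known kinetics: one ring of spots on a small
# detector. Returns the render_movie() result.
tiny_movie <- function(rate_sum = 0.6, n_spots = 12L, n_frames = 400L,
                       seed = 7L, background = 2, on_intensity = 45,
                       shape = c(64L, 64L), radius = 22, width = 4,
                       drift_slope = 0) {
  cfg <- sim_config(n_spots = n_spots, k_on = rate_sum / 2,
                    k_off = rate_sum / 2, on_intensity = on_intensity,
                    background = background, n_frames = n_frames,
                    drift_slope = drift_slope, seed = seed, shape = shape)
  ring <- sim_ring(center = (shape - 1) / 2, radius = radius, width = width)
  states <- if (n_spots > 0L)
    simulate_telegraph_states(cfg$k_on, cfg$k_off, n_frames,
                              cfg$frame_interval, n_spots, seed = seed + 1L)
  render_movie(states, ring, cfg)
}
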