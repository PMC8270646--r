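# Run orchestration: configuration handling and the simulate -> analyze ->
# compare entry points behind the command-line front end (inst/cli/dxb.R).
# Every run writes its fully-resolved configuration and seed next to its
# outputs, so re-running a run directory reproduces it bit-identically.

default_run_config <- function() {
  list(
    seed = 1L,
    geometry = list(wavelength = 1.54, distance = 60, pixel_pitch = 172,
                    beam_center = NULL),
    timing = list(frame_interval = 0.05, exposure = 0.042),
    analysis = list(bin_size = 1L, roi = NULL, max_lag_fraction = 0.25,
                    detrend_policy = "auto", residual_rule = "sum",
                    min_pixels = 20L),
    physics = list(phi_theta = NULL, motion_class = "rotational-diffusion"),
    simulation = NULL
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a run configuration
#'
#' YAML with blocks `geometry` (wavelength Angstrom, distance mm,
#' pixel_pitch um, beam_center 0-based `[row, col]`), `timing`
#' (frame_interval, exposure; seconds), `analysis` (bin_size, roi
#' {two_theta_center, two_theta_halfwidth}, max_lag_fraction,
#' detrend_policy, residual_rule, min_pixels), `physics` (phi_theta pm,
#' motion_class), `simulation` (the [sim_config()] fields plus optional
#' `ring: {radius}`), and a top-level `seed`. Missing fields take
#' documented defaults.
#'
#' @param path YAML file path, or a list already in config form.
#' @return Resolved configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop_config("config file does not exist: %s", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) path else
    stop_config("config must be a YAML path or a list")
  cfg <- merge_config(default_run_config(), cfg)
  tm <- cfg$timing
  if (!is_scalar_num(tm$frame_interval) || tm$frame_interval <= 0)
    stop_config("timing$frame_interval must be > 0")
  if (!is.null(cfg$analysis$bin_size) &&
      !(cfg$analysis$bin_size %in% c(1, 2, 3)))
    stop_config("analysis$bin_size must be 1, 2 or 3")
  cfg
}

run_geometry <- function(cfg, shape = NULL) {
  g <- cfg$geometry
  bc <- g$beam_center
  if (is.null(bc)) {
    if (is.null(shape)) stop_config("geometry$beam_center missing")
    bc <- (shape - 1) / 2
  }
  detector_geometry(g$wavelength, g$distance, g$pixel_pitch, bc)
}

sim_ring_from_config <- function(cfg, shape) {
  rad <- cfg$simulation$ring$radius
  if (is.null(rad)) {
    if (is.null(cfg$analysis$roi))
      stop_config("simulation needs ring$radius or an analysis roi")
    geom <- run_geometry(cfg, shape)
    rad <- geom$distance *
      tan(cfg$analysis$roi$two_theta_center * pi / 180) /
      (geom$pixel_pitch / 1000)
  }
  bc <- cfg$geometry$beam_center
  if (is.null(bc)) bc <- (shape - 1) / 2
  w <- cfg$simulation$ring$width
  sim_ring(center = bc, radius = rad, width = if (is.null(w)) 0 else w)
}

#' Simulate a blinking movie run
#'
#' Renders a synthetic movie per the configuration's `simulation` block and
#' writes `movie.tif` (multi-frame 16-bit TIFF), `mask.tif`, `truth.csv`
#' (spot positions and generating rates), and `config_resolved.yaml` to the
#' output directory. Repeating a run with the same seed gives byte-identical
#' outputs.
#'
#' @param config Path to a YAML config or a config list.
#' @param out_dir Output directory.
#' @return Invisible list with the rendered `stack`, `truth` and paths.
#' @export
dxb_simulate <- function(config, out_dir) {
  cfg <- read_run_config(config)
  sb <- cfg$simulation
  if (is.null(sb)) stop_config("configuration has no 'simulation' block")
  shape <- if (is.null(sb$shape)) c(192L, 192L) else as.integer(unlist(sb$shape))
  sc <- sim_config(
    n_spots = sb$n_spots, k_on = sb$k_on, k_off = sb$k_off,
    on_intensity = sb$on_intensity, background = sb$background,
    psf_size = if (is.null(sb$psf_size)) 3L else sb$psf_size,
    n_frames = if (is.null(sb$n_frames)) 2000L else sb$n_frames,
    frame_interval = cfg$timing$frame_interval,
    exposure = cfg$timing$exposure,
    drift_slope = if (is.null(sb$drift_slope)) 0 else sb$drift_slope,
    seed = cfg$seed,
    mode = if (is.null(sb$mode)) "telegraph" else sb$mode,
    angular = sb$angular, shape = shape)
  ring <- sim_ring_from_config(cfg, shape)
  states <- if (sc$n_spots > 0L) {
    sd <- sub_seed(cfg$seed, "states")
    switch(sc$mode,
      telegraph = simulate_telegraph_states(
        sc$k_on, sc$k_off, sc$n_frames, sc$frame_interval, sc$n_spots, sd),
      angular_diffusion = simulate_angular_diffusion_states(
        sc$angular$diffusion, sc$angular$halfwidth, sc$n_frames,
        sc$frame_interval, sc$n_spots, sd, range = sc$angular$range))
  } else NULL
  mv <- render_movie(states, ring, sc)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(movie = file.path(out_dir, "movie.tif"),
                mask = file.path(out_dir, "mask.tif"),
                truth = file.path(out_dir, "truth.csv"),
                config = file.path(out_dir, "config_resolved.yaml"))
  write_stack(mv$stack, paths$movie)
  write_mask(mv$stack$mask, paths$mask)
  utils::write.csv(mv$truth, paths$truth, row.names = FALSE)
  cfg$simulation$shape <- shape
  cfg$simulation$ring <- list(radius = ring$radius)
  yaml::write_yaml(cfg, paths$config)
  invisible(c(mv, list(paths = paths, config = cfg)))
}

#' Analyze a diffraction movie run
#'
#' The full pipeline: read stack and mask, bin, select the ring ROI,
#' detrend, compute per-pixel ACFs, fit with acceptance criteria, summarize
#' the accepted decay constants, and convert the median into a rotational
#' diffusion coefficient when `physics$phi_theta` is configured. Writes
#' `pixels.csv` and `ensemble.json` via [write_results()].
#'
#' @param config Path to a YAML config or a config list.
#' @param stack_path Movie path (multi-frame TIFF or frame directory), or a
#'   [frame_stack()] directly.
#' @param out_dir Output directory.
#' @param mask_path Optional mask image path.
#' @param verbose Log stage pixel counts (default TRUE).
#' @return Invisible list with `pixel_table`, `summary`, and output paths.
#' @export
dxb_analyze <- function(config, stack_path, out_dir, mask_path = NULL,
                        verbose = TRUE) {
  cfg <- read_run_config(config)
  an <- cfg$analysis
  stack <- if (inherits(stack_path, "frame_stack")) stack_path else
    read_stack(stack_path, cfg$timing$frame_interval, cfg$timing$exposure,
               mask = mask_path)
  shape <- dim(stack$counts)[1:2]
  b <- as.integer(an$bin_size)
  binned <- bin_pixels(stack, b)
  pixels <- NULL
  if (!is.null(an$roi)) {
    geom <- run_geometry(cfg, shape)
    roi <- ring_roi(an$roi$two_theta_center, an$roi$two_theta_halfwidth)
    pixels <- select_ring_pixels(geom, roi, binned$mask, b)
    if (verbose)
      message(sprintf("ring ROI: %d of %d binned pixels selected",
                      nrow(pixels), sum(binned$mask)))
  }
  tab <- analyze_stack(binned, pixels = pixels, bin_size = b,
                       max_lag_fraction = an$max_lag_fraction,
                       residual_rule = an$residual_rule,
                       detrend = an$detrend_policy, verbose = verbose)
  summary <- list(condition = cfg$condition, bin_size = b,
                  n_pixels_analyzed = nrow(tab))
  if (any(tab$accepted)) {
    sm <- summarize_gammas(tab)
    summary <- c(summary, sm)
    summary$gammas <- decay_ensemble(tab)$gammas
    if (!is.null(cfg$physics$phi_theta) && !is.null(an$roi)) {
      dyn <- dynamics_result(an$roi$two_theta_center, cfg$geometry$wavelength,
                             sm$median, cfg$physics$phi_theta,
                             cfg$physics$motion_class)
      summary$two_theta <- dyn$two_theta
      summary$d_space <- dyn$d_space
      summary$phi_theta <- dyn$phi_theta
      summary$d_r <- dyn$d_r
      summary$motion_class <- dyn$motion_class
    }
  } else {
    summary$n_accepted <- 0L
    summary$n_rejected <- nrow(tab)
    summary$gammas <- numeric(0)
    warning("no pixel passed the acceptance criteria", call. = FALSE)
  }
  paths <- write_results(tab, summary, out_dir)
  yaml::write_yaml(cfg, file.path(out_dir, "config_resolved.yaml"))
  invisible(list(pixel_table = tab, summary = summary, paths = paths))
}

#' Compare decay-constant ensembles across conditions
#'
#' Pairwise two-sided Wilcoxon rank-sum tests on the accepted decay
#' constants of two or more analyzed runs, with medians. Raw pairwise
#' p-values are reported by default; `holm = TRUE` adds Holm-adjusted ones.
#'
#' @param ensembles Character vector of `ensemble.json` paths (>= 2), or a
#'   list of [decay_ensemble()]s / gamma vectors.
#' @param out Optional path for a TSV report.
#' @param holm Add Holm-corrected p-values?
#' @return Data frame with one row per pair: `a`, `b`, `median_a`,
#'   `median_b`, `statistic`, `p_value` (and `p_holm` if requested).
#' @export
dxb_compare <- function(ensembles, out = NULL, holm = FALSE) {
  if (length(ensembles) < 2L)
    stop_parameter("need at least 2 ensembles to compare")
  if (is.character(ensembles)) {
    names <- basename(dirname(ensembles))
    gam <- lapply(ensembles, function(p) {
      e <- read_ensemble(p)
      as.numeric(e$gammas)
    })
  } else {
    names <- if (!is.null(names(ensembles))) names(ensembles) else
      paste0("ensemble", seq_along(ensembles))
    gam <- lapply(ensembles, as_gammas)
  }
  pairs <- utils::combn(length(gam), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    rt <- rank_sum_test(gam[[a]], gam[[b]])
    data.frame(a = names[a], b = names[b],
               median_a = stats::median(gam[[a]]),
               median_b = stats::median(gam[[b]]),
               statistic = rt$statistic, p_value = rt$p_value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (holm) tab$p_holm <- stats::p.adjust(tab$p_value, "holm")
  if (!is.null(out))
    utils::write.table(tab, out, sep = "\t", row.names = FALSE, quote = FALSE)
  tab
}
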