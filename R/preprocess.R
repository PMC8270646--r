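# Preprocessing ahead of the correlation analysis: pixel binning, ring-ROI
# selection on the flat detector, linear detrending, frame splitting.

#' Detector geometry
#'
#' @param wavelength X-ray wavelength in Angstrom.
#' @param distance Sample-to-detector distance in mm.
#' @param pixel_pitch Pixel pitch in micrometres.
#' @param beam_center `c(row, col)` beam center in 0-based pixel coordinates.
#' @return A `detector_geometry` list.
#' @export
detector_geometry <- function(wavelength, distance, pixel_pitch, beam_center) {
  if (!is_scalar_num(wavelength) || wavelength <= 0)
    stop_parameter("wavelength must be > 0")
  if (!is_scalar_num(distance) || distance <= 0)
    stop_parameter("distance must be > 0")
  if (!is_scalar_num(pixel_pitch) || pixel_pitch <= 0)
    stop_parameter("pixel_pitch must be > 0")
  if (length(beam_center) != 2L || !all(is.finite(beam_center)))
    stop_parameter("beam_center must be c(row, col)")
  structure(list(wavelength = wavelength, distance = distance,
                 pixel_pitch = pixel_pitch,
                 beam_center = as.numeric(beam_center)),
            class = "detector_geometry")
}

#' Ring region of interest on the Debye-Scherrer ring
#'
#' @param two_theta_center Scattering angle 2-theta at the ring center,
#'   degrees, in (0, 90).
#' @param two_theta_halfwidth Annulus half-width in degrees (> 0).
#' @return A `ring_roi` list.
#' @export
ring_roi <- function(two_theta_center, two_theta_halfwidth) {
  if (!is_scalar_num(two_theta_center) ||
      two_theta_center <= 0 || two_theta_center >= 90)
    stop_parameter("two_theta_center must be in (0, 90) degrees")
  if (!is_scalar_num(two_theta_halfwidth) || two_theta_halfwidth <= 0)
    stop_parameter("two_theta_halfwidth must be > 0")
  structure(list(two_theta_center = two_theta_center,
                 two_theta_halfwidth = two_theta_halfwidth),
            class = "ring_roi")
}

#' Bin a stack into non-overlapping b x b pixel blocks
#'
#' Counts inside each block are summed per frame (diffraction intensity grows
#' in proportion to the number of pixels binned); trailing rows/columns that
#' do not fill a block are dropped, never padded. A binned pixel is valid
#' only if all `b^2` constituent pixels are valid.
#'
#' @param stack A [frame_stack()].
#' @param b Bin size, one of 1, 2, 3.
#' @return A binned [frame_stack()].
#' @export
bin_pixels <- function(stack, b) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!is_count(b) || !(b %in% c(1, 2, 3)))
    stop_parameter("bin size b must be 1, 2 or 3")
  b <- as.integer(b)
  if (b == 1L) return(stack)
  d <- dim(stack$counts)
  nr <- d[1] %/% b; nc <- d[2] %/% b
  if (nr < 1 || nc < 1) stop_parameter("stack too small for %d x %d binning", b, b)
  x <- stack$counts[seq_len(nr * b), seq_len(nc * b), , drop = FALSE]
  # sum over the two within-block dimensions
  dim(x) <- c(b, nr, b * nc * d[3])
  x <- colSums(x)                       # (nr, b * nc * frames)
  dim(x) <- c(nr, b, nc * d[3])
  x <- aperm(x, c(2, 1, 3))             # (b, nr, nc * frames)
  x <- colSums(x)
  dim(x) <- c(nr, nc, d[3])
  m <- stack$mask[seq_len(nr * b), seq_len(nc * b), drop = FALSE] * 1
  dim(m) <- c(b, nr * b * nc)
  m <- colSums(m); dim(m) <- c(nr, b, nc)
  m <- colSums(aperm(m, c(2, 1, 3))); dim(m) <- c(nr, nc)
  frame_stack(x, stack$frame_interval, stack$exposure, mask = m == b * b)
}

#' Select binned pixels on a Debye-Scherrer annulus
#'
#' Maps the ring ROI to detector radii with the flat-detector relation
#' `r = distance * tan(2 theta)` and returns the binned pixels whose center
#' falls inside the annulus and whose constituents are all valid. Static
#' per-pixel factors (polarization, solid angle) are not corrected: the
#' ACF normalization cancels them.
#'
#' @param geometry A [detector_geometry()].
#' @param roi A [ring_roi()].
#' @param mask Logical validity matrix of the *binned* grid (from the binned
#'   stack), or `NULL` for all-valid.
#' @param bin_size Bin size used to form the grid (1, 2 or 3).
#' @param shape Original detector `c(rows, cols)`; required when `mask` is
#'   `NULL`.
#' @return Data frame with 0-based binned coordinates `row`, `col` and the
#'   center radius `radius_px` in original-pixel units. Warns (and returns
#'   zero rows) when the ROI misses the detector.
#' @export
select_ring_pixels <- function(geometry, roi, mask = NULL, bin_size = 1L,
                               shape = NULL) {
  stopifnot(inherits(geometry, "detector_geometry"), inherits(roi, "ring_roi"))
  b <- as.integer(bin_size)
  if (is.null(mask)) {
    if (is.null(shape)) stop_parameter("need mask or shape")
    mask <- matrix(TRUE, shape[1] %/% b, shape[2] %/% b)
  }
  nr <- nrow(mask); nc <- ncol(mask)
  pitch_mm <- geometry$pixel_pitch / 1000
  lo <- max(roi$two_theta_center - roi$two_theta_halfwidth, 1e-9)
  hi <- min(roi$two_theta_center + roi$two_theta_halfwidth, 90 - 1e-9)
  r_lo <- geometry$distance * tan(lo * pi / 180) / pitch_mm
  r_hi <- geometry$distance * tan(hi * pi / 180) / pitch_mm
  # binned pixel (i, j), 0-based, covers original rows [b*i, b*i + b); its
  # center in original 0-based pixel units is b*i + (b - 1) / 2
  rc <- (seq_len(nr) - 1) * b + (b - 1) / 2
  cc <- (seq_len(nc) - 1) * b + (b - 1) / 2
  rad <- sqrt(outer((rc - geometry$beam_center[1])^2,
                    (cc - geometry$beam_center[2])^2, `+`))
  sel <- rad >= r_lo & rad <= r_hi & mask
  idx <- which(sel, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    warning("ring ROI selects no pixels on the detector", call. = FALSE)
  data.frame(row = idx[, 1] - 1L, col = idx[, 2] - 1L,
             radius_px = rad[idx])
}

#' One pixel's intensity time series
#'
#' @param intensities Numeric count series (length >= 2, finite).
#' @param row,col 0-based coordinates on the (binned) grid.
#' @param bin_size Bin size of the grid the trace came from.
#' @param frame_interval Frame interval in seconds.
#' @param detrended Has a linear trend been removed?
#' @return A `pixel_trace` object.
#' @export
pixel_trace <- function(intensities, row = NA_integer_, col = NA_integer_,
                        bin_size = 1L, frame_interval = 0.05,
                        detrended = FALSE) {
  if (length(intensities) < 2L || !all(is.finite(intensities)))
    stop_parameter("intensities must be a finite series of length >= 2")
  structure(list(intensities = as.numeric(intensities),
                 row = row, col = col, bin_size = as.integer(bin_size),
                 frame_interval = frame_interval, detrended = detrended),
            class = "pixel_trace")
}

#' Remove a long-term linear trend from a pixel trace
#'
#' Fits an ordinary least-squares line to intensity versus frame index,
#' subtracts it, and adds the original mean back, so the trace mean — and
#' with it the Eq.-style ACF normalization — is unchanged to machine
#' precision. Under `policy = "auto"` the trend is removed only when the
#' slope differs from zero at the 5% level; because blinking traces are
#' strongly autocorrelated, the slope test uses an AR(1)
#' effective-sample-size correction (a naive i.i.d. t test would flag the
#' majority of stationary blinking traces as trending). Under `"never"`
#' the trace passes through untouched.
#'
#' @param trace A [pixel_trace()].
#' @param policy `"always"`, `"auto"` or `"never"`.
#' @return The (possibly) detrended [pixel_trace()].
#' @export
detrend_trace <- function(trace, policy = c("auto", "always", "never")) {
  policy <- match.arg(policy)
  stopifnot(inherits(trace, "pixel_trace"))
  if (policy == "never") return(trace)
  y <- trace$intensities
  n <- length(y)
  if (n < 3L) stop_parameter("need >= 3 points to fit a trend")
  t <- seq_len(n) - 1
  tc <- t - mean(t)
  sxx <- sum(tc^2)
  slope <- sum(tc * y) / sxx
  if (policy == "auto") {
    res <- y - mean(y) - slope * tc
    s2 <- sum(res^2) / (n - 2)
    # AR(1) effective sample size: autocorrelated residuals make the
    # naive slope test fire on most stationary blinking traces
    rho <- if (s2 > 0)
      sum(res[-1] * res[-n]) / sum(res^2) else 0
    rho <- max(min(rho, 0.999), 0)
    n_eff <- max(n * (1 - rho) / (1 + rho), 3)
    se <- sqrt(s2 / sxx * (n / n_eff))
    p <- if (se == 0) as.numeric(slope != 0) else
      2 * stats::pt(-abs(slope / se), df = max(n_eff - 2, 1))
    if (is.na(p) || p >= 0.05) return(trace)
  }
  out <- trace
  out$intensities <- y - slope * tc   # subtract line, keep the mean
  out$detrended <- TRUE
  out
}

#' Split a stack into contiguous equal-length substacks
#'
#' Frames are divided into `k` contiguous, non-overlapping blocks of
#' `floor(n_frames / k)` frames; remainder frames at the tail are dropped.
#'
#' @param stack A [frame_stack()].
#' @param k Number of substacks (1 <= k <= n_frames).
#' @return List of `k` [frame_stack()] objects.
#' @export
split_frames <- function(stack, k) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- dim(stack$counts)[3]
  if (!is_count(k) || k < 1) stop_parameter("k must be a positive integer")
  if (k > n) stop_parameter("k = %d exceeds n_frames = %d", k, n)
  len <- n %/% k
  lapply(seq_len(k), function(i) {
    idx <- ((i - 1L) * len + 1L):(i * len)
    frame_stack(stack$counts[, , idx, drop = FALSE], stack$frame_interval,
                stack$exposure, stack$mask)
  })
}
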