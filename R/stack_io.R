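# Image-stack, mask, and results I/O.
#
# TIFF is the mandatory stack dialect (16-bit unsigned; photon-counting
# detector exports). Frame timing is never taken from TIFF tags, which are
# unreliable in practice: it always comes from the configuration.

#' Construct a frame stack
#'
#' The core container: a time-ordered series of 2-D count images with frame
#' timing and a per-pixel validity mask.
#'
#' @param counts 3-D non-negative integer array, `rows x cols x frames`.
#' @param frame_interval Frame interval in seconds (> 0).
#' @param exposure Exposure per frame in seconds (<= frame_interval).
#' @param mask Logical matrix `rows x cols`, `TRUE` = valid pixel; default
#'   all valid.
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(counts, frame_interval, exposure = frame_interval,
                        mask = NULL) {
  if (length(dim(counts)) != 3L)
    stop_format("counts must be a 3-D array (rows x cols x frames)")
  if (any(counts < 0)) stop_format("counts must be non-negative")
  if (!is_scalar_num(frame_interval) || frame_interval <= 0)
    stop_parameter("frame_interval must be > 0")
  if (!is_scalar_num(exposure) || exposure <= 0 || exposure > frame_interval)
    stop_parameter("exposure must satisfy 0 < exposure <= frame_interval")
  d <- dim(counts)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!is.logical(mask) || !identical(dim(mask), d[1:2]))
    stop_format("mask must be a logical matrix matching the frame shape")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, frame_interval = frame_interval,
                 exposure = exposure, mask = mask),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<frame_stack> %d frames of %d x %d pixels, dt = %g s (exposure %g s), %d masked px\n",
    d[3], d[1], d[2], x$frame_interval, x$exposure, sum(!x$mask)))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$counts)

read_tiff_frames <- function(path) {
  img <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(img)) img <- list(img)
  lapply(img, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1]  # tolerate grey stored with channels
    m
  })
}

#' Read an image stack from disk
#'
#' Accepts either a multi-frame TIFF or a directory of single-frame TIFFs
#' ordered lexicographically by file name. Sample values are widened to R
#' integers losslessly; frame timing comes from the arguments, never from
#' TIFF tags.
#'
#' @param path Multi-frame TIFF file or directory of per-frame TIFFs.
#' @param frame_interval,exposure Frame timing in seconds.
#' @param mask Optional logical mask or path readable by [read_mask()].
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, frame_interval, exposure = frame_interval,
                       mask = NULL) {
  if (!file.exists(path)) stop_format("stack path does not exist: %s", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) stop_format("no TIFF frames found in %s", path)
    frames <- unlist(lapply(files, read_tiff_frames), recursive = FALSE)
  } else {
    frames <- read_tiff_frames(path)
  }
  if (length(frames) == 0L) stop_format("zero frames in %s", path)
  d1 <- dim(frames[[1]])
  if (!all(vapply(frames, function(m) identical(dim(m), d1), logical(1))))
    stop_format("inconsistent frame shapes in %s", path)
  counts <- array(0L, dim = c(d1[1], d1[2], length(frames)))
  for (f in seq_along(frames)) counts[, , f] <- frames[[f]]
  if (is.character(mask)) mask <- read_mask(mask)
  frame_stack(counts, frame_interval, exposure, mask)
}

#' Write an image stack as a multi-frame 16-bit TIFF
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  if (max(stack$counts) > 65535L)
    stop_format("counts exceed the 16-bit TIFF range (max %d)", max(stack$counts))
  n <- dim(stack$counts)[3]
  pages <- lapply(seq_len(n), function(f) stack$counts[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a detector validity mask
#'
#' Zero-valued pixels mark invalid regions (e.g. detector module gaps);
#' anything non-zero is valid. TIFF and PNG are accepted.
#'
#' @param path Mask image path.
#' @return Logical matrix, `TRUE` = valid.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop_format("mask path does not exist: %s", path)
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path, as.is = TRUE)
  }
  if (length(dim(m)) == 3L) m <- m[, , 1]
  mask <- m != 0
  message(sprintf("mask: %d of %d pixels invalid", sum(!mask), length(mask)))
  mask
}

#' Write a mask as a TIFF image
#'
#' @param mask Logical matrix (`TRUE` = valid).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(ifelse(mask, 1, 0), path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

RESULTS_SCHEMA <- "dxblink/1"

#' Write per-pixel and ensemble analysis results
#'
#' Writes `pixels.csv` (one row per analyzed pixel: `row`, `col`,
#' `bin_size`, `direction`, `A`, `gamma`, `y`, `residual`, `accepted`,
#' `reason`; coordinates are 0-based `(row, col)`, row-major) and
#' `ensemble.json` (schema-versioned summary with the accepted decay
#' constants, median, Lorentz fit when feasible, and physics conversions).
#'
#' @param pixel_table Data frame from [analyze_stack()].
#' @param summary List from [summarize_gammas()] plus any physics fields.
#' @param out_dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_results <- function(pixel_table, summary, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "pixels.csv")
  js <- file.path(out_dir, "ensemble.json")
  cols <- c("row", "col", "bin_size", "direction", "A", "gamma", "y",
            "residual", "accepted", "reason")
  tab <- pixel_table[, intersect(cols, names(pixel_table)), drop = FALSE]
  con <- file(csv, "w")
  writeLines("# pixel coordinates are 0-based (row, col), row-major", con)
  utils::write.csv(tab, con, row.names = FALSE)
  close(con)
  summary$schema <- RESULTS_SCHEMA
  summary$pixel_table <- basename(csv)
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(list(pixels = csv, ensemble = js))
}

#' Read an ensemble summary JSON written by [write_results()]
#'
#' @param path Path to `ensemble.json`.
#' @return Parsed list; `$gammas` holds the accepted decay constants.
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path)) stop_format("ensemble file does not exist: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
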