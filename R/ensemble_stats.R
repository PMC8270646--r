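# Ensemble statistics over accepted per-pixel decay constants:
# Cauchy-Lorentz fitting (mode reporting), boxplot/median summaries,
# rank-sum comparison of conditions, and frame-splitting robustness.

#' Bundle accepted decay constants into an ensemble
#'
#' @param x Either a numeric vector of decay constants (s^-1) or the pixel
#'   table from [analyze_stack()] (accepted rows are extracted).
#' @param condition Free-text condition label (e.g. a temperature).
#' @param directions Optional per-value direction labels.
#' @param n_rejected Number of rejected pixels (filled automatically from a
#'   pixel table).
#' @return A `decay_ensemble` list.
#' @export
decay_ensemble <- function(x, condition = NA_character_, directions = NULL,
                           n_rejected = 0L) {
  if (is.data.frame(x)) {
    acc <- x[which(x$accepted), , drop = FALSE]
    n_rejected <- sum(!x$accepted, na.rm = TRUE)
    directions <- acc$direction
    x <- acc$gamma
  }
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x <= 0))
    stop_parameter("decay constants must be finite and > 0")
  structure(list(gammas = x, directions = directions, condition = condition,
                 n_rejected = as.integer(n_rejected)),
            class = "decay_ensemble")
}

as_gammas <- function(x) {
  if (inherits(x, "decay_ensemble")) x$gammas
  else if (is.data.frame(x)) decay_ensemble(x)$gammas
  else as.numeric(x)
}

#' Fit a Cauchy-Lorentz distribution to a decay-constant ensemble
#'
#' `"mle"` maximizes the Cauchy likelihood on the raw values (via
#' [MASS::fitdistr()]); `"histogram"` least-squares fits an
#' amplitude-scaled Lorentzian `a / ((x - x0)^2 + scale^2)` to histogram
#' densities with Freedman-Diaconis bins. The reported mode is the location
#' `x0` in either case.
#'
#' @param ensemble A [decay_ensemble()], pixel table, or numeric vector.
#' @param method `"mle"` (>= 5 values) or `"histogram"` (>= 20 values).
#' @param bin_rule Histogram break rule (default `"FD"`).
#' @return A `lorentz_fit` list: `x0` (mode, s^-1), `scale` (s^-1),
#'   `method`, and `bin_width` for the histogram method.
#' @export
fit_lorentzian <- function(ensemble, method = c("mle", "histogram"),
                           bin_rule = "FD") {
  method <- match.arg(method)
  g <- as_gammas(ensemble)
  n_min <- if (method == "mle") 5L else 20L
  if (length(g) < n_min)
    stop_insufficient("Lorentz %s fit needs >= %d values (got %d)",
                      method, n_min, length(g))
  if (method == "mle") {
    fit <- suppressWarnings(MASS::fitdistr(g, "cauchy"))
    est <- fit$estimate
    return(structure(list(x0 = unname(est["location"]),
                          scale = unname(est["scale"]),
                          method = "mle", bin_width = NA_real_),
                     class = "lorentz_fit"))
  }
  h <- graphics::hist(g, breaks = bin_rule, plot = FALSE)
  xm <- h$mids
  dens <- h$density
  x0_0 <- stats::median(g)
  sc_0 <- max(stats::IQR(g) / 2, 1e-6)
  obj <- function(p) {
    x0 <- p[1]; sc <- exp(p[2]); a <- exp(p[3])
    sum((a / ((xm - x0)^2 + sc^2) - dens)^2)
  }
  a_0 <- max(dens) * sc_0^2
  opt <- stats::optim(c(x0_0, log(sc_0), log(max(a_0, 1e-12))), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  structure(list(x0 = opt$par[1], scale = exp(opt$par[2]),
                 method = "histogram",
                 bin_width = diff(h$breaks[1:2])),
            class = "lorentz_fit")
}

#' @export
print.lorentz_fit <- function(x, ...) {
  cat(sprintf("<lorentz_fit> mode x0 = %.4g s^-1, scale = %.4g s^-1 (%s)\n",
              x$x0, x$scale, x$method))
  invisible(x)
}

#' Summarize a decay-constant ensemble
#'
#' Reports the median (the statistic entering the rotational diffusion
#' coefficient), quartiles, a boxplot five-number summary (1.5 IQR
#' whiskers), counts, and — when at least 20 values are available — the
#' Cauchy-Lorentz mode. Below 20 values the Lorentz fit is skipped and only
#' boxplot statistics are reported.
#'
#' @param ensemble A [decay_ensemble()], pixel table, or numeric vector.
#' @param lorentz_method Passed to [fit_lorentzian()] when feasible.
#' @return List with `median`, `q1`, `q3`, `iqr`, `boxplot` (lower whisker,
#'   q1, median, q3, upper whisker), `n_accepted`, `n_rejected`,
#'   `lorentz_mode`, `lorentz_scale` (NA when not fitted).
#' @export
summarize_gammas <- function(ensemble, lorentz_method = "mle") {
  g <- as_gammas(ensemble)
  if (length(g) == 0L) stop_insufficient("empty ensemble: nothing to summarize")
  n_rej <- if (inherits(ensemble, "decay_ensemble")) ensemble$n_rejected
    else if (is.data.frame(ensemble)) sum(!ensemble$accepted, na.rm = TRUE)
    else 0L
  q <- unname(stats::quantile(g, c(0.25, 0.5, 0.75)))
  iqr <- q[3] - q[1]
  lo_w <- min(g[g >= q[1] - 1.5 * iqr])
  hi_w <- max(g[g <= q[3] + 1.5 * iqr])
  lz <- if (length(g) >= 20L)
    tryCatch(fit_lorentzian(g, lorentz_method), error = function(e) NULL)
  else NULL
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       boxplot = c(lower = lo_w, q1 = q[1], median = q[2], q3 = q[3],
                   upper = hi_w),
       n_accepted = length(g), n_rejected = as.integer(n_rej),
       lorentz_mode = if (is.null(lz)) NA_real_ else lz$x0,
       lorentz_scale = if (is.null(lz)) NA_real_ else lz$scale)
}

#' Wilcoxon rank-sum comparison of two ensembles
#'
#' Two-sided two-sample rank-sum test: exact enumeration when both samples
#' have at most 20 values and no ties, otherwise the normal approximation
#' with tie correction (no continuity correction, so identical samples give
#' p = 1 exactly).
#'
#' @param a,b [decay_ensemble()]s, pixel tables, or numeric vectors.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` (default) chooses automatically as described above.
#' @return List with `statistic` (Mann-Whitney W for the first sample),
#'   `p_value`, and `method`.
#' @export
rank_sum_test <- function(a, b, exact = NULL) {
  x <- as_gammas(a); y <- as_gammas(b)
  if (length(x) == 0L || length(y) == 0L)
    stop_insufficient("rank-sum test needs non-empty ensembles")
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact))
    exact <- length(x) <= 20L && length(y) <= 20L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Frame-splitting robustness analysis
#'
#' Splits the stack into `k` contiguous substacks for each `k` in `k_list`,
#' reruns the full per-pixel analysis on every substack, and returns the
#' per-substack ensembles and summaries. Shorter substacks mean shorter
#' total observation time, so condition differences measured on them grow
#' ambiguous — the effect this function lets callers reproduce.
#'
#' @param stack A [frame_stack()] (already binned/masked as desired).
#' @param k_list Integer vector of split counts (1 = full stack).
#' @param pixels,... Passed to [analyze_stack()].
#' @return Named list (one element per `k`, names `"k<k>"`), each a list of
#'   per-substack entries with `table` (pixel table), `summary`
#'   ([summarize_gammas()] or `NULL` when no pixel was accepted), and
#'   `n_frames`.
#' @export
frame_robustness <- function(stack, k_list, pixels = NULL, ...) {
  stopifnot(inherits(stack, "frame_stack"))
  out <- list()
  for (k in k_list) {
    subs <- split_frames(stack, k)
    out[[paste0("k", k)]] <- lapply(subs, function(s) {
      tab <- analyze_stack(s, pixels = pixels, ...)
      sm <- if (any(tab$accepted)) summarize_gammas(tab) else NULL
      list(table = tab, summary = sm, n_frames = dim(s$counts)[3])
    })
  }
  out
}
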