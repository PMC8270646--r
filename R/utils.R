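# Classed error helpers and seed plumbing shared across modules.

dxb_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "dxb_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_parameter <- function(msg, ...) dxb_stop("dxb_parameter_error", msg, ...)
stop_format <- function(msg, ...) dxb_stop("dxb_format_error", msg, ...)
stop_config <- function(msg, ...) dxb_stop("dxb_config_error", msg, ...)
stop_insufficient <- function(msg, ...) dxb_stop("dxb_insufficient_data_error", msg, ...)
stop_normalization <- function(msg, ...) dxb_stop("dxb_normalization_error", msg, ...)

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded simulation helpers do not
#' disturb the caller's RNG stream. With `seed = NULL` the expression runs
#' on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-purpose substream: every stochastic stage of a run pulls
# its own seed from the single top-level seed, so stages are independently
# reproducible. Kept below 2^31 - 1.
sub_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) + h * 1009L) %% 2147483629L
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
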