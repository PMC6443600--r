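#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef fivenum kruskal.test median pnorm qnorm quantile
#'   rbinom rexp rlnorm rnorm runif sd var setNames predict
#' @importFrom utils write.csv read.csv head
NULL

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`%s` must be a single finite number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_invalid("`%s` = %g is outside its admissible range", name, x)
  invisible(x)
}

#' Derive per-stage seeds from one master seed
#'
#' One global seed fans out to independent per-stage seeds so that
#' each pipeline stage is rerunnable in isolation.  The mapping is a fixed
#' affine hash modulo a large prime below `2^31`, so derived seeds remain
#' valid R integer seeds.
#'
#' @param seed master integer seed.
#' @param stage stage name (character) or index.
#' @return an integer seed.
#' @export
split_seed <- function(seed, stage) {
  check_number(seed, "seed")
  key <- if (is.character(stage)) sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) else as.numeric(stage)
  as.integer((abs(seed) * 48271 + key * 16807) %% 2147483563)
}

## Shannon entropy (base 2) of a histogram of counts
shannon_entropy <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

## weighted helpers used by reclassification metrics
wmean <- function(x, w) sum(x * w) / sum(w)
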