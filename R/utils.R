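# Internal helpers: seed plumbing, weighted quantiles, input checks.

#' @importFrom rlang abort warn .data
#' @importFrom stats rexp rpois runif dpois quantile median pf setNames
NULL

# Derive a reproducible child seed from a master seed and a stream label, so
# that every stochastic stage of a pipeline run consumes its own stream.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * (31L^(seq_along(utf8ToInt(as.character(stream))) %% 7L)))
  as.integer((abs(seed) * 48271 + h) %% 2147483399) + 1L
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's RNG
# state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Weighted quantiles with the inclusive (Hazen) plotting position
#'
#' Computes quantiles of a weighted sample using plotting positions
#' \eqn{p_i = (c_i - w_i/2) / W} where \eqn{c_i} is the cumulative weight up to
#' and including observation \eqn{i} (after sorting) and \eqn{W} the total
#' weight, with linear interpolation between positions. With equal weights this
#' reproduces `stats::quantile(type = 5)`, so weighted and unweighted
#' summaries in this package agree bit-for-bit on uniform weights.
#'
#' @param x Numeric vector of observations.
#' @param probs Probabilities in `[0, 1]`.
#' @param weights Non-negative weights, recycled length of `x`; `NULL` for
#'   equal weights.
#' @return Numeric vector of quantiles, one per element of `probs`.
#' @export
#' @examples
#' weighted_quantile(1:10, c(0.025, 0.5, 0.975))
weighted_quantile <- function(x, probs = c(0.025, 0.5, 0.975), weights = NULL) {
  stopifnot(is.numeric(x), length(x) >= 1L, all(probs >= 0 & probs <= 1))
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(weights) != length(x)) abort("`weights` must match `x` in length.")
  if (any(!is.finite(weights)) || any(weights < 0)) {
    abort("`weights` must be finite and non-negative.")
  }
  if (sum(weights) <= 0) abort("All weights are zero.")
  keep <- weights > 0
  x <- x[keep]; w <- weights[keep]
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w)
  pp <- (cw - w / 2) / cw[length(cw)]
  vapply(probs, function(p) {
    if (p <= pp[1]) return(x[1])
    if (p >= pp[length(pp)]) return(x[length(x)])
    stats::approx(pp, x, xout = p, ties = "ordered")$y
  }, numeric(1))
}

# Standard three-number summary used across posterior-like objects.
summaries_hazen <- function(x, weights = NULL) {
  q <- weighted_quantile(x, c(0.025, 0.5, 0.975), weights)
  tibble::tibble(median = q[2], q2.5 = q[1], q97.5 = q[3])
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s.", name, min))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s.", name, min))
  }
  as.numeric(x)
}
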