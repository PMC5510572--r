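# One-phase decay fits for cycloheximide-chase protein levels and the extra
# sum-of-squares F test comparing degradation constants between constructs.

validate_decay_curve <- function(curve) {
  curve <- tibble::as_tibble(curve)
  if (!all(c("time_h", "level_pct") %in% names(curve))) {
    abort("A decay curve needs columns `time_h` and `level_pct`.")
  }
  if (any(curve$time_h < 0)) abort("Times must be >= 0.")
  if (length(unique(curve$time_h)) < 3L) abort("Need at least 3 distinct times.")
  if (!any(curve$time_h == 0)) abort("The time course must include t = 0.")
  curve
}

#' Fit a one-phase exponential decay
#'
#' Least-squares fit of `level(t) = (100 - plateau) * exp(-K * t) + plateau`
#' to a pooled time course of normalized protein levels (percent of the
#' level at time 0). Replicates are pooled, not averaged, so residual
#' degrees of freedom reflect every measured point. The plateau is a free
#' parameter bounded to `[0, 100]`. Initialization is deterministic:
#' `plateau0` is the smallest observed level (clamped to the bounds) and
#' `K0` comes from a log-linear regression of the plateau-subtracted levels,
#' so the fit is reproducible given the data.
#'
#' @param curve A data frame with columns `time_h` and `level_pct`
#'   (`replicate`/`construct` columns are carried along if present).
#' @return An object of class `decay_fit`: `K` (per hour), `plateau` (%),
#'   `sse`, `df` (residual degrees of freedom), `n`, `fitted` (function of
#'   time), `data`, and `construct`.
#' @export
#' @examples
#' curve <- simulate_decay_curve(K = 0.3, noise_sd = 0, n_replicates = 1)
#' fit_one_phase_decay(curve)
fit_one_phase_decay <- function(curve) {
  curve <- validate_decay_curve(curve)
  construct <- if ("construct" %in% names(curve)) {
    paste(unique(curve$construct), collapse = "+")
  } else NA_character_
  y <- curve$level_pct
  t <- curve$time_h
  n <- length(y)
  if (diff(range(y)) < 1e-12) {
    # Degenerate flat curve: no decay signal; K = 0 by convention.
    fit <- list(K = 0, plateau = y[1], sse = 0)
  } else {
    plateau0 <- min(max(min(y), 0), 100)
    shifted <- pmax(y - plateau0, 1e-6)
    k0 <- -stats::coef(stats::lm(log(shifted) ~ t))[["t"]]
    k0 <- min(max(k0, 1e-4), 100)
    m <- tryCatch(
      minpack.lm::nlsLM(
        level_pct ~ (100 - plateau) * exp(-K * time_h) + plateau,
        data = curve,
        start = list(K = k0, plateau = plateau0),
        lower = c(K = 0, plateau = 0), upper = c(K = Inf, plateau = 100),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) {
        abort(sprintf(
          "One-phase decay fit failed to converge (start K0 = %.4g, plateau0 = %.4g): %s",
          k0, plateau0, conditionMessage(e)))
      })
    cf <- stats::coef(m)
    fit <- list(K = unname(cf["K"]), plateau = unname(cf["plateau"]),
                sse = sum(stats::resid(m)^2))
  }
  K <- fit$K; plateau <- fit$plateau
  structure(list(K = K, plateau = plateau, sse = fit$sse,
                 df = n - 2L, n = n,
                 fitted = function(time) (100 - plateau) * exp(-K * time) + plateau,
                 data = curve, construct = construct),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit>%s K = %.4g /h, plateau = %.3g%%, SSE = %.4g (df %d)\n",
              if (is.na(x$construct)) "" else paste0(" [", x$construct, "]"),
              x$K, x$plateau, x$sse, x$df))
  invisible(x)
}

#' Parameter table for a decay fit
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("K", "plateau"), estimate = c(x$K, x$plateau))
}

#' One-row summary of a decay fit
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(K = x$K, plateau = x$plateau, half_life_h = log(2) / x$K,
                 sse = x$sse, df = x$df, n = x$n)
}

#' Compare degradation constants with the extra sum-of-squares F test
#'
#' Fits the two curves separately (one `K` and plateau each) and jointly
#' under a shared model (one `K` and plateau forced across both), and tests
#' the improvement:
#' `F = ((SSE_shared - SSE_separate) / (df_shared - df_separate)) /
#' (SSE_separate / df_separate)`, with the p-value from the F distribution.
#'
#' @param a,b Decay-curve data frames (see [fit_one_phase_decay()]).
#' @return A list of class `rate_comparison`: `F`, `df1`, `df2`, `p`,
#'   `shared_fit_sse`, `separate_fit_sse`, and the three fits.
#' @export
#' @examples
#' wt <- simulate_decay_curve(K = 0.06, construct = "WT", seed = 1)
#' mu <- simulate_decay_curve(K = 1.17, construct = "dup", seed = 2)
#' compare_decay_rates(wt, mu)
compare_decay_rates <- function(a, b) {
  a <- validate_decay_curve(a); b <- validate_decay_curve(b)
  fit_a <- fit_one_phase_decay(a)
  fit_b <- fit_one_phase_decay(b)
  pooled <- dplyr::bind_rows(
    dplyr::select(a, dplyr::any_of(c("time_h", "level_pct"))),
    dplyr::select(b, dplyr::any_of(c("time_h", "level_pct"))))
  fit_shared <- fit_one_phase_decay(pooled)
  n <- nrow(pooled)
  df_sep <- n - 4L
  df_shared <- n - 2L
  if (df_sep <= 0L) abort("Too few points for the separate-fit model.")
  sse_sep <- fit_a$sse + fit_b$sse
  sse_shared <- max(fit_shared$sse, sse_sep)  # nested models: shared >= separate
  Fstat <- ((sse_shared - sse_sep) / (df_shared - df_sep)) / (sse_sep / df_sep)
  p <- stats::pf(Fstat, df_shared - df_sep, df_sep, lower.tail = FALSE)
  structure(list(F = Fstat, df1 = df_shared - df_sep, df2 = df_sep, p = p,
                 shared_fit_sse = sse_shared, separate_fit_sse = sse_sep,
                 fit_a = fit_a, fit_b = fit_b, fit_shared = fit_shared),
            class = "rate_comparison")
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat(sprintf("<rate_comparison> F(%d, %d) = %.4g, p = %.4g\n  K: %.4g vs %.4g /h\n",
              x$df1, x$df2, x$F, x$p, x$fit_a$K, x$fit_b$K))
  invisible(x)
}

#' One-row summary of a rate comparison
#' @param x A `rate_comparison`.
#' @param ... Unused.
#' @export
glance.rate_comparison <- function(x, ...) {
  tibble::tibble(F = x$F, df1 = x$df1, df2 = x$df2, p = x$p,
                 K_a = x$fit_a$K, K_b = x$fit_b$K,
                 shared_fit_sse = x$shared_fit_sse,
                 separate_fit_sse = x$separate_fit_sse)
}
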