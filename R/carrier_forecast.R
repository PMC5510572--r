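# Forward branching-process forecast of the number of living carriers,
# conditioned on the observed minimum count, integrating tMRCA uncertainty.

#' Forward-simulation configuration
#'
#' Each carrier independently leaves a Poisson(`lambda`) number of carrier
#' offspring per generation, starting from the single founder. Trajectories
#' whose final-generation count falls below `min_carriers` are rejected,
#' mirroring the observed minimum number of unrelated carriers per
#' generation. Present-day totals assume `coexisting_generations` 25-year
#' generations alive at once.
#'
#' @param lambda Mean carrier offspring per carrier per generation. The
#'   default 1.02 -- mild long-run growth per 25-year generation -- is
#'   calibrated jointly with the dating defaults against the worked example
#'   (see the methods vignette).
#' @param min_carriers Rejection threshold on the final-generation count.
#' @param n_sims Number of *accepted* trajectories to collect.
#' @param coexisting_generations Generations assumed to co-exist at present.
#' @param seed Integer seed.
#' @return A list of class `forward_config`.
#' @export
forward_config <- function(lambda = 1.02, min_carriers = 9, n_sims = 1e4,
                           coexisting_generations = 3, seed = 1) {
  structure(list(lambda = check_number(lambda, "lambda", min = 0),
                 min_carriers = check_count(min_carriers, "min_carriers", min = 1),
                 n_sims = check_count(n_sims, "n_sims", min = 1),
                 coexisting_generations = check_count(coexisting_generations,
                                                     "coexisting_generations", min = 1),
                 seed = as.integer(seed)),
            class = "forward_config")
}

#' Simulate one carrier-count trajectory
#'
#' Starts from a single carrier at generation 0 and propagates
#' `N_{g+1} ~ Poisson(lambda * N_g)` (the sum of independent
#' Poisson(`lambda`) offspring across the `N_g` carriers).
#'
#' @param t Number of generations to simulate, `>= 0`.
#' @param cfg A [forward_config()] (supplies `lambda`).
#' @param seed Integer seed.
#' @return Integer vector of length `t + 1`: carrier counts at generations
#'   `0 ... t`.
#' @export
#' @examples
#' simulate_carriers(5, forward_config(lambda = 1.05), seed = 1)
simulate_carriers <- function(t, cfg = forward_config(), seed = 1) {
  t <- check_count(t, "t", min = 0)
  with_seed(seed, {
    traj <- integer(t + 1L)
    traj[1L] <- 1L
    if (t > 0) {
      for (g in seq_len(t)) {
        traj[g + 1L] <- rpois(1L, cfg$lambda * traj[g])
        if (traj[g + 1L] == 0L) {
          traj[(g + 1L):(t + 1L)] <- 0L
          break
        }
      }
    }
    traj
  })
}

#' Exact distribution of the carrier count after t generations
#'
#' Iterates the probability mass function of the Poisson branching process
#' started from one carrier: `P(N_{g+1} = m) = sum_j P(N_g = j) *
#' dpois(m, j * lambda)`, truncated at `max_n` (mass above the truncation is
#' effectively absorbing for the tail probabilities of interest).
#'
#' @param t Generations, `>= 0`.
#' @param lambda Offspring mean.
#' @param max_n Truncation point of the support.
#' @return Numeric vector `p` of length `max_n + 1`; `p[m + 1]` is
#'   `P(N_t = m)` for `m = 0 ... max_n` (tail mass above `max_n` is
#'   `1 - sum(p)`).
#' @export
carrier_count_pmf <- function(t, lambda, max_n = 600) {
  t <- check_count(t, "t", min = 0)
  max_n <- check_count(max_n, "max_n", min = 1)
  support <- 0:max_n
  p <- c(0, 1, rep(0, max_n - 1L))  # start from the single founder carrier
  if (t == 0) return(p)
  # Transition matrix: row j+1 = offspring pmf of a generation with j carriers.
  M <- outer(support, support, function(j, m) dpois(m, j * lambda))
  for (g in seq_len(t)) p <- as.vector(p %*% M)
  p
}

#' Probability that a founder of age t leaves at least k carriers
#'
#' Computes `P(N_t >= min_carriers)` for every `t = 1 ... t_max` in one pass
#' of the branching-process pmf iteration. Used as the default posterior
#' adjustment weight in [adjust_posterior()].
#'
#' @param t_max Largest age needed.
#' @param lambda Offspring mean.
#' @param min_carriers Threshold count.
#' @param max_n pmf truncation point.
#' @return Numeric vector of length `t_max`; element `t` is
#'   `P(N_t >= min_carriers)`.
#' @export
carrier_survival_prob <- function(t_max, lambda, min_carriers, max_n = 600) {
  t_max <- check_count(t_max, "t_max", min = 1)
  support <- 0:max_n
  M <- outer(support, support, function(j, m) dpois(m, j * lambda))
  p <- c(0, 1, rep(0, max_n - 1L))  # start from the single founder carrier
  out <- numeric(t_max)
  below <- seq_len(min_carriers)  # indices of counts 0 ... min_carriers - 1
  for (g in seq_len(t_max)) {
    p <- as.vector(p %*% M)
    out[g] <- 1 - sum(p[below])
  }
  out
}

#' Forecast the present-day number of carriers per generation
#'
#' Repeatedly samples a tMRCA from the (possibly adjusted) posterior, runs
#' the forward branching process for that many generations, rejects
#' trajectories ending with fewer than `min_carriers` carriers, and collects
#' accepted final-generation counts until `cfg$n_sims` have accumulated.
#'
#' @param posterior A `tmrca_posterior`.
#' @param cfg A [forward_config()].
#' @return An object of class `carrier_distribution` with elements `samples`
#'   (accepted final counts), `summaries` (median and 95% interval),
#'   `total_today` (the per-generation summaries scaled by
#'   `coexisting_generations`), and `config`.
#' @export
estimate_current_carriers <- function(posterior, cfg = forward_config()) {
  stopifnot(inherits(posterior, "tmrca_posterior"))
  if (length(posterior$samples) == 0L) abort("Posterior is empty.")
  w <- posterior$weights
  accepted <- integer(0)
  n_tried <- 0L
  with_seed(cfg$seed, {
    while (length(accepted) < cfg$n_sims) {
      m <- max(2L * (cfg$n_sims - length(accepted)), 1000L)
      t_draw <- posterior$samples[sample.int(length(posterior$samples), m,
                                             replace = TRUE, prob = w)]
      counts <- rep(1L, m)
      horizon <- t_draw
      for (g in seq_len(max(horizon))) {
        active <- which(horizon >= g & counts > 0L)
        if (length(active) == 0L) break
        counts[active] <- rpois(length(active), cfg$lambda * counts[active])
      }
      n_tried <- n_tried + m
      accepted <- c(accepted, counts[counts >= cfg$min_carriers])
      if (n_tried > 1e6 && length(accepted) / n_tried < 1e-6) {
        abort("Forward-simulation acceptance rate below 1e-6.")
      }
    }
  })
  accepted <- accepted[seq_len(cfg$n_sims)]
  new_carrier_distribution(accepted, cfg, acceptance_rate = cfg$n_sims / n_tried)
}

new_carrier_distribution <- function(samples, cfg, acceptance_rate = NA_real_) {
  s <- summaries_hazen(samples)
  structure(list(samples = samples,
                 summaries = s,
                 total_today = s * cfg$coexisting_generations,
                 acceptance_rate = acceptance_rate,
                 config = cfg),
            class = "carrier_distribution")
}

#' Total carriers alive today
#'
#' Scales the per-generation summaries by the number of co-existing
#' generations: the point estimate is `coexisting_generations * median`, and
#' the interval bounds are the same multiple of the per-generation
#' percentiles.
#'
#' @param dist A `carrier_distribution`.
#' @return A tibble with `median`, `q2.5`, `q97.5` on the total-alive scale.
#' @export
#' @examples
#' # median 32 per generation and 3 co-existing generations give 96 in total
total_alive <- function(dist) {
  stopifnot(inherits(dist, "carrier_distribution"))
  tibble::as_tibble(dist$total_today)
}

#' @export
print.carrier_distribution <- function(x, ...) {
  s <- x$summaries
  tot <- x$total_today
  cat(sprintf(
    "<carrier_distribution> %d accepted trajectories (rate %.3g)\n  per generation: %g (%g-%g); total today (x%d): %g (%g-%g)\n",
    length(x$samples), x$acceptance_rate,
    s$median, s$q2.5, s$q97.5, x$config$coexisting_generations,
    tot$median, tot$q2.5, tot$q97.5))
  invisible(x)
}

#' Tidy a carrier distribution into one row per accepted trajectory
#' @param x A `carrier_distribution`.
#' @param ... Unused.
#' @return A tibble with column `carriers`.
#' @export
tidy.carrier_distribution <- function(x, ...) {
  tibble::tibble(carriers = x$samples)
}

#' One-row summary of a carrier distribution
#' @param x A `carrier_distribution`.
#' @param ... Unused.
#' @return A tibble with per-generation and total-today summaries.
#' @export
glance.carrier_distribution <- function(x, ...) {
  s <- x$summaries
  tot <- x$total_today
  tibble::tibble(median_per_generation = s$median,
                 q2.5 = s$q2.5, q97.5 = s$q97.5,
                 total_today_median = tot$median,
                 total_today_q2.5 = tot$q2.5,
                 total_today_q97.5 = tot$q97.5,
                 acceptance_rate = x$acceptance_rate)
}
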