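test_that("genealogy limiting cases give exact branch lengths", {
  g1 <- simulate_genealogy(1, 12, seed = 1)
  expect_equal(g1$total_length, 12)
  star <- simulate_genealogy(9, 47, demography_config("star"), seed = 2)
  expect_equal(star$total_length, 9 * 47)
  expect_true(all(star$edge_length == 47))
})

test_that("a two-lineage genealogy conditioned at depth t has length 2t", {
  # With n = 2 both lineages persist the full conditioned depth, whatever
  # the demography, so the total length is exactly 2t.
  for (s in 1:20) {
    g <- simulate_genealogy(2, 35, demography_config(present_size = 1e6), seed = s)
    expect_equal(g$total_length, 70, tolerance = 1e-9)
    expect_equal(max(g$node_time), 35, tolerance = 1e-9)
  }
})

test_that("conditioned coalescent genealogies are valid trees rooted at t", {
  for (s in 1:10) {
    g <- simulate_genealogy(9, 47, demography_config(), seed = s)
    expect_equal(max(g$node_time), 47, tolerance = 1e-9)
    expect_equal(sum(is.na(g$parent)), 1)  # single root
    expect_true(all(g$edge_length > 0))
    expect_equal(g$total_length, sum(g$edge_length))
    # every tip reaches the root
    paths <- founderhap:::tip_paths(g)
    expect_true(all(vapply(paths, function(p) length(p) >= 1, logical(1))))
  }
})

test_that("block decay honours its degenerate limits", {
  g <- simulate_genealogy(9, 47, demography_config("star"), seed = 3)
  flat <- toy_map(5, flat_cm = TRUE)
  res <- simulate_block_decay(g, map = flat, mu = 0.01, seed = 4)
  expect_equal(res$block_cm, 0)        # zero-cM map: nothing to break, and
  expect_equal(res$ext_left, 0)        # the whole (zero-length) region is kept
  res2 <- simulate_block_decay(g, mu = 0, seed = 5)
  expect_equal(res2$n_mutations, 0)
})

test_that("star-genealogy block extension follows the closed form exp(-n t d)", {
  n <- 9; t <- 20
  d_grid <- c(0.1, 0.25, 0.5)  # cM
  m <- 1500
  ext <- vapply(seq_len(m), function(s) {
    g <- simulate_genealogy(n, t, demography_config("star"), seed = 7000 + s)
    simulate_block_decay(g, mu = 0, seed = 8000 + s)$ext_right
  }, numeric(1))
  for (d in d_grid) {
    p_hat <- mean(ext >= d)
    p_true <- exp(-n * t * d / 100)  # rate n*t per Morgan = n*t/100 per cM
    se <- sqrt(p_true * (1 - p_true) / m)
    expect_lt(abs(p_hat - p_true), 3 * se + 1e-9)
  }
})

test_that("a degenerate prior returns that value and exact yearly conversion holds", {
  obs <- aip_observed_summary("hapmap")
  post <- abc_tmrca(obs, abc_config(prior_t = c(30, 30), n_sims = 20000, seed = 5))
  expect_true(all(post$samples == 30))
  expect_equal(post$summaries$median, 30)
  expect_equal(to_years(47), 1175)
  expect_equal(to_years(48), 1200)
  expect_equal(to_years(0), 0)
  expect_equal(to_years(c(9, 113)), c(225, 2825))
})

test_that("ABC runs replay bit-exactly from the seed and stay in prior support", {
  obs <- aip_observed_summary("hapmap")
  cfg <- abc_config(n_sims = 30000, seed = 17)
  p1 <- abc_tmrca(obs, cfg)
  p2 <- abc_tmrca(obs, cfg)
  expect_identical(p1$samples, p2$samples)
  expect_true(all(p1$samples >= cfg$prior_t[1] & p1$samples <= cfg$prior_t[2]))
  s <- p1$summaries
  expect_true(s$q2.5 <= s$median && s$median <= s$q97.5)
})

test_that("an unmatchable observation reports the failing constraint", {
  obs <- observed_summary(9, c(100, 101), 1, 14, "hapmap")  # impossible length
  expect_error(abc_tmrca(obs, abc_config(n_sims = 2000, seed = 1)),
               "block-length")
})

test_that("widening the observed block bracket does not tighten the posterior", {
  narrow <- abc_tmrca(observed_summary(9, c(1.83, 2.59), 1, 14, "hapmap"),
                      abc_config(n_sims = 1e5, seed = 23))
  wide <- abc_tmrca(observed_summary(9, c(1.4, 3.1), 1, 14, "hapmap"),
                    abc_config(n_sims = 1e5, seed = 23))
  w_narrow <- narrow$summaries$q97.5 - narrow$summaries$q2.5
  w_wide <- wide$summaries$q97.5 - wide$summaries$q2.5
  expect_gte(w_wide, w_narrow - 2)  # slack for quantile interpolation noise
})

test_that("posterior reweighting identities hold", {
  obs <- aip_observed_summary("hapmap")
  post <- abc_tmrca(obs, abc_config(n_sims = 1e5, seed = 31))
  uni <- adjust_posterior(post, weight_fn = function(t) rep(1, length(t)))
  expect_equal(uni$summaries, post$summaries)
  ind <- adjust_posterior(post, weight_fn = function(t) as.numeric(t <= 50))
  expect_equal(ind$summaries$median,
               unname(weighted_quantile(post$samples[post$samples <= 50], 0.5)))
  expect_error(adjust_posterior(post, weight_fn = function(t) rep(0, length(t))),
               "zero")
})

test_that("weighted medians match a brute-force resampling estimate", {
  set.seed(61)
  samples <- sample(1:100, 1000, replace = TRUE)
  post <- founderhap:::new_tmrca_posterior(
    samples, NULL, aip_observed_summary("hapmap"),
    abc_config(n_sims = 1000), acceptance_rate = 1)
  wfun <- function(t) ifelse(t < 30, 0.2, ifelse(t < 70, 1, 0.5))
  adj <- adjust_posterior(post, weight_fn = wfun)
  resampled <- sample(samples, 2e5, replace = TRUE, prob = wfun(samples))
  expect_lt(abs(adj$summaries$median - median(resampled)), 2)
})

test_that("the default adjustment upweights ages that can leave enough carriers", {
  obs <- aip_observed_summary("hapmap")
  post <- abc_tmrca(obs, abc_config(n_sims = 5e4, seed = 41))
  adj <- adjust_posterior(post)
  expect_true(all(adj$weights >= 0 & is.finite(adj$weights)))
  # Survival weights increase with age here (more generations to multiply),
  # so the adjusted median cannot fall below the unadjusted one by much.
  expect_gte(adj$summaries$median, post$summaries$median - 2)
})

test_that("star-model ABC posterior matches a numerically integrated one", {
  # Independent oracle: the star-model acceptance probability as a function
  # of t, computed by numerical integration of the two truncated-exponential
  # block extents and the Poisson mutation condition, rather than by
  # simulating genealogies.
  obs <- observed_summary(9, c(0.4, 1.2), 1, 14, "hapmap")
  cfg <- abc_config(prior_t = c(5L, 60L), n_sims = 3e5, mu = 5e-4,
                    demography = demography_config("star"), seed = 53)
  post <- abc_tmrca(obs, cfg)

  geo <- founderhap:::map_geometry(cfg$map, "hapmap")
  del <- 0.01
  el <- seq(del / 2, geo$flank_left, by = del)
  er <- seq(del / 2, geo$flank_right, by = del)
  kl <- findInterval(el, geo$left_offsets)
  kr <- findInterval(er, geo$right_offsets)
  accept_prob <- function(t) {
    L <- 9 * t
    r <- L / 100  # per cM
    fl <- r * exp(-r * el) * del
    fr <- r * exp(-r * er) * del
    # interior x interior
    B <- outer(el, er, "+")
    K <- outer(kl, kr, "+")
    inb <- B >= obs$block_cm[1] & B <= obs$block_cm[2]
    pm <- dpois(1, cfg$mu * L * K)
    p <- sum((fl %o% fr) * inb * pm)
    # atoms at the truncation boundaries (extent capped at the flank)
    al <- exp(-r * geo$flank_left); ar <- exp(-r * geo$flank_right)
    kl_max <- length(geo$left_offsets); kr_max <- length(geo$right_offsets)
    bl <- geo$flank_left + er
    ok <- bl >= obs$block_cm[1] & bl <= obs$block_cm[2]
    p <- p + al * sum(fr * ok * dpois(1, cfg$mu * L * (kl_max + kr)))
    br <- el + geo$flank_right
    ok <- br >= obs$block_cm[1] & br <= obs$block_cm[2]
    p <- p + ar * sum(fl * ok * dpois(1, cfg$mu * L * (kl + kr_max)))
    btot <- geo$flank_left + geo$flank_right
    if (btot >= obs$block_cm[1] && btot <= obs$block_cm[2]) {
      p <- p + al * ar * dpois(1, cfg$mu * L * (kl_max + kr_max))
    }
    p
  }
  ts <- cfg$prior_t[1]:cfg$prior_t[2]
  pt <- vapply(ts, accept_prob, numeric(1))
  oracle_pmf <- pt / sum(pt)
  emp_pmf <- tabulate(factor(post$samples, levels = ts)) / length(post$samples)
  tv <- 0.5 * sum(abs(oracle_pmf - emp_pmf))
  expect_lt(tv, 0.05)
})
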