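# End-to-end orchestration: panel -> shared block -> tMRCA ABC (per map
# source) -> adjusted posterior -> carrier forecast, with JSON artifacts.

#' Pipeline configuration
#'
#' @param panel A `haplotype_panel`, or a path to a panel TSV, or `NULL` to
#'   skip block detection and use `obs` directly.
#' @param obs Named list of [observed_summary()] objects keyed by map source,
#'   or `NULL` to derive them from the detected block.
#' @param map A [marker_map()].
#' @param map_sources Character vector of map sources to run.
#' @param abc An [abc_config()] template (its seed is re-derived per stage).
#' @param forward A [forward_config()].
#' @param out_dir Output directory for JSON artifacts (`NULL`: no files).
#' @param seed Master integer seed; every stage derives its own stream.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(panel = NULL, obs = NULL, map = aip_marker_map(),
                            map_sources = c("hapmap", "rutgers"),
                            abc = abc_config(), forward = forward_config(),
                            out_dir = NULL, seed = 1) {
  if (is.null(panel) && is.null(obs)) {
    abort("Provide a `panel` (for block detection) or observed summaries `obs`.")
  }
  bad <- setdiff(map_sources, c("hapmap", "rutgers"))
  if (length(bad)) abort(paste0("Unknown map source(s): ", paste(bad, collapse = ", ")))
  structure(list(panel = panel, obs = obs, map = map,
                 map_sources = map_sources, abc = abc, forward = forward,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

write_artifact <- function(x, path, cfg_hash, seed) {
  payload <- c(list(config_hash = cfg_hash, seed = seed), x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the founder-dating pipeline
#'
#' Executes block detection (when a panel is supplied), the tMRCA ABC per
#' map source, the survival-probability adjustment, conversion to years, and
#' the conditioned carrier forecast (from the first map source's adjusted
#' posterior). With `out_dir` set, each stage writes a JSON artifact
#' embedding the configuration hash and the seed, and a machine-readable
#' `summary.json`; identical configuration and seed reproduce identical
#' outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `pipeline_result`: `block` (or `NULL`),
#'   `posteriors` (per map source, adjusted), `carriers`, `summary` tibble.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  cfg_hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  t0 <- Sys.time()
  stage <- function(name, expr) {
    st <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    message(sprintf("[founderhap] %-14s %6.2fs", name,
                    as.numeric(difftime(Sys.time(), st, units = "secs"))))
    res
  }
  out <- function(name) file.path(cfg$out_dir, name)
  if (!is.null(cfg$out_dir) && !dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE)
  }

  panel <- cfg$panel
  if (is.character(panel)) panel <- read_haplotype_panel(panel, cfg$map)
  block <- NULL
  obs_list <- cfg$obs
  if (!is.null(panel)) {
    block <- stage("detect_block", detect_shared_block(panel))
    if (is.null(obs_list)) {
      obs_list <- lapply(setNames(cfg$map_sources, cfg$map_sources),
                         function(src) block_observed_summary(block, panel, src))
    }
    if (!is.null(cfg$out_dir)) {
      write_artifact(as.list(glance(block)), out("block.json"), cfg_hash, cfg$seed)
    }
  }

  posteriors <- list()
  for (src in cfg$map_sources) {
    obs <- obs_list[[src]]
    if (is.null(obs)) abort(sprintf("No observed summary for map source '%s'.", src))
    abc_cfg <- cfg$abc
    abc_cfg$map <- cfg$map
    abc_cfg$seed <- derive_seed(cfg$seed, paste0("abc_", src))
    post <- stage(paste0("abc_", src), abc_tmrca(obs, abc_cfg))
    post <- stage(paste0("adjust_", src), adjust_posterior(post, forward_cfg = cfg$forward))
    posteriors[[src]] <- post
    if (!is.null(cfg$out_dir)) {
      write_artifact(list(summaries = as.list(glance(post)),
                          samples = post$samples, weights = post$weights),
                     out(sprintf("posterior_%s.json", src)), cfg_hash, cfg$seed)
    }
  }

  fwd <- cfg$forward
  fwd$seed <- derive_seed(cfg$seed, "forward")
  carriers <- stage("carriers",
                    estimate_current_carriers(posteriors[[cfg$map_sources[1]]], fwd))
  if (!is.null(cfg$out_dir)) {
    write_artifact(list(summaries = as.list(glance(carriers))),
                   out("carriers.json"), cfg_hash, cfg$seed)
  }

  summary_tbl <- dplyr::bind_rows(lapply(cfg$map_sources, function(src) {
    g <- glance(posteriors[[src]])
    tibble::tibble(map_source = src,
                   tmrca_median = g$median_generations,
                   tmrca_q2.5 = g$q2.5, tmrca_q97.5 = g$q97.5,
                   years_median = to_years(g$median_generations),
                   years_q2.5 = to_years(g$q2.5),
                   years_q97.5 = to_years(g$q97.5))
  }))
  cg <- glance(carriers)
  result <- structure(list(block = block, posteriors = posteriors,
                           carriers = carriers, summary = summary_tbl,
                           config_hash = cfg_hash, seed = cfg$seed),
                      class = "pipeline_result")
  if (!is.null(cfg$out_dir)) {
    write_artifact(list(tmrca = summary_tbl, carriers = as.list(cg)),
                   out("summary.json"), cfg_hash, cfg$seed)
  }
  message(sprintf("[founderhap] pipeline done in %.2fs",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$summary)
  print(x$carriers)
  invisible(x)
}
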