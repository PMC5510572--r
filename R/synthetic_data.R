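# Seeded synthetic-data generator: founder-descended STR haplotypes with
# recombination and stepwise mutation, background chromosomes, and protein
# decay time courses.

#' Simulation configuration for synthetic STR haplotype panels
#'
#' Defines the study conditions emulated by the generator: a panel of STR
#' loci spanning a contiguous region around a disease locus, carrier
#' chromosomes descending from a single founder `t_true` generations ago with
#' recombination against background haplotypes on the genetic-map scale, and
#' stepwise STR mutation (gain or loss of one repeat unit, equal
#' probability) at rate `mu` per locus per generation per lineage.
#'
#' Background alleles are drawn independently per locus (linkage equilibrium
#' outside the founder segment), from per-locus categorical distributions
#' centred on the founder allele by default (a discretized normal over
#' founder +/- 4 repeats, giving a realistic ~20% chance of matching the
#' founder allele by state).
#'
#' @param map A [marker_map()]; defaults to the bundled 14-locus synthetic
#'   AIP-region map (8.3 Mbp).
#' @param founder_haplotype Integer repeat numbers at each locus.
#' @param t_true Generations since the founder.
#' @param n_carriers Carrier chromosomes to sample.
#' @param n_background Non-carrier background chromosomes to emit.
#' @param mu STR mutation rate per locus per generation per lineage
#'   (default 5e-4, a typical dinucleotide STR rate).
#' @param background_allele_freqs List (one element per locus) of named
#'   numeric probability vectors (names are allele repeat numbers); each must
#'   sum to 1 within 1e-9. `NULL` for the default described above.
#' @param map_source Genetic map used for recombination distances.
#' @param demography [demography_config()] for the carrier genealogy.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(map = aip_marker_map(),
                       founder_haplotype = default_founder_haplotype(),
                       t_true = 30, n_carriers = 9, n_background = 20,
                       mu = 5e-4, background_allele_freqs = NULL,
                       map_source = c("hapmap", "rutgers"),
                       demography = demography_config(), seed = 1) {
  map_source <- match.arg(map_source)
  n_loci <- nrow(map)
  if (n_loci < 2L) abort("Need at least 2 loci.")
  if (length(founder_haplotype) != n_loci) {
    abort("`founder_haplotype` length must match the number of map loci.")
  }
  t_true <- check_count(t_true, "t_true", min = 0)
  mu <- check_number(mu, "mu", min = 0)
  if (is.null(background_allele_freqs)) {
    background_allele_freqs <- default_background_freqs(founder_haplotype)
  }
  if (length(background_allele_freqs) != n_loci) {
    abort("`background_allele_freqs` needs one element per locus.")
  }
  for (f in background_allele_freqs) {
    if (abs(sum(f) - 1) > 1e-9) abort("Background frequencies must sum to 1.")
  }
  structure(list(map = map, founder_haplotype = as.integer(founder_haplotype),
                 t_true = t_true,
                 n_carriers = check_count(n_carriers, "n_carriers", min = 1),
                 n_background = check_count(n_background, "n_background"),
                 mu = mu, background_allele_freqs = background_allele_freqs,
                 map_source = map_source, demography = demography,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_founder_haplotype <- function() {
  c(12L, 9L, 14L, 17L, 11L, 23L, 13L, 15L, 10L, 19L, 16L, 12L, 21L, 14L)
}

#' @rdname sim_config
#' @export
default_background_freqs <- function(founder_haplotype) {
  w <- stats::dnorm(-4:4, sd = 2)
  w <- w / sum(w)
  lapply(founder_haplotype, function(a) {
    setNames(w, as.character(a + (-4:4)))
  })
}

draw_background_allele <- function(freqs, n) {
  alleles <- as.integer(names(freqs))
  alleles[sample.int(length(alleles), n, replace = TRUE, prob = freqs)]
}

#' Generate a synthetic panel of carrier and background STR haplotypes
#'
#' Draws a carrier genealogy with [simulate_genealogy()], places
#' recombination breakpoints as a Poisson process on the genetic (cM) scale
#' along every branch, and builds each carrier chromosome as the founder
#' haplotype inside its retained segment (the interval around the disease
#' locus unbroken on its root-to-tip path) with background alleles outside.
#' Stepwise STR mutations (+/- 1 repeat, equal probability) fall on branches
#' at rate `mu` per locus per generation and propagate to all descendant
#' carriers that still carry the founder segment at that locus. Background
#' chromosomes are drawn locus-wise from the background distributions. The
#' disease allele itself is never recombined away: carriers are carriers by
#' construction of the conditioning.
#'
#' @param config A [sim_config()].
#' @return A list of class `haplotype_panel`: `map`, `chromosomes` (tibble
#'   with `sample_id`, `copy`, `carrier`, then one integer column per
#'   marker), and `truth` (`t_true`, the genealogy, per-tip retained founder
#'   segments, and the mutation events).
#' @export
#' @examples
#' panel <- simulate_str_haplotypes(sim_config(t_true = 10, seed = 2))
#' dplyr::count(panel$chromosomes, carrier)
simulate_str_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  map <- config$map
  n_loci <- nrow(map)
  geo <- map_geometry(map, config$map_source)
  col <- paste0("cM_", config$map_source)
  locus_off <- map[[col]] - geo$disease_cm   # signed cM offsets from disease locus

  gen <- NULL
  seg <- NULL
  mut_events <- tibble::tibble(marker = character(0), branch_node = integer(0),
                               step = integer(0))
  carrier_rows <- with_seed(derive_seed(config$seed, "carriers"), {
    if (config$t_true == 0) {
      seg <- tibble::tibble(tip = seq_len(config$n_carriers),
                             ext_left = geo$flank_left, ext_right = geo$flank_right)
      matrix(rep(config$founder_haplotype, config$n_carriers),
             nrow = config$n_carriers, byrow = TRUE)
    } else {
      gen <- simulate_genealogy(config$n_carriers, config$t_true,
                                 config$demography,
                                 seed = derive_seed(config$seed, "genealogy"))
      paths <- tip_paths(gen)
      n_branch <- length(gen$edge_length)
      span_morgan <- geo$span_cm / 100
      # Per-branch breakpoints (signed cM offsets from the disease locus).
      bp <- vector("list", n_branch)
      counts <- rpois(n_branch, gen$edge_length * span_morgan)
      for (b in which(counts > 0)) {
        bp[[b]] <- runif(counts[b], -geo$flank_left, geo$flank_right)
      }
      # Per-branch stepwise mutations: locus chosen uniformly, one +/-1 step.
      mcounts <- rpois(n_branch, config$mu * gen$edge_length * n_loci)
      mut_events <- tibble::tibble(
        branch_node = rep(seq_len(n_branch), mcounts),
        marker = map$marker[sample.int(n_loci, sum(mcounts), replace = TRUE)],
        step = sample(c(-1L, 1L), sum(mcounts), replace = TRUE)
      )
      seg_l <- numeric(gen$n); seg_r <- numeric(gen$n)
      hap <- matrix(NA_integer_, nrow = gen$n, ncol = n_loci)
      for (tip in seq_len(gen$n)) {
        path <- paths[[tip]]
        pts <- unlist(bp[path])
        lt <- pts[pts < 0]; rt <- pts[pts > 0]
        el <- if (length(lt)) min(geo$flank_left, -max(lt)) else geo$flank_left
        er <- if (length(rt)) min(geo$flank_right, min(rt)) else geo$flank_right
        seg_l[tip] <- el; seg_r[tip] <- er
        retained <- (locus_off < 0 & -locus_off <= el) |
          (locus_off > 0 & locus_off <= er) | locus_off == 0
        alleles <- config$founder_haplotype
        # Apply mutations on this tip's path, only where the founder segment
        # is retained (mutations on background stretches are absorbed into
        # the background draw).
        if (nrow(mut_events) > 0) {
          on_path <- mut_events[mut_events$branch_node %in% path, ]
          if (nrow(on_path) > 0) {
            idx <- match(on_path$marker, map$marker)
            for (j in seq_along(idx)) {
              if (retained[idx[j]]) alleles[idx[j]] <- alleles[idx[j]] + on_path$step[j]
            }
          }
        }
        for (l in seq_len(n_loci)) {
          if (!retained[l]) {
            alleles[l] <- draw_background_allele(config$background_allele_freqs[[l]], 1L)
          }
        }
        hap[tip, ] <- alleles
      }
      seg <- tibble::tibble(tip = seq_len(gen$n), ext_left = seg_l, ext_right = seg_r)
      hap
    }
  })

  background_rows <- with_seed(derive_seed(config$seed, "background"), {
    if (config$n_background == 0) {
      matrix(integer(0), nrow = 0, ncol = n_loci)
    } else {
      vapply(seq_len(n_loci), function(l) {
        draw_background_allele(config$background_allele_freqs[[l]],
                               config$n_background)
      }, integer(config$n_background))
    }
  })
  if (config$n_background == 1L) background_rows <- matrix(background_rows, nrow = 1L)

  chrom <- tibble::tibble(
    sample_id = c(sprintf("carrier_%02d", seq_len(config$n_carriers)),
                  if (config$n_background > 0)
                    sprintf("background_%02d", seq_len(config$n_background))),
    copy = 1L,
    carrier = rep(c(TRUE, FALSE), c(config$n_carriers, config$n_background))
  )
  allele_tbl <- tibble::as_tibble(rbind(carrier_rows, background_rows),
                                  .name_repair = "minimal")
  names(allele_tbl) <- map$marker
  chrom <- dplyr::bind_cols(chrom, allele_tbl)

  structure(list(map = map,
                 chromosomes = chrom,
                 truth = list(t_true = config$t_true, genealogy = gen,
                              founder_segments = seg, mutations = mut_events,
                              config = config)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d chromosomes (%d carrier) x %d loci; t_true = %s\n",
              nrow(x$chromosomes), sum(x$chromosomes$carrier), nrow(x$map),
              x$truth$t_true))
  invisible(x)
}

#' Read / write a haplotype panel as TSV
#'
#' Columns `sample_id`, `copy`, `carrier`, then one integer column per locus.
#' The truth record is not serialized; the writer emits exactly the
#' observable panel.
#'
#' @param panel A `haplotype_panel` (or its `chromosomes` tibble).
#' @param map A [marker_map()] used to re-attach locus metadata on read.
#' @param path File path.
#' @return `read_haplotype_panel()` returns a `haplotype_panel` without
#'   truth; `write_haplotype_panel()` returns `path` invisibly.
#' @export
write_haplotype_panel <- function(panel, path) {
  chrom <- if (inherits(panel, "haplotype_panel")) panel$chromosomes else panel
  readr::write_tsv(chrom, path)
  invisible(path)
}

#' @rdname write_haplotype_panel
#' @export
read_haplotype_panel <- function(path, map = aip_marker_map()) {
  chrom <- readr::read_tsv(path, show_col_types = FALSE)
  missing <- setdiff(map$marker, names(chrom))
  if (length(missing)) {
    abort(paste0("Panel file lacks locus columns: ", paste(missing, collapse = ", ")))
  }
  chrom <- dplyr::mutate(chrom, carrier = as.logical(.data$carrier),
                         copy = as.integer(.data$copy))
  structure(list(map = map, chromosomes = tibble::as_tibble(chrom),
                 truth = NULL),
            class = "haplotype_panel")
}

#' Export a panel unphased
#'
#' Pairs consecutive chromosome copies of each sample and emits unordered
#' genotypes (allele pairs sorted within each locus), emulating unphased
#' genotype data. Re-phasing is out of scope; the export exists for realism
#' of downstream file formats.
#'
#' @param panel A `haplotype_panel` whose samples carry two copies each (the
#'   generator emits one copy per row; pair rows by `sample_id` first).
#' @return A tibble with `sample_id`, `carrier`, and per-locus genotype
#'   strings `"a/b"` with `a <= b`.
#' @export
unphase_panel <- function(panel) {
  chrom <- panel$chromosomes
  loci <- panel$map$marker
  chrom |>
    tidyr::pivot_longer(dplyr::all_of(loci), names_to = "marker",
                        values_to = "allele") |>
    dplyr::group_by(.data$sample_id, .data$marker) |>
    dplyr::summarise(
      carrier = any(.data$carrier),
      genotype = paste(sort(.data$allele), collapse = "/"),
      .groups = "drop") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "genotype") |>
    dplyr::select(dplyr::all_of(c("sample_id", "carrier", loci)))
}

#' Simulate a protein decay time course
#'
#' Generates normalized protein levels following one-phase decay,
#' `level(t) = 100 * ((1 - plateau) * exp(-K t) + plateau)` plus Gaussian
#' noise, for use as input to [fit_one_phase_decay()].
#'
#' @param K Degradation constant per hour, `>= 0`.
#' @param plateau Plateau as a fraction of the initial level, in `[0, 1]`.
#' @param timepoints Hours; must include 0.
#' @param n_replicates Replicates per timepoint.
#' @param noise_sd Gaussian noise standard deviation in percent, `>= 0`.
#' @param construct Label for the construct.
#' @param seed Integer seed.
#' @return A tibble (`construct`, `time_h`, `replicate`, `level_pct`).
#' @export
#' @examples
#' simulate_decay_curve(K = log(2), plateau = 0, timepoints = c(0, 1, 2),
#'                      n_replicates = 1, noise_sd = 0)
simulate_decay_curve <- function(K, plateau = 0, timepoints = c(0, 2, 4, 8, 24),
                                 n_replicates = 3, noise_sd = 5,
                                 construct = "construct", seed = 1) {
  K <- check_number(K, "K", min = 0)
  plateau <- check_number(plateau, "plateau", min = 0)
  if (plateau > 1) abort("`plateau` is a fraction in [0, 1].")
  if (!any(timepoints == 0)) abort("`timepoints` must include 0.")
  if (any(timepoints < 0)) abort("`timepoints` must be >= 0.")
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  n_replicates <- check_count(n_replicates, "n_replicates", min = 1)
  grid <- tidyr::expand_grid(time_h = as.numeric(timepoints),
                             replicate = seq_len(n_replicates))
  with_seed(seed, {
    mean_level <- 100 * ((1 - plateau) * exp(-K * grid$time_h) + plateau)
    tibble::tibble(construct = construct,
                   time_h = grid$time_h,
                   replicate = grid$replicate,
                   level_pct = mean_level + stats::rnorm(nrow(grid), 0, noise_sd))
  })
}

#' Read / write decay curves as CSV
#'
#' Schema: `construct`, `time_h`, `replicate`, `level_pct`.
#'
#' @param curves A tibble as produced by [simulate_decay_curve()].
#' @param path File path.
#' @return `read_decay_curves()` returns the tibble;
#'   `write_decay_curves()` returns `path` invisibly.
#' @export
write_decay_curves <- function(curves, path) {
  readr::write_csv(curves, path)
  invisible(path)
}

#' @rdname write_decay_curves
#' @export
read_decay_curves <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(construct = "c", time_h = "d",
                                          replicate = "i", level_pct = "d"))
}
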