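# Conserved-haploblock detection: the contiguous run of STR loci at which all
# carrier chromosomes share one identical-by-state allele, with a small
# mutation allowance, plus pairwise "private" extended sharing.

# Does a locus column satisfy sharing? Returns list(ok, deviator): ok when all
# carriers agree, or exactly one chromosome deviates from the shared allele of
# all the others (deviator = its row index within the carrier subset).
locus_sharing <- function(alleles) {
  tab <- table(alleles)
  if (length(tab) == 1L) return(list(ok = TRUE, deviator = NA_integer_))
  if (length(tab) == 2L && min(tab) == 1L && length(alleles) >= 3L) {
    minor <- names(tab)[which.min(tab)]
    return(list(ok = TRUE, deviator = which(as.character(alleles) == minor)))
  }
  # With exactly 2 chromosomes any disagreement is irreconcilable: no
  # majority allele exists.
  list(ok = FALSE, deviator = NA_integer_)
}

# Validity of a contiguous window [i, j] for the carrier allele matrix: all
# loci fully concordant except at most `allowance` loci with a single
# deviating chromosome. Returns NULL when invalid, else a tibble of the
# deviating (locus, chromosome) records.
window_mutations <- function(mat, i, j, allowance) {
  muts <- list()
  for (l in i:j) {
    s <- locus_sharing(mat[, l])
    if (!s$ok) return(NULL)
    if (!is.na(s$deviator[1])) {
      muts[[length(muts) + 1L]] <- tibble::tibble(locus_index = l,
                                                  chromosome = s$deviator)
    }
    if (length(muts) > allowance) return(NULL)
  }
  if (length(muts) == 0L) {
    return(tibble::tibble(locus_index = integer(0), chromosome = integer(0)))
  }
  dplyr::bind_rows(muts)
}

#' Detect the haploblock shared by all carrier chromosomes
#'
#' Finds the maximal contiguous run of loci containing `anchor_locus` at
#' which every carrier chromosome shares one identical-by-state allele,
#' except at up to `max_mutation_loci` loci where exactly one chromosome
#' deviates (recorded as within-block mutations). Identity is
#' identical-by-state on integer repeat numbers, with no allele-size binning.
#'
#' Span conventions: `span_min` (bp and cM) is the distance between the
#' outermost loci of the block; `span_max` extends to the nearest flanking
#' discordant loci, or to the region ends where the block reaches the edge of
#' the map. When several maximal windows tie on locus count the one with the
#' greater genetic length (then the leftmost) wins, deterministically.
#'
#' @param panel A `haplotype_panel` (only carrier chromosomes are used).
#' @param anchor_locus Marker name the block must contain; defaults to the
#'   marker nearest the disease locus.
#' @param max_mutation_loci Mutation allowance (default 1).
#' @return A list of class `shared_haploblock`: `first_locus`, `last_locus`,
#'   `n_loci`, `span_bp_min`, `span_bp_max`, `span_cm_min`, `span_cm_max`
#'   (the cM spans are tibbles with one column per map source),
#'   `mutation_loci` (tibble: `marker`, `sample_id`), `n_chromosomes`.
#' @export
#' @examples
#' panel <- simulate_str_haplotypes(sim_config(t_true = 20, seed = 3))
#' detect_shared_block(panel)
detect_shared_block <- function(panel, anchor_locus = NULL, max_mutation_loci = 1) {
  stopifnot(inherits(panel, "haplotype_panel"))
  map <- panel$map
  max_mutation_loci <- check_count(max_mutation_loci, "max_mutation_loci")
  if (is.null(anchor_locus)) {
    anchor_locus <- map$marker[which.min(abs(map$pos_bp - attr(map, "disease_bp")))]
  }
  a <- match(anchor_locus, map$marker)
  if (is.na(a)) abort(sprintf("Anchor locus '%s' is not on the map.", anchor_locus))
  carriers <- dplyr::filter(panel$chromosomes, .data$carrier)
  if (nrow(carriers) < 2L) abort("Need at least 2 carrier chromosomes.")
  mat <- as.matrix(carriers[, map$marker])
  n_loci <- nrow(map)

  best <- NULL
  for (i in seq_len(a)) {
    for (j in a:n_loci) {
      muts <- window_mutations(mat, i, j, max_mutation_loci)
      if (is.null(muts)) next
      cand <- list(i = i, j = j, muts = muts,
                   n = j - i + 1L,
                   cm = map$cM_hapmap[j] - map$cM_hapmap[i])
      if (is.null(best) ||
          cand$n > best$n ||
          (cand$n == best$n && cand$cm > best$cm + 1e-12) ||
          (cand$n == best$n && abs(cand$cm - best$cm) <= 1e-12 && cand$i < best$i)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    abort("Carrier chromosomes do not share an allele at the anchor locus.")
  }
  i <- best$i; j <- best$j
  region <- c(min(map$pos_bp), max(map$pos_bp))
  span_bp_min <- map$pos_bp[j] - map$pos_bp[i]
  span_bp_max <- (if (j < n_loci) map$pos_bp[j + 1L] else region[2]) -
    (if (i > 1L) map$pos_bp[i - 1L] else region[1])
  cm_span <- function(col) {
    lo <- if (i > 1L) map[[col]][i - 1L] else min(map[[col]])
    hi <- if (j < n_loci) map[[col]][j + 1L] else max(map[[col]])
    c(min = map[[col]][j] - map[[col]][i], max = hi - lo)
  }
  hm <- cm_span("cM_hapmap"); rt <- cm_span("cM_rutgers")
  mutation_loci <- tibble::tibble(
    marker = map$marker[best$muts$locus_index %||% integer(0)],
    sample_id = carriers$sample_id[best$muts$chromosome %||% integer(0)])
  structure(list(first_locus = map$marker[i], last_locus = map$marker[j],
                 first_index = i, last_index = j, n_loci = best$n,
                 span_bp_min = span_bp_min, span_bp_max = span_bp_max,
                 span_cm_min = tibble::tibble(hapmap = hm[["min"]],
                                              rutgers = rt[["min"]]),
                 span_cm_max = tibble::tibble(hapmap = hm[["max"]],
                                              rutgers = rt[["max"]]),
                 mutation_loci = mutation_loci,
                 n_chromosomes = nrow(carriers),
                 anchor_locus = anchor_locus),
            class = "shared_haploblock")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.shared_haploblock <- function(x, ...) {
  cat(sprintf(
    "<shared_haploblock> %s..%s (%d loci, %d chromosomes)\n  span %.2f-%.2f Mbp (%.2f-%.2f cM HapMap; %.2f-%.2f cM Rutgers); %d mutation locus/loci\n",
    x$first_locus, x$last_locus, x$n_loci, x$n_chromosomes,
    x$span_bp_min / 1e6, x$span_bp_max / 1e6,
    x$span_cm_min$hapmap, x$span_cm_max$hapmap,
    x$span_cm_min$rutgers, x$span_cm_max$rutgers,
    nrow(x$mutation_loci)))
  invisible(x)
}

#' Block summary as a one-row tibble
#' @param x A `shared_haploblock`.
#' @param ... Unused.
#' @export
glance.shared_haploblock <- function(x, ...) {
  tibble::tibble(first_locus = x$first_locus, last_locus = x$last_locus,
                 n_loci = x$n_loci, n_chromosomes = x$n_chromosomes,
                 span_bp_min = x$span_bp_min, span_bp_max = x$span_bp_max,
                 span_cm_min_hapmap = x$span_cm_min$hapmap,
                 span_cm_max_hapmap = x$span_cm_max$hapmap,
                 span_cm_min_rutgers = x$span_cm_min$rutgers,
                 span_cm_max_rutgers = x$span_cm_max$rutgers,
                 n_mutation_loci = nrow(x$mutation_loci))
}

#' Translate a detected block into an ABC observed summary
#'
#' Uses the block's min/max cM span under one map source as the
#' measurement bracket and the number of recorded within-block mutation loci
#' as the mutation count.
#'
#' @param block A `shared_haploblock`.
#' @param panel The panel the block was detected on.
#' @param map_source Genetic map source.
#' @return An [observed_summary()].
#' @export
block_observed_summary <- function(block, panel,
                                   map_source = c("hapmap", "rutgers")) {
  map_source <- match.arg(map_source)
  observed_summary(
    n_lineages = block$n_chromosomes,
    block_cm = c(block$span_cm_min[[map_source]], block$span_cm_max[[map_source]]),
    n_block_mutations = nrow(block$mutation_loci),
    n_loci = nrow(panel$map),
    map_source = map_source)
}

#' Pairwise extended haplotype sharing around the core block
#'
#' For every pair of carrier chromosomes, finds the contiguous run of loci
#' containing the core block at which the two chromosomes are
#' identical-by-state, and reports its genetic length (`span_min`
#' convention: cM between the outermost shared loci). The diagonal holds the
#' full typed-region length. Subsets of chromosomes sharing beyond the core
#' block reveal "private" sharing between closely related pedigrees.
#'
#' @param panel A `haplotype_panel`.
#' @param core_block A `shared_haploblock` from [detect_shared_block()].
#' @param map_source Genetic map source for the reported lengths.
#' @return A symmetric numeric matrix (carriers x carriers, dimnames =
#'   sample ids) of shared-run genetic lengths in cM.
#' @export
pairwise_extended_sharing <- function(panel, core_block,
                                      map_source = c("hapmap", "rutgers")) {
  map_source <- match.arg(map_source)
  stopifnot(inherits(core_block, "shared_haploblock"))
  map <- panel$map
  col <- paste0("cM_", map_source)
  carriers <- dplyr::filter(panel$chromosomes, .data$carrier)
  mat <- as.matrix(carriers[, map$marker])
  n <- nrow(mat); n_loci <- ncol(mat)
  out <- matrix(0, n, n, dimnames = list(carriers$sample_id, carriers$sample_id))
  full_span <- max(map[[col]]) - min(map[[col]])
  ci <- core_block$first_index; cj <- core_block$last_index
  for (p in seq_len(n)) {
    out[p, p] <- full_span
    for (q in seq_len(n)[-seq_len(p)]) {
      eq <- mat[p, ] == mat[q, ]
      i <- ci; j <- cj
      # The pairwise run must contain the core block; scan outward from it.
      while (i > 1L && eq[i - 1L]) i <- i - 1L
      while (j < n_loci && eq[j + 1L]) j <- j + 1L
      # Within the core block the pair may deviate at an allowed mutation
      # locus; the run is still anchored on the block by definition.
      run_cm <- map[[col]][j] - map[[col]][i]
      out[p, q] <- out[q, p] <- run_cm
    }
  }
  out
}
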