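# Shared fixtures: tiny maps and panels built in code.

# A small marker map with uniform spacing; cM columns can be forced flat to
# switch recombination off.
toy_map <- function(n_loci = 5, spacing_bp = 1e6, cm_per_mb = 1,
                    flat_cm = FALSE) {
  pos <- seq(1e6, by = spacing_bp, length.out = n_loci)
  cm <- if (flat_cm) rep(0, n_loci) else (pos - pos[1]) / 1e6 * cm_per_mb
  marker_map(
    tibble::tibble(marker = sprintf("M%02d", seq_len(n_loci)), chrom = "1",
                   pos_bp = pos, cM_hapmap = cm, cM_rutgers = cm),
    disease_bp = pos[ceiling(n_loci / 2)])
}

# A panel built directly from an allele matrix (rows = chromosomes).
toy_panel <- function(allele_matrix, map = toy_map(ncol(allele_matrix)),
                      carrier = rep(TRUE, nrow(allele_matrix))) {
  chrom <- tibble::tibble(
    sample_id = sprintf("chr%02d", seq_len(nrow(allele_matrix))),
    copy = 1L, carrier = carrier)
  alleles <- tibble::as_tibble(allele_matrix, .name_repair = "minimal")
  names(alleles) <- map$marker
  structure(list(map = map, chromosomes = dplyr::bind_cols(chrom, alleles),
                 truth = NULL),
            class = "haplotype_panel")
}

# Brute-force oracle for the shared-block detector: enumerate every
# contiguous window containing the anchor, apply the sharing rule
# independently, and pick max locus count, then max cM, then leftmost.
oracle_shared_block <- function(mat, map, anchor_index, allowance = 1) {
  n_loci <- ncol(mat)
  ok_locus <- function(x) {
    tab <- table(x)
    if (length(tab) == 1L) return(0L)              # concordant
    if (length(tab) == 2L && min(tab) == 1L && length(x) >= 3L) return(1L)
    NA_integer_                                     # irreconcilable
  }
  best <- NULL
  for (i in seq_len(anchor_index)) {
    for (j in anchor_index:n_loci) {
      devs <- vapply(i:j, function(l) ok_locus(mat[, l]), integer(1))
      if (anyNA(devs) || sum(devs) > allowance) next
      cand <- list(i = i, j = j, n = j - i + 1L,
                   cm = map$cM_hapmap[j] - map$cM_hapmap[i],
                   n_mut = sum(devs))
      if (is.null(best) || cand$n > best$n ||
          (cand$n == best$n && cand$cm > best$cm + 1e-12) ||
          (cand$n == best$n && abs(cand$cm - best$cm) <= 1e-12 && cand$i < best$i)) {
        best <- cand
      }
    }
  }
  best
}

# Exhaustive oracle for tandem-duplication detection: all (start, len) whose
# tandem insertion into wt yields mut.
oracle_tandem_dups <- function(wt, mut) {
  d <- nchar(mut) - nchar(wt)
  found <- list()
  for (s in 0:(nchar(wt) - d)) {
    seg <- substr(wt, s + 1L, s + d)
    rebuilt <- paste0(substr(wt, 1L, s + d), seg,
                      substr(wt, s + d + 1L, nchar(wt)))
    if (rebuilt == mut) found[[length(found) + 1L]] <- c(start = s, len = d)
  }
  found
}

# Independent one-phase-decay SSE minimizer (Nelder-Mead on the same model),
# used as the oracle route for F-statistic checks.
oracle_decay_sse <- function(curve) {
  obj <- function(par) {
    K <- exp(par[1]); plateau <- 100 * stats::plogis(par[2])
    sum((curve$level_pct - ((100 - plateau) * exp(-K * curve$time_h) + plateau))^2)
  }
  best <- Inf
  for (k0 in c(-3, -1.5, 0, 1)) {
    for (p0 in c(-3, 0)) {
      o <- stats::optim(c(k0, p0), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
      best <- min(best, o$value)
    }
  }
  best
}
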