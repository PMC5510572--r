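# Slipped-strand-mispairing analysis: detect a tandem duplication between WT
# and mutant sequences and locate the flanking imperfect direct repeats that
# make the duplication consistent with replication slippage.
#
# Slippage model: during replication the primer strand dissociates after
# synthesizing the 3' direct repeat, re-anneals at the 5' copy of the repeat,
# and re-synthesizes -- inserting one repeat copy plus the intervening
# sequence. A duplication is slippage-consistent when its duplicated segment
# equals intervening sequence + 3' repeat, with the 5' repeat (allowing a few
# mismatches: the repeats may be imperfect) ending exactly where the
# duplication begins.

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

hamming <- function(a, b) {
  ca <- chars(a); cb <- chars(b)
  stopifnot(length(ca) == length(cb))
  which(ca != cb)
}

#' Find a tandem duplication explaining a WT/mutant sequence pair
#'
#' Scans all placements of an inserted segment of length
#' `nchar(mut) - nchar(wt)` whose removal restores the WT sequence and whose
#' copy lies tandemly adjacent. Repeats make placements ambiguous; the
#' canonical placement reported is the 3'-most one (the HGVS convention for
#' duplications), with all equivalent alternates listed.
#'
#' @param wt,mut DNA strings (case-insensitive).
#' @param cds_offset Optional integer: the coding-sequence coordinate of the
#'   first base of `wt` minus one, enabling HGVS-style `c.` reporting.
#' @return A list of class `duplication_event`: `wt_seq`, `mut_seq`,
#'   `dup_start` (0-based offset in WT of the duplicated segment),
#'   `dup_len`, `dup_seq`, `in_frame` (`dup_len` divisible by 3),
#'   `alternate_starts` (other equivalent 0-based starts), `hgvs`
#'   (`NA` unless `cds_offset` given).
#' @export
#' @examples
#' ev <- find_tandem_duplication("aacgtacgttaa", "aacgtacgtacgttaa")
#' ev$dup_seq
find_tandem_duplication <- function(wt, mut, cds_offset = NULL) {
  wt <- tolower(as.character(wt)); mut <- tolower(as.character(mut))
  if (nchar(mut) <= nchar(wt)) {
    abort("No duplication: mutant sequence is not longer than WT.")
  }
  d <- nchar(mut) - nchar(wt)
  nm <- nchar(mut)
  starts <- integer(0)  # 0-based starts, in MUT, of a removable copy
  for (s in 0:(nm - d)) {
    rest <- paste0(substr(mut, 1L, s), substr(mut, s + d + 1L, nm))
    if (rest != wt) next
    seg <- substr(mut, s + 1L, s + d)
    nxt <- if (s + 2L * d <= nm) substr(mut, s + d + 1L, s + 2L * d) else ""
    prv <- if (s - d >= 0L) substr(mut, s - d + 1L, s) else ""
    if (identical(seg, nxt) || identical(seg, prv)) starts <- c(starts, s)
  }
  if (length(starts) == 0L) {
    abort("Not a tandem duplication: no tandem placement restores WT.")
  }
  # Canonical placement: 3'-most start whose copy is a perfect tandem square
  # with the *following* segment, i.e. the second copy of the duplicated WT
  # segment immediately follows the first (HGVS 3' rule).
  square <- vapply(starts, function(s) {
    s + 2L * d <= nm && substr(mut, s + 1L, s + d) == substr(mut, s + d + 1L, s + 2L * d)
  }, logical(1))
  s0 <- if (any(square)) max(starts[square]) else max(starts) - d
  dup_seq <- substr(mut, s0 + 1L, s0 + d)
  # 0-based start, in WT coordinates, of the duplicated WT segment: removing
  # mut[s0+d+1 .. s0+2d] (the second copy) restores WT, so the segment that
  # was duplicated starts at WT offset s0.
  dup_start <- s0
  hgvs <- NA_character_
  if (!is.null(cds_offset)) {
    hgvs <- sprintf("c.%d_%ddup", dup_start + 1L + cds_offset,
                    dup_start + d + cds_offset)
  }
  structure(list(wt_seq = wt, mut_seq = mut,
                 dup_start = dup_start, dup_len = d, dup_seq = dup_seq,
                 in_frame = d %% 3L == 0L,
                 alternate_starts = setdiff(starts, s0),
                 hgvs = hgvs),
            class = "duplication_event")
}

#' @export
print.duplication_event <- function(x, ...) {
  cat(sprintf("<duplication_event> %d bp tandem duplication at WT offset %d (%s)\n  dup_seq: %s\n",
              x$dup_len, x$dup_start,
              if (x$in_frame) "in-frame" else "frameshifting", x$dup_seq))
  if (!is.na(x$hgvs)) cat(sprintf("  HGVS: %s\n", x$hgvs))
  invisible(x)
}

#' Reconstruct the mutant sequence implied by a duplication event
#'
#' Inserts the duplicated segment tandemly after its first occurrence in WT;
#' re-detecting on the result is a fixed point of
#' [find_tandem_duplication()].
#'
#' @param event A `duplication_event`.
#' @return The mutant sequence string.
#' @export
reconstruct_mutant <- function(event) {
  wt <- event$wt_seq
  paste0(substr(wt, 1L, event$dup_start + event$dup_len),
         event$dup_seq,
         substr(wt, event$dup_start + event$dup_len + 1L, nchar(wt)))
}

#' Locate the direct repeats flanking a tandem duplication
#'
#' Searches for the longest suffix of the duplicated segment (length
#' `>= min_len`, at most `max_mismatch` mismatches) that also occurs as the
#' WT substring ending exactly where the duplication begins: the 5' repeat
#' ends where the duplication begins and the 3' repeat ends where the
#' duplication ends. Length is maximized first, then mismatches minimized.
#' The intervening sequence is the WT sequence between the two repeats, and
#' the duplication is slippage-consistent exactly when such a repeat pair
#' exists (by construction the duplicated segment then equals intervening +
#' 3' repeat).
#'
#' @param event A `duplication_event`.
#' @param min_len Minimum repeat length in bp.
#' @param max_mismatch Maximum Hamming mismatches tolerated between the two
#'   repeat copies.
#' @return A list of class `repeat_pair`: `repeat5_seq`, `repeat3_seq`,
#'   `repeat_len`, `mismatch_positions` (1-based within the repeat),
#'   `intervening_seq`, `slippage_consistent`.
#' @export
find_direct_repeats <- function(event, min_len = 6, max_mismatch = 1) {
  stopifnot(inherits(event, "duplication_event"))
  min_len <- check_count(min_len, "min_len", min = 1)
  max_mismatch <- check_count(max_mismatch, "max_mismatch")
  wt <- event$wt_seq
  d <- event$dup_len
  s0 <- event$dup_start       # 0-based start of dup segment in WT
  max_len <- min(d, s0)       # 5' repeat must fit upstream of the dup
  if (max_len >= min_len) {
    for (len in max_len:min_len) {
      r3 <- substr(event$dup_seq, d - len + 1L, d)
      r5 <- substr(wt, s0 - len + 1L, s0)
      mm <- hamming(r5, r3)
      if (length(mm) <= max_mismatch) {
        return(structure(list(repeat5_seq = r5, repeat3_seq = r3,
                              repeat_len = len, mismatch_positions = mm,
                              intervening_seq = substr(event$dup_seq, 1L, d - len),
                              slippage_consistent = TRUE),
                         class = "repeat_pair"))
      }
    }
  }
  structure(list(repeat5_seq = "", repeat3_seq = "", repeat_len = 0L,
                 mismatch_positions = integer(0), intervening_seq = "",
                 slippage_consistent = FALSE),
            class = "repeat_pair")
}

#' @export
print.repeat_pair <- function(x, ...) {
  if (x$slippage_consistent) {
    cat(sprintf("<repeat_pair> %d bp direct repeats %s / %s (%d mismatch(es))\n  intervening: %s; slippage-consistent\n",
                x$repeat_len, x$repeat5_seq, x$repeat3_seq,
                length(x$mismatch_positions), x$intervening_seq))
  } else {
    cat("<repeat_pair> no qualifying direct repeats; not slippage-consistent\n")
  }
  invisible(x)
}

#' WT and mutant AIP sequence context of the c.805_825dup
#'
#' Reconstructs the sequence context of the 21-bp AIP exon 6 duplication
#' from its published building blocks: the imperfect direct repeats
#' `caaggcctac` (5') and `caaggcccac` (3'), and the intervening sequence
#' `ttcaagcgggg`. The flanking bases are synthetic filler (the analysis only
#' uses the repeat region), sized so that with `cds_offset = 780` the event
#' reports as c.805_825dup. The duplicated segment is
#' `ttcaagcggggcaaggcccac`: the intervening sequence plus the 3' repeat, the
#' signature of slipped-strand mispairing.
#'
#' @return A list with `wt`, `mut` (DNA strings) and `cds_offset`.
#' @export
#' @examples
#' seqs <- aip_duplication_sequences()
#' find_tandem_duplication(seqs$wt, seqs$mut, cds_offset = seqs$cds_offset)
aip_duplication_sequences <- function() {
  repeat5 <- "caaggcctac"
  intervening <- "ttcaagcgggg"
  repeat3 <- "caaggcccac"
  flank5 <- "ctggagcccagcta"   # synthetic filler, 14 bp (c.781-c.794)
  flank3 <- "atggacgagttcctg"  # synthetic filler
  wt <- paste0(flank5, repeat5, intervening, repeat3, flank3)
  dup <- paste0(intervening, repeat3)
  mut <- paste0(flank5, repeat5, dup, dup, flank3)
  list(wt = wt, mut = mut, cds_offset = 780L)
}

#' Read / write sequences as FASTA
#'
#' Thin wrappers over Biostrings for single-sequence FASTA files.
#'
#' @param path FASTA file path.
#' @param seqs Named character vector of sequences.
#' @return `read_fasta()` returns a named character vector;
#'   `write_fasta()` returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    setNames(tolower(as.character(x)), names(x))
  } else {
    lines <- readLines(path)
    idx <- grep("^>", lines)
    nm <- sub("^>\\s*", "", lines[idx])
    ends <- c(idx[-1] - 1L, length(lines))
    seqs <- vapply(seq_along(idx), function(i) {
      tolower(paste0(lines[(idx[i] + 1L):ends[i]], collapse = ""))
    }, character(1))
    setNames(seqs, nm)
  }
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i] %||% paste0("seq", i)), seqs[[i]]), con)
  }
  invisible(path)
}
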