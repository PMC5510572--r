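test_that("the AIP duplication is detected with its published anatomy", {
  seqs <- aip_duplication_sequences()
  ev <- find_tandem_duplication(seqs$wt, seqs$mut, cds_offset = seqs$cds_offset)
  expect_equal(ev$dup_len, 21)
  expect_equal(ev$dup_seq, "ttcaagcggggcaaggcccac")
  expect_true(ev$in_frame)
  expect_equal(ev$hgvs, "c.805_825dup")
  rp <- find_direct_repeats(ev)
  expect_true(rp$slippage_consistent)
  expect_equal(rp$repeat5_seq, "caaggcctac")
  expect_equal(rp$repeat3_seq, "caaggcccac")
  expect_equal(length(rp$mismatch_positions), 1)
  expect_equal(rp$intervening_seq, "ttcaagcgggg")
  expect_equal(paste0(rp$intervening_seq, rp$repeat3_seq), ev$dup_seq)
})

test_that("identical sequences and non-tandem insertions are rejected", {
  expect_error(find_tandem_duplication("acgtacgt", "acgtacgt"), "No duplication")
  expect_error(find_tandem_duplication("aaaacccc", "aaaaggcccc"), "Not a tandem")
})

test_that("planted duplications match the exhaustive placement oracle", {
  bases <- c("a", "c", "g", "t")
  for (s in 1:120) {
    set.seed(s)
    wt <- paste(sample(bases, 60, replace = TRUE), collapse = "")
    start <- sample(0:51, 1)
    dup <- substr(wt, start + 1, start + 9)
    mut <- paste0(substr(wt, 1, start + 9), dup, substr(wt, start + 10, 60))
    ev <- find_tandem_duplication(wt, mut)
    expect_equal(ev$dup_len, 9)
    oracle <- oracle_tandem_dups(wt, mut)
    oracle_starts <- sort(vapply(oracle, `[[`, numeric(1), "start"))
    expect_true(ev$dup_start %in% oracle_starts)
    # Every reported placement that is a valid WT-coordinate insertion point
    # must coincide with the oracle's exhaustive (start, len) set.
    reported <- sort(unique(c(ev$dup_start, ev$alternate_starts)))
    reported_wt <- Filter(function(s) {
      s + 9 <= nchar(wt) &&
        paste0(substr(wt, 1, s + 9), substr(wt, s + 1, s + 9),
               substr(wt, s + 10, nchar(wt))) == mut
    }, reported)
    expect_setequal(as.numeric(reported_wt), oracle_starts)
    # Round-trip: reconstructing and re-detecting is a fixed point.
    expect_equal(reconstruct_mutant(ev), mut)
    ev2 <- find_tandem_duplication(wt, reconstruct_mutant(ev))
    expect_equal(ev2$dup_start, ev$dup_start)
    expect_equal(ev2$dup_seq, ev$dup_seq)
  }
})

test_that("reverse-complementing both sequences mirrors the event", {
  revcomp <- function(x) {
    chartr("acgt", "tgca", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  seqs <- aip_duplication_sequences()
  ev <- find_tandem_duplication(seqs$wt, seqs$mut)
  ev_rc <- find_tandem_duplication(revcomp(seqs$wt), revcomp(seqs$mut))
  expect_equal(ev_rc$dup_len, ev$dup_len)
  # the mirrored event reconstructs the mirrored mutant
  expect_equal(reconstruct_mutant(ev_rc), revcomp(seqs$mut))
  # coordinates reflect: the sets of valid WT-coordinate placements mirror
  wt_starts <- function(ev, wt, mut) {
    d <- ev$dup_len
    Filter(function(s) {
      s + d <= nchar(wt) &&
        paste0(substr(wt, 1, s + d), substr(wt, s + 1, s + d),
               substr(wt, s + d + 1, nchar(wt))) == mut
    }, sort(unique(c(ev$dup_start, ev$alternate_starts))))
  }
  fwd <- as.numeric(wt_starts(ev, seqs$wt, seqs$mut))
  rc <- as.numeric(wt_starts(ev_rc, revcomp(seqs$wt), revcomp(seqs$mut)))
  expect_setequal(rc, sort(nchar(seqs$wt) - ev$dup_len - fwd))
})

test_that("perfect planted direct repeats are found", {
  wt <- "aaattttttggccttttttccc"
  mut <- "aaattttttggccttttttggccttttttccc"  # dup = ggcctttttt
  ev <- find_tandem_duplication(wt, mut)
  expect_equal(ev$dup_len, 10)
  # With no mismatch budget the planted perfect 6-mer repeat is recovered.
  rp0 <- find_direct_repeats(ev, min_len = 6, max_mismatch = 0)
  expect_true(rp0$slippage_consistent)
  expect_equal(rp0$repeat_len, 6)
  expect_equal(rp0$repeat5_seq, "tttttt")
  expect_equal(length(rp0$mismatch_positions), 0)
  # With a 1-mismatch budget the length-first rule extends into the
  # homopolymer: a longer (7 bp) repeat with one mismatch wins.
  rp1 <- find_direct_repeats(ev, min_len = 6, max_mismatch = 1)
  expect_true(rp1$slippage_consistent)
  expect_equal(rp1$repeat_len, 7)
  expect_equal(length(rp1$mismatch_positions), 1)
  expect_equal(paste0(rp1$intervening_seq, rp1$repeat3_seq), ev$dup_seq)
})

test_that("repeat search maximizes length then minimizes mismatches", {
  oracle_repeats <- function(ev, min_len, max_mm) {
    best <- NULL
    for (len in min_len:min(ev$dup_len, ev$dup_start)) {
      r3 <- substr(ev$dup_seq, ev$dup_len - len + 1, ev$dup_len)
      r5 <- substr(ev$wt_seq, ev$dup_start - len + 1, ev$dup_start)
      mm <- sum(strsplit(r5, "")[[1]] != strsplit(r3, "")[[1]])
      if (mm <= max_mm && (is.null(best) || len > best$len)) {
        best <- list(len = len, mm = mm, r5 = r5, r3 = r3)
      }
    }
    best
  }
  bases <- c("a", "c", "g", "t")
  n_checked <- 0
  for (s in 1:80) {
    set.seed(200 + s)
    core <- paste(sample(bases, 8, replace = TRUE), collapse = "")
    core2 <- core
    substr(core2, 4, 4) <- sample(setdiff(bases, substr(core, 4, 4)), 1)
    interv <- paste(sample(bases, 5, replace = TRUE), collapse = "")
    flank5 <- paste(sample(bases, 10, replace = TRUE), collapse = "")
    flank3 <- paste(sample(bases, 10, replace = TRUE), collapse = "")
    wt <- paste0(flank5, core, interv, core2, flank3)
    dup <- paste0(interv, core2)
    mut <- paste0(flank5, core, dup, dup, flank3)
    ev <- tryCatch(find_tandem_duplication(wt, mut), error = function(e) NULL)
    if (is.null(ev) || ev$dup_len != nchar(dup)) next  # accidental extra repeats
    rp <- find_direct_repeats(ev, min_len = 6, max_mismatch = 1)
    o <- oracle_repeats(ev, 6, 1)
    expect_true(rp$slippage_consistent)
    expect_equal(rp$repeat_len, o$len)
    expect_equal(length(rp$mismatch_positions), o$mm)
    expect_equal(rp$repeat5_seq, o$r5)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 50)
})

test_that("absence of repeats is reported as slippage-inconsistent", {
  # Construct a duplication whose upstream context shares nothing with it.
  wt <- paste0(strrep("a", 12), "ccccggtgtg")
  mut <- paste0(strrep("a", 12), "ccccggtgtg", "ccccggtgtg")
  ev <- find_tandem_duplication(wt, mut)
  rp <- find_direct_repeats(ev, min_len = 6, max_mismatch = 1)
  expect_false(rp$slippage_consistent)
  expect_equal(rp$repeat_len, 0)
})

test_that("FASTA round-trips preserve sequences", {
  seqs <- aip_duplication_sequences()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(c(wt = seqs$wt, mut = seqs$mut), path)
  back <- read_fasta(path)
  expect_equal(unname(back["wt"]), seqs$wt)
  expect_equal(unname(back["mut"]), seqs$mut)
})
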