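test_that("fully identical carriers yield a block covering the whole map", {
  mat <- matrix(5L, nrow = 9, ncol = 14)
  map <- aip_marker_map()
  panel <- toy_panel(mat, map)
  b <- detect_shared_block(panel)
  expect_equal(b$first_locus, map$marker[1])
  expect_equal(b$last_locus, map$marker[14])
  expect_equal(b$span_bp_min, max(map$pos_bp) - min(map$pos_bp))
  expect_equal(b$span_bp_max, max(map$pos_bp) - min(map$pos_bp))
  expect_equal(b$span_cm_min$hapmap, max(map$cM_hapmap) - min(map$cM_hapmap))
  expect_equal(nrow(b$mutation_loci), 0)
})

test_that("carriers sharing only the anchor give a single-locus block", {
  # Two chromosomes agree at the anchor (middle locus) and nowhere else.
  mat <- rbind(c(1L, 1L, 7L, 1L, 1L),
               c(2L, 2L, 7L, 2L, 2L))
  panel <- toy_panel(mat)
  b <- detect_shared_block(panel, anchor_locus = "M03", max_mutation_loci = 0)
  expect_equal(b$first_locus, "M03")
  expect_equal(b$last_locus, "M03")
  expect_equal(b$span_bp_min, 0)
  expect_equal(b$span_cm_min$hapmap, 0)
})

test_that("a single deviating chromosome is absorbed by the mutation allowance", {
  mat <- matrix(4L, nrow = 3, ncol = 5)
  mat[2, 3] <- 9L  # one chromosome deviates at the middle locus
  panel <- toy_panel(mat)
  b <- detect_shared_block(panel, anchor_locus = "M03", max_mutation_loci = 1)
  expect_equal(c(b$first_index, b$last_index), c(1L, 5L))
  expect_equal(b$mutation_loci$marker, "M03")
  expect_equal(b$mutation_loci$sample_id, "chr02")
  o <- oracle_shared_block(mat, panel$map, 3, allowance = 1)
  expect_equal(c(b$first_index, b$last_index), c(o$i, o$j))
  # Without the allowance the block must not bridge the deviation.
  b0 <- detect_shared_block(panel, anchor_locus = "M04", max_mutation_loci = 0)
  expect_equal(c(b0$first_index, b0$last_index), c(4L, 5L))
  # An anchor that is itself irreconcilable is an input error.
  expect_error(detect_shared_block(panel, "M03", max_mutation_loci = 0),
               "anchor")
})

test_that("detection agrees with the brute-force window oracle exhaustively", {
  # Every 4-locus / 3-chromosome panel over a biallelic alphabet.
  map <- toy_map(4)
  combos <- expand.grid(rep(list(1:2), 12))
  for (r in seq_len(nrow(combos))) {
    mat <- matrix(as.integer(unlist(combos[r, ])), nrow = 3, ncol = 4)
    o <- oracle_shared_block(mat, map, anchor_index = 2, allowance = 1)
    if (is.null(o)) {
      expect_error(detect_shared_block(toy_panel(mat, map), "M02"), "anchor")
    } else {
      b <- detect_shared_block(toy_panel(mat, map), "M02")
      expect_identical(c(b$first_index, b$last_index), c(o$i, o$j))
      expect_identical(nrow(b$mutation_loci), as.integer(o$n_mut))
    }
  }
})

test_that("reversing marker order yields a mirror-identical block", {
  set.seed(21)
  mat <- matrix(sample(1:3, 9 * 8, replace = TRUE), nrow = 8)
  mat[, 4:6] <- 2L
  map <- toy_map(9)
  b <- detect_shared_block(toy_panel(mat, map), "M05")
  # Mirror the panel: reverse locus order, flip coordinates.
  pos_r <- rev(max(map$pos_bp) + min(map$pos_bp) - map$pos_bp)
  cm_r <- rev(max(map$cM_hapmap) - map$cM_hapmap)
  map_r <- marker_map(
    tibble::tibble(marker = sprintf("M%02d", 1:9), chrom = "1", pos_bp = pos_r,
                   cM_hapmap = cm_r, cM_rutgers = cm_r),
    disease_bp = max(map$pos_bp) + min(map$pos_bp) - attr(map, "disease_bp"))
  b_r <- detect_shared_block(toy_panel(mat[, 9:1], map_r), "M05")
  expect_equal(b_r$n_loci, b$n_loci)
  expect_equal(b_r$span_bp_min, b$span_bp_min)
  expect_equal(b_r$span_cm_min$hapmap, b$span_cm_min$hapmap)
  expect_equal(10L - b_r$last_index, b$first_index)
})

test_that("the block always contains the anchor and grows with the allowance", {
  set.seed(33)
  for (rep in 1:20) {
    mat <- matrix(sample(1:3, 7 * 5, replace = TRUE), nrow = 5)
    mat[, 4] <- 1L  # guarantee anchor concordance
    panel <- toy_panel(mat, toy_map(7))
    b1 <- detect_shared_block(panel, "M04", max_mutation_loci = 0)
    b2 <- detect_shared_block(panel, "M04", max_mutation_loci = 1)
    expect_true(b1$first_index <= 4 && b1$last_index >= 4)
    expect_gte(b2$n_loci, b1$n_loci)
  }
})

test_that("pairwise extended sharing matches a brute-force per-pair scan", {
  set.seed(44)
  mat <- matrix(sample(1:2, 6 * 10, replace = TRUE), nrow = 6)
  mat[, 5:6] <- 3L
  map <- toy_map(10)
  panel <- toy_panel(mat, map)
  core <- detect_shared_block(panel, "M05", max_mutation_loci = 0)
  m <- pairwise_extended_sharing(panel, core)
  full <- max(map$cM_hapmap) - min(map$cM_hapmap)
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == full))
  for (p in 1:5) for (q in (p + 1):6) {
    i <- core$first_index; j <- core$last_index
    while (i > 1 && mat[p, i - 1] == mat[q, i - 1]) i <- i - 1
    while (j < 10 && mat[p, j + 1] == mat[q, j + 1]) j <- j + 1
    expect_equal(m[p, q], map$cM_hapmap[j] - map$cM_hapmap[i])
  }
})

test_that("identical chromosomes share the full region pairwise", {
  mat <- matrix(2L, nrow = 4, ncol = 6)
  map <- toy_map(6)
  panel <- toy_panel(mat, map)
  core <- detect_shared_block(panel, "M03")
  m <- pairwise_extended_sharing(panel, core)
  expect_true(all(m == max(map$cM_hapmap)))
})

test_that("input errors are reported for bad anchors and too few carriers", {
  panel <- toy_panel(matrix(1L, 3, 5))
  expect_error(detect_shared_block(panel, "nope"), "not on the map")
  solo <- toy_panel(matrix(1L, 1, 5))
  expect_error(detect_shared_block(solo, "M03"), "2 carrier")
})

test_that("a detected block converts into a usable observed summary", {
  mat <- matrix(5L, nrow = 9, ncol = 14); mat[3, 7] <- 6L
  panel <- toy_panel(mat, aip_marker_map())
  b <- detect_shared_block(panel)
  obs <- block_observed_summary(b, panel, "hapmap")
  expect_s3_class(obs, "observed_summary")
  expect_equal(obs$n_lineages, 9)
  expect_equal(obs$n_block_mutations, 1)
  expect_equal(obs$block_cm[1], b$span_cm_min$hapmap)
})
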