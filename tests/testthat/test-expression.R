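test_that("mapping references concatenate units by the stated rules", {
  r30 <- prepare_reference(strrep("ACGTA", 6), read_length = 101)
  expect_identical(r30$copies, 4L)
  expect_identical(nchar(r30$sequence), 120L)
  withr::with_seed(61, {
    u172 <- random_seq(172, 0.75)
    r172 <- prepare_reference(u172, read_length = 76)
    expect_identical(r172$copies, 2L)
    expect_identical(nchar(r172$sequence), 344L)
    u100 <- random_seq(100, 0.75)
    r100 <- prepare_reference(u100, read_length = 100)
    expect_identical(r100$copies, 2L)
  })
})

test_that("reads map to their best reference once, above the identity floor", {
  withr::with_seed(62, {
    uA <- random_seq(150, 0.7)
    uB <- satcomp:::mutate_copies(uA, 1, 0.30)  # ~70% identical to A
    refs <- list(prepare_reference(uA, 101, family = "A"),
                 prepare_reference(uB, 101, family = "B"))
    # exact substring of A: one hit for A
    rd <- substr(refs[[1]]$sequence, 10, 110)
    mp <- map_reads(rd, refs)
    expect_identical(unname(mp$counts), c(1L, 0L))
    expect_identical(mp$total_mapped, 1L)
    # read ~90% identical to A and ~70% to B: counted for A only
    rd2 <- satcomp:::mutate_copies(rd, 1, 0.10)
    mp2 <- map_reads(rd2, refs)
    expect_identical(unname(mp2$counts), c(1L, 0L))
    # reverse-complemented reads map identically
    mp3 <- map_reads(revcomp(rd), refs)
    expect_identical(unname(mp3$counts), c(1L, 0L))
    # junk stays unassigned
    mp4 <- map_reads(random_seq(101, 0.5), refs)
    expect_identical(mp4$total_mapped, 0L)
    expect_identical(mp4$unassigned, 1L)
    expect_error(map_reads(rd, list()), "empty reference")
  })
})

test_that("hit fractions from a known mixture match planted fractions", {
  spec <- make_nested_spec(0.002)
  tr <- synthesize_library(spec, seed = 63)
  lib <- generate_transcriptome_reads(tr, "M4", "J2", library_size = 3e4,
                                      seed = 64)
  pres <- which(tr$presence[, "M4"])
  refs <- lapply(pres, function(i)
    prepare_reference(tr$consensi[i, "M4"], 101L,
                      family = rownames(tr$presence)[i]))
  mp <- map_reads(lib$reads, refs, background = tr$genes)
  expect_gte(mp$total_mapped / length(lib$reads), 0.99)
  for (f in names(mp$counts)) {
    p <- lib$expected_fractions[f]
    sigma <- sqrt(3e4 * p * (1 - p))
    expect_lt(abs(mp$counts[f] - 3e4 * p), 3 * sigma + 3)
  }
})

test_that("rpkm follows the formula and its scale invariance", {
  expect_equal(rpkm(100, 1e6, 100), 1000)
  expect_equal(rpkm(0, 1e6, 100), 0)
  expect_equal(rpkm(50, 5e5, 200), 500)
  expect_equal(rpkm(100, 1e6, 100), rpkm(200, 2e6, 100))
  expect_error(rpkm(10, 0, 100))
  expect_error(rpkm(10, 1e6, 0), "unit_length")
})

test_that("log profiles keep masks and zeros distinct", {
  m <- matrix(c(1023, 0, NA, 7), 2, 2)
  lg <- log_profile(m)
  expect_equal(lg[1, 1], 10)
  expect_equal(lg[2, 1], 0)
  expect_true(is.na(lg[1, 2]))
  expect_equal(lg[2, 2], 3)
})

test_that("activity ratios and active calls follow the stated rules", {
  expect_equal(activity_ratio(1e-3, 1e-3), 0)
  expect_equal(activity_ratio(2e-3, 1e-3), 1)
  expect_equal(activity_ratio(5e-4, 1e-3), -1)
  expect_identical(activity_ratio(0, 1e-3), -Inf)
  expect_error(activity_ratio(1e-3, 0))
  ratios <- rbind(both_pos = c(0.5, 0.2),
                  mixed = c(0.5, -0.1),
                  absent_other = c(0.5, NA),
                  silent = c(-0.2, -Inf))
  colnames(ratios) <- c("spA", "spB")
  act <- call_active(ratios)
  expect_setequal(act$candidates, c("both_pos", "mixed", "absent_other"))
  expect_setequal(act$cross_species_active, c("both_pos", "absent_other"))
})

test_that("pearson matches the closed form and rejects degenerate input", {
  expect_equal(pearson(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_equal(pearson(1:5, 1:5), 1)
  expect_equal(pearson(1:3, 3:1), -1)
  # masked pairs are dropped before the computation
  expect_equal(pearson(c(1, 2, 3, NA), c(1, 3, 2, 5)), 0.5)
  expect_error(pearson(c(1, 2), c(2, 1)), "at least 3")
  expect_warning(r <- pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_true(is.na(r))
})

test_that("replicate profiles correlate higher than cross-species profiles", {
  spec <- make_nested_spec(0.002)
  tr <- synthesize_library(spec, seed = 65)
  libs <- lapply(c(71, 72), function(sd)
    generate_transcriptome_reads(tr, "M4", "J2", library_size = 5e4,
                                 seed = sd))
  pres <- which(tr$presence[, "M4"])
  refs <- lapply(pres, function(i)
    prepare_reference(tr$consensi[i, "M4"], 101L,
                      family = rownames(tr$presence)[i]))
  em <- expression_matrix(list(rep1 = libs[[1]]$reads, rep2 = libs[[2]]$reads),
                          refs, background = tr$genes)
  r_rep <- pearson(em$log2rpkm[, "rep1"], em$log2rpkm[, "rep2"])
  expect_gte(r_rep, 0.95)
  # perturbed sibling-species profile: weaker but positive correlation
  withr::with_seed(73, {
    perturbed <- em$rpkm[, "rep1"] * 2^stats::rnorm(nrow(em$rpkm), 0, 0.9)
    r_sib <- pearson(em$log2rpkm[, "rep1"], log2(perturbed + 1))
  })
  expect_lt(r_sib, r_rep)
  expect_gt(r_sib, 0.3)
})

test_that("stage clustering recovers planted archetype groups", {
  withr::with_seed(66, {
    arch <- rbind(always_high = c(8, 8, 8, 8, 8, 8),
                  dropout = c(5, 5, 0, 5, 5, 0),
                  low = c(1, 1, 1, 1, 1, 1),
                  restricted = c(8, 1, 1, 1, 1, 8))
    m <- arch[rep(1:4, each = 5), ] + matrix(rnorm(120, 0, 0.3), 20, 6)
    rownames(m) <- sprintf("f%02d", 1:20)
    cl <- cluster_stages(m, k = 4)
    truth <- rep(1:4, each = 5)
    # same-archetype rows share a cluster, different archetypes never do
    expect_identical(length(unique(paste(cl$assignment, truth))), 4L)
    # k = 1: everything together
    cl1 <- cluster_stages(m, k = 1)
    expect_true(all(cl1$assignment == 1L))
    # identical rows: deterministic assignment by row order
    ident <- matrix(1, 5, 3, dimnames = list(paste0("r", 1:5), NULL))
    c2 <- cluster_stages(ident, k = 4)
    c3 <- cluster_stages(ident, k = 4)
    expect_identical(c2$assignment, c3$assignment)
    expect_identical(length(unique(c2$assignment)), 4L)
    expect_error(cluster_stages(ident, k = 9), "exceeds")
  })
})

test_that("simulated stage archetypes separate in the clustered heatmap matrix", {
  spec <- default_library_spec(genome_scale = 0.002)
  tr <- synthesize_library(spec, seed = 67)
  # expected log2 RPKM profile per family across stages, from the
  # planted activity multipliers (fast surrogate for full libraries)
  act <- spec$activity
  gf <- spec$fractions[, "M2"]
  keep <- tr$presence[, "M2"] & gf > 1e-4
  prof <- log2(1 + 1e6 * gf[keep] * act[keep, ] /
                 (spec$families$unit_length[keep] / 1000))
  cl <- cluster_stages(prof, k = 4)
  expect_identical(cl$k, 4L)
  expect_identical(sort(unique(unname(cl$assignment))), 1:4)
})
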