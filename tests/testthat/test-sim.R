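test_that("library_spec validates its invariants", {
  species <- data.frame(name = c("A", "B"), ploidy = c("2n", "4n"),
                        genome_size = c(1e6, 2e6))
  fam <- data.frame(id = c("f1", "f2"), unit_length = c(100, 50),
                    at_fraction = c(0.7, 0.8), divergence = c(0.02, 0.02),
                    signature = c("A+B", "B"))
  expect_s3_class(library_spec(species, fam, c(0.001, 0.002)), "library_spec")
  fam_dup <- fam; fam_dup$id <- c("f1", "f1")
  expect_error(library_spec(species, fam_dup, c(0.001, 0.002)), "duplicate")
  fam_div <- fam; fam_div$divergence <- c(0.6, 0.02)
  expect_error(library_spec(species, fam_div, c(0.001, 0.002)),
               "identity undefined")
  fam_len <- fam; fam_len$unit_length <- c(10, 50)
  expect_error(library_spec(species, fam_len, c(0.001, 0.002)), "unit_length")
  expect_error(library_spec(species, fam, c(0.2, 0.2)), "minor genome fraction")
})

test_that("default spec plants the nested subset design with catalog-like features", {
  spec <- default_library_spec(genome_scale = 0.01)
  part <- partition_by_signature(spec$presence)
  # 39/20/21 nested subsets minus the four planted losses, plus privates
  expect_identical(unname(part$counts["M1+M2+M3+M4"]), 35L)
  expect_identical(unname(part$counts["M2+M3+M4"]), 20L)
  expect_identical(unname(part$counts["M3+M4"]), 21L)
  expect_identical(unname(part$counts["M1+M3+M4"]), 2L)  # lost in M2
  expect_identical(unname(part$counts["M1+M2+M4"]), 2L)  # lost in M3
  expect_identical(sum(part$counts), 83L)
  # unit lengths within the catalog range, bimodal concentration
  expect_true(all(spec$families$unit_length >= 30 &
                    spec$families$unit_length <= 300))
  bins <- length_distribution(spec$families$unit_length,
                              list(c(50, 90), c(170, 190)))
  expect_gte(sum(bins), 45)
  expect_true(all(spec$families$at_fraction >= 0.70 &
                    spec$families$at_fraction <= 0.80))
  # abundances in the catalog range and a minor total genome fraction
  expect_true(all(spec$fractions[spec$presence] >= 2e-5 - 1e-12))
  expect_equal(max(spec$fractions), 0.00613, tolerance = 1e-9)
  expect_true(all(colSums(spec$fractions) < 0.06))
})

test_that("synthesized truth is deterministic and respects divergence settings", {
  spec <- make_nested_spec(0.002)
  t1 <- synthesize_library(spec, seed = 9)
  t2 <- synthesize_library(spec, seed = 9)
  expect_identical(t1, t2)
  t3 <- synthesize_library(spec, seed = 10)
  expect_false(identical(t1$consensi, t3$consensi))
  # zero divergence: per-species consensi identical strings
  spec0 <- make_nested_spec(0.002)
  spec0$families$divergence[] <- 0
  tr0 <- synthesize_library(spec0, seed = 1)
  for (i in seq_len(nrow(tr0$presence))) {
    cs <- tr0$consensi[i, !is.na(tr0$consensi[i, ])]
    expect_true(all(cs == cs[1]))
  }
  # copy number consistent with fraction within rounding
  fr <- t1$copy_number * spec$families$unit_length /
    matrix(rep(spec$species$genome_size, each = 14), 14)
  dev <- abs(fr - spec$fractions)[spec$presence]
  expect_true(all(dev <= spec$families$unit_length[row(spec$presence)][spec$presence] /
                    rep(spec$species$genome_size, each = 14)[spec$presence]))
})

test_that("interspecies consensus divergence matches the planted rate", {
  spec <- make_nested_spec(0.002)
  tr <- synthesize_library(spec, seed = 4)
  divs <- c()
  for (i in seq_len(nrow(tr$presence))) {
    sp <- which(tr$presence[i, ])
    if (length(sp) < 2) next
    pr <- utils::combn(sp, 2)
    for (j in seq_len(ncol(pr))) {
      a <- tr$consensi[i, pr[1, j]]; b <- tr$consensi[i, pr[2, j]]
      divs <- c(divs, mean(charToRaw(a) != charToRaw(b)))
    }
  }
  # each species mutated at divergence/2 from the ancestor; expected
  # pairwise divergence ~ 2.7% (slightly less through coincident hits)
  expect_gt(mean(divs), 0.015)
  expect_lt(mean(divs), 0.04)
})

test_that("genomic read simulation honors coverage arithmetic and determinism", {
  spec <- make_mining_spec(n = 5L, genome_size = 2e6)
  tr <- synthesize_library(spec, seed = 2)
  rr <- generate_genome_reads(tr, "S1", coverage = 0.25, read_length = 100,
                              seed = 7)
  expect_identical(rr$n_reads, 5000)
  expect_true(all(nchar(rr$reads) == 100))
  rr2 <- generate_genome_reads(tr, "S1", coverage = 0.25, read_length = 100,
                               seed = 7)
  expect_identical(rr$reads, rr2$reads)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(rr$reads, f1); write_fastq(rr2$reads, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))
  expect_false(identical(
    rr$reads, generate_genome_reads(tr, "S1", coverage = 0.25, seed = 8)$reads))
})

test_that("error-free reads are exact substrings of the genome mosaic", {
  spec <- make_mining_spec(n = 3L, genome_size = 2e5)
  tr <- synthesize_library(spec, seed = 3)
  rr <- generate_genome_reads(tr, "S1", coverage = 0.1, error_rate = 0,
                              seed = 3, keep_genome = TRUE)
  fwd <- rr$strand == "+"
  expect_true(all(vapply(which(fwd)[1:50], function(i)
    grepl(rr$reads[i], rr$genome, fixed = TRUE), TRUE)))
  expect_true(all(vapply(which(!fwd)[1:50], function(i)
    grepl(revcomp(rr$reads[i]), rr$genome, fixed = TRUE), TRUE)))
})

test_that("per-family read fractions land inside binomial bounds", {
  spec <- make_mining_spec(n = 5L, genome_size = 2e6)
  tr <- synthesize_library(spec, seed = 6)
  rr <- generate_genome_reads(tr, "S1", coverage = 0.5, seed = 6)
  frac <- spec$fractions[, "S1"]
  for (i in seq_along(frac)) {
    # read overlaps slightly inflate the array fraction; use the
    # midpoint-origin convention and 99% binomial bounds
    got <- sum(rr$origin == spec$families$id[i])
    ci <- stats::qbinom(c(0.005, 0.995), rr$n_reads, frac[i])
    expect_gte(got, ci[1] - 1)
    expect_lte(got, ci[2] + 1)
  }
})

test_that("transcriptome libraries follow the passive/active model", {
  spec <- make_nested_spec(0.002)
  spec$activity["Fam02", ] <- 4
  tr <- synthesize_library(spec, seed = 12)
  lib <- generate_transcriptome_reads(tr, "M4", "J2", library_size = 1e5,
                                      seed = 13)
  tf <- lib$expected_fractions
  gf <- spec$fractions[, "M4"]
  # passive families: expected transcript fraction equals genomic fraction
  passive <- setdiff(names(tf)[tf > 0], "Fam02")
  expect_equal(unname(tf[passive]), unname(gf[passive]))
  # multiplier-4 family: activity ratio log2(4) = 2 by construction, and
  # the sampled estimate recovers it within Monte-Carlo error
  expect_equal(unname(log2(tf["Fam02"] / gf["Fam02"])), 2)
  est <- log2((lib$counts["Fam02"] / lib$library_size) / gf["Fam02"])
  expect_lt(abs(est - 2), 0.25)
  # family absent from the genome yields zero transcript reads
  absent <- rownames(tr$presence)[!tr$presence[, "M4"]]
  expect_true(all(lib$counts[absent] == 0))
  # determinism
  lib2 <- generate_transcriptome_reads(tr, "M4", "J2", library_size = 1e5,
                                       seed = 13)
  expect_identical(lib$reads, lib2$reads)
})
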