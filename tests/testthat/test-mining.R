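test_that("similarity graph edges count distinct shared canonical k-mers", {
  withr::with_seed(21, {
    r <- random_seq(100, 0.5)
    g <- build_similarity_graph(c(r, r), k = 17, min_shared = 5)
    expect_identical(nrow(g$edges), 1L)
    # identical reads share every distinct canonical 17-mer
    expect_identical(g$edges$weight,
                     length(oracle_read_kmers(r, 17L)))
    # unrelated random sequences share no 17-mer
    g2 <- build_similarity_graph(c(random_seq(100, 0.5), random_seq(100, 0.5)),
                                 k = 17, min_shared = 5)
    expect_identical(nrow(g2$edges), 0L)
    # empty input gives an empty graph
    g3 <- build_similarity_graph(character(0))
    expect_identical(g3$n_reads, 0L)
    expect_identical(nrow(g3$edges), 0L)
  })
})

test_that("graph construction validates k and read lengths", {
  expect_error(build_similarity_graph(c("ACGT"), k = 16), "k")
  expect_error(build_similarity_graph(rep("ACGTACGT", 3), k = 17),
               "shorter than k")
})

test_that("reads from two planted families form exactly two components", {
  withr::with_seed(22, {
    u1 <- random_seq(120, 0.72)
    u2 <- random_seq(80, 0.78)
    reads <- c(tiled_reads(u1, 20, by = 11, copy_divergence = 0.02,
                           error_rate = 0.01),
               tiled_reads(u2, 25, by = 13, copy_divergence = 0.02,
                           error_rate = 0.01))
    g <- build_similarity_graph(reads)
    cls <- cluster_graph(g, min_cluster_size = 10)
    expect_length(cls, 2L)
    # members of each cluster come from one family: the split index is
    # the number of u1-derived reads
    n1 <- length(tiled_reads(u1, 20, by = 11))
    for (cl in cls) {
      from1 <- mean(cl$members <= n1)
      expect_true(from1 %in% c(0, 1))
    }
  })
})

test_that("cluster density matches clique and chain expectations", {
  withr::with_seed(23, {
    # two disjoint cliques: reads tiled densely from short monomers so
    # every pair overlaps on the monomer circle
    u1 <- random_seq(40, 0.7); u2 <- random_seq(45, 0.7)
    reads <- c(tiled_reads(u1, 60, by = 97)[1:20],
               tiled_reads(u2, 60, by = 97)[1:20])
    g <- build_similarity_graph(reads)
    cls <- cluster_graph(g, min_cluster_size = 10)
    expect_length(cls, 2L)
    expect_equal(cls[[1]]$density, 1.0)
    expect_equal(cls[[2]]$density, 1.0)
    # chain of 5: consecutive reads share one 50-bp block
    blocks <- vapply(1:6, function(i) random_seq(50, 0.5), "")
    chain <- vapply(1:5, function(i) paste0(blocks[i], blocks[i + 1]), "")
    gc <- build_similarity_graph(chain, min_shared = 5)
    ccl <- cluster_graph(gc, min_cluster_size = 3)
    expect_length(ccl, 1L)
    expect_equal(ccl[[1]]$density, 0.4)  # 4 edges over 10 pairs
  })
})

test_that("label-propagation refinement is deterministic and keeps cliques whole", {
  withr::with_seed(27, {
    u1 <- random_seq(40, 0.7); u2 <- random_seq(45, 0.7)
    reads <- c(tiled_reads(u1, 60, by = 97)[1:15],
               tiled_reads(u2, 60, by = 97)[1:15])
    g <- build_similarity_graph(reads)
    r1 <- cluster_graph(g, min_cluster_size = 10, refine = TRUE)
    r2 <- cluster_graph(g, min_cluster_size = 10, refine = TRUE)
    expect_length(r1, 2L)
    expect_identical(lapply(r1, `[[`, "members"),
                     lapply(r2, `[[`, "members"))
    # refinement of two disjoint cliques reproduces the components
    r0 <- cluster_graph(g, min_cluster_size = 10, refine = FALSE)
    expect_identical(lapply(r1, `[[`, "members"),
                     lapply(r0, `[[`, "members"))
  })
})

test_that("monomer period is recovered with the minimal-period rule", {
  # exact pentamer: periods 5, 10, ... all perfect; smallest reported
  reads <- tiled_reads(strrep("ACGTT", 1), copies = 100, by = 7)
  pe <- estimate_monomer_period(reads)
  expect_identical(pe$period, 5L)
  expect_equal(pe$identity, 1.0)
  withr::with_seed(24, {
    # 172-bp planted monomer at 2% copy divergence
    u <- random_seq(172, 0.75)
    reads2 <- tiled_reads(u, 40, by = 7, copy_divergence = 0.02)
    pe2 <- estimate_monomer_period(reads2)
    expect_identical(pe2$period, 172L)
    # non-tandem input: unrelated reads give no period
    rnd <- vapply(1:15, function(i) random_seq(100, 0.5), "")
    pe3 <- estimate_monomer_period(rnd)
    expect_true(is.na(pe3$period))
  })
})

test_that("consensus derivation recovers the planted monomer", {
  withr::with_seed(25, {
    u <- random_seq(90, 0.74)
    # noiseless: consensus equals the monomer up to rotation/strand
    reads <- tiled_reads(u, 30, by = 7)
    rec <- derive_consensus(reads, 90L)
    expect_identical(rec$sequence, canonical_rotation(u))
    expect_identical(rec$unit_length, 90L)
    # half the reads reverse-complemented: identical record
    half <- seq_along(reads) %% 2 == 0
    reads_rc <- reads
    reads_rc[half] <- revcomp(reads_rc[half])
    rec_rc <- derive_consensus(reads_rc, 90L)
    expect_identical(rec_rc$sequence, rec$sequence)
    # 2% copy divergence + 1% errors: consensus >= 98% identical
    for (s in 1:3) {
      reads3 <- tiled_reads(u, 40, by = 7, copy_divergence = 0.02,
                            error_rate = 0.01)
      rec3 <- derive_consensus(reads3, 90L)
      expect_gte(pairwise_identity(rec3$sequence, u, circular = TRUE), 98)
    }
    # too few reads: low-support error
    expect_error(derive_consensus(reads[1:2], 90L), "low support")
  })
})

test_that("mining output is invariant to reverse-complementing all reads", {
  withr::with_seed(26, {
    u1 <- random_seq(60, 0.72); u2 <- random_seq(130, 0.76)
    reads <- c(tiled_reads(u1, 40, by = 9, copy_divergence = 0.02),
               tiled_reads(u2, 30, by = 9, copy_divergence = 0.02))
    m1 <- mine_satellites(reads)
    m2 <- mine_satellites(revcomp(reads))
    expect_identical(sort(unname(m1$consensi)), sort(unname(m2$consensi)))
    expect_identical(sort(m1$families$unit_length),
                     sort(m2$families$unit_length))
  })
})

test_that("clusters recovered at low coverage carry their species tags", {
  spec <- make_mining_spec(n = 3L, genome_size = 1e6)
  tr <- synthesize_library(spec, seed = 31)
  rr <- generate_genome_reads(tr, "S1", coverage = 0.5, seed = 31)
  mm <- mine_satellites(rr$reads, species = rep("S1", rr$n_reads))
  expect_gte(nrow(mm$families), 2L)
  expect_identical(colnames(mm$species_hits), "S1")
  expect_identical(unname(rowSums(mm$species_hits)),
                   as.numeric(mm$families$n_reads))
  # cluster membership matches planted origin for >= 95% of clustered
  # reads; reads whose midpoint falls in flanking background (array
  # junction reads) are legitimate members and not counted against
  for (id in names(mm$clusters)) {
    cl <- mm$clusters[[id]]
    orig <- rr$origin[cl$members]
    sat <- orig[orig != "background"]
    expect_gte(max(table(sat)) / length(sat), 0.95)
  }
})
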