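# Synthetic-data generator: nested satDNA libraries across a species
# chain, low-coverage genomic reads and transcriptome libraries with a
# known active/passive split.  Everything is driven by a LibrarySpec and
# a single integer seed; identical seeds give byte-identical output.

#' Construct a satDNA library specification
#'
#' A `library_spec` describes a chain of species related by successive
#' hybridization and the satDNA families planted in their genomes.
#' Species order in `species` is the lineage (maternal recipient first);
#' each family carries an explicit presence signature, so nested subset
#' designs and planted losses are both expressed directly.
#'
#' @param species data.frame with columns `name`, `ploidy`,
#'   `genome_size` (bp), in lineage order.
#' @param families data.frame with columns `id`, `unit_length` (bp,
#'   20-500), `at_fraction` (0.5-0.9 by default), `divergence`
#'   (expected pairwise substitutions/site between species consensi,
#'   < 0.5), and `signature` (character, `+`-separated species names in
#'   which the family is present).
#' @param fractions numeric vector (per family, recycled across the
#'   species of its signature) or matrix (families x species) of genomic
#'   fractions (0-1). Per-species totals must stay below `max_total`.
#' @param losses optional data.frame (`id`, `species`) recording which
#'   absences are planted losses rather than never-gained families
#'   (bookkeeping only; the signature already reflects them).
#' @param stages character vector of life-stage labels.
#' @param activity matrix (families x stages) of transcription activity
#'   multipliers; 1 = passive (transcript fraction equals genomic
#'   fraction), values > 1 mark active transcription. Default all 1.
#' @param intra_divergence per-copy substitution rate within an array
#'   (intraspecific repeat variability).
#' @param background_at A+T fraction of the non-satellite genome.
#' @param n_background_genes,background_gene_length size of the
#'   transcriptome background gene pool (one gene is GAPDH-like and can
#'   serve as a reference).
#' @param at_limits,max_total validation bounds for `at_fraction` and
#'   per-species summed genomic fraction.
#' @return an object of class `library_spec`.
#' @export
library_spec <- function(species, families, fractions, losses = NULL,
                         stages = c("eggs", "J2", "J3", "J3J4", "female", "male"),
                         activity = NULL,
                         intra_divergence = 0.02,
                         background_at = 0.7,
                         n_background_genes = 50L,
                         background_gene_length = 1000L,
                         at_limits = c(0.5, 0.9),
                         max_total = 0.10) {
  stopifnot(is.data.frame(species),
            all(c("name", "ploidy", "genome_size") %in% names(species)),
            all(species$genome_size > 0),
            !anyDuplicated(species$name))
  stopifnot(is.data.frame(families),
            all(c("id", "unit_length", "at_fraction", "divergence",
                  "signature") %in% names(families)))
  if (anyDuplicated(families$id))
    stop("duplicate family ids in library spec")
  if (any(families$divergence >= 0.5))
    stop("interspecies divergence >= 0.5: consensus identity undefined")
  if (any(families$unit_length < 20 | families$unit_length > 500))
    stop("unit_length must lie in [20, 500]")
  if (any(families$at_fraction < at_limits[1] | families$at_fraction > at_limits[2]))
    stop("at_fraction outside allowed range")

  nf <- nrow(families); ns <- nrow(species)
  pres <- matrix(FALSE, nf, ns, dimnames = list(families$id, species$name))
  for (i in seq_len(nf)) {
    sp <- strsplit(families$signature[i], "+", fixed = TRUE)[[1]]
    if (!all(sp %in% species$name))
      stop("signature of family ", families$id[i], " names unknown species")
    pres[i, sp] <- TRUE
  }
  if (any(rowSums(pres) == 0L)) stop("family present in no species")

  if (is.matrix(fractions)) {
    frac <- fractions
    dimnames(frac) <- dimnames(pres)
  } else {
    stopifnot(length(fractions) == nf)
    frac <- matrix(rep(fractions, ns), nf, ns, dimnames = dimnames(pres))
  }
  frac[!pres] <- 0
  if (any(frac[pres] <= 0)) stop("present families need a positive genomic fraction")
  tot <- colSums(frac)
  if (any(tot >= max_total))
    stop("summed satDNA fraction reaches ", round(max(tot), 3),
         "; satellite DNA must stay a minor genome fraction (< ", max_total, ")")

  if (is.null(activity)) {
    activity <- matrix(1, nf, length(stages),
                       dimnames = list(families$id, stages))
  } else {
    stopifnot(nrow(activity) == nf, ncol(activity) == length(stages),
              all(activity >= 0))
    dimnames(activity) <- list(families$id, stages)
  }

  structure(list(species = species, families = families, presence = pres,
                 fractions = frac, losses = losses, stages = stages,
                 activity = activity, intra_divergence = intra_divergence,
                 background_at = background_at,
                 n_background_genes = as.integer(n_background_genes),
                 background_gene_length = as.integer(background_gene_length)),
            class = "library_spec")
}

#' Default study-condition library specification
#'
#' Four species related by two successive hybridizations on a maternal
#' chain (ploidy 2n, <3n, <4n, 4n), with a nested satDNA library: an
#' ancestral subset shared by all species, a second subset gained with
#' the first hybridization, a third gained with the second, plus one
#' species-specific family per derived species, and a few planted losses
#' in the intermediate species (the hypotriploid/hypotetraploid
#' signature). Unit lengths span 30-300 bp with modes at 50-90 and
#' 170-190 bp, A+T fractions lie in 0.70-0.80, genomic fractions decay
#' from 0.613% following a power law, and interspecies consensus
#' divergence is 2.7% for most families with a divergent tail up to 21%.
#'
#' @param n_shared sizes of the nested subsets: ancestral, gained at the
#'   first hybridization, gained at the second.
#' @param n_private number of species-specific families per species.
#' @param genome_scale multiplier applied to the full-scale genome sizes
#'   (100/189/297/304 Mb); use a small value for tractable simulations.
#' @param n_losses number of ancestral-set families lost in each of the
#'   two intermediate species.
#' @param stage_archetypes plant the four developmental activity
#'   archetypes (always-high, moderate-with-dropout, low,
#'   stage-restricted) on the first families of the catalog.
#' @param ... passed to [library_spec()].
#' @return a `library_spec`.
#' @export
default_library_spec <- function(n_shared = c(39L, 20L, 21L),
                                 n_private = c(0L, 1L, 1L, 1L),
                                 genome_scale = 1,
                                 n_losses = c(2L, 2L),
                                 stage_archetypes = TRUE, ...) {
  species <- data.frame(
    name = c("M1", "M2", "M3", "M4"),
    ploidy = c("2n", "<3n", "<4n", "4n"),
    genome_size = round(c(100e6, 189e6, 297e6, 304e6) * genome_scale))

  sig_for <- function(first) paste(species$name[first:4], collapse = "+")
  n_sub <- sum(n_shared)
  nf <- n_sub + sum(n_private)
  ids <- sprintf("Fam%02d", seq_len(nf))

  signature <- c(rep(sig_for(1), n_shared[1]),
                 rep(sig_for(2), n_shared[2]),
                 rep(sig_for(3), n_shared[3]),
                 unlist(lapply(1:4, function(i) rep(species$name[i], n_private[i]))))

  # unit lengths: 47/83-style concentration in 50-90 and 170-190 bp
  n_mode1 <- round(nf * 24 / 83); n_mode2 <- round(nf * 23 / 83)
  n_rest <- nf - n_mode1 - n_mode2
  lengths <- c(round(seq(50, 90, length.out = max(n_mode1, 1))),
               round(seq(170, 190, length.out = max(n_mode2, 1))),
               round(seq(30, 300, length.out = max(n_rest, 1))))
  lengths <- lengths[seq_len(nf)]
  # interleave so every subset carries the full length range
  lengths <- lengths[order(rep_len(seq_len(7), nf))]

  at <- rep_len(seq(0.70, 0.80, by = 0.01), nf)
  # power-law abundance decay: top family 0.613%, floor 0.002%. A
  # stride permutation interleaves abundance ranks across the nested
  # subsets, so each subset spans the abundance range as in real
  # comparative catalogs.
  stride <- 23L
  while (stride > 1L && nf %% stride == 0L) stride <- stride - 1L
  ranks <- ((seq_len(nf) - 1L) * stride) %% nf + 1L
  fractions <- pmax(0.00613 * ranks^-1.30, 2e-5)
  divergence <- rep(0.027, nf)
  divergence[seq_len(nf) %% 17 == 0] <- seq(0.10, 0.21,
                                            length.out = sum(seq_len(nf) %% 17 == 0))

  families <- data.frame(id = ids, unit_length = lengths, at_fraction = at,
                         divergence = divergence, signature = signature)

  # planted losses in the intermediate species, on abundant ancestral
  # families (losses of well-amplified satellites are the detectable
  # signature of genome reduction after hybridization)
  losses <- NULL
  anc <- which(signature == sig_for(1))
  pick <- anc[order(ranks[anc])][seq_len(sum(n_losses))]
  lost_m2 <- pick[seq_len(n_losses[1])]
  lost_m3 <- pick[n_losses[1] + seq_len(n_losses[2])]
  drop_species <- function(sig, sp) {
    parts <- setdiff(strsplit(sig, "+", fixed = TRUE)[[1]], sp)
    paste(parts, collapse = "+")
  }
  for (i in lost_m2) families$signature[i] <- drop_species(families$signature[i], "M2")
  for (i in lost_m3) families$signature[i] <- drop_species(families$signature[i], "M3")
  losses <- data.frame(id = c(ids[lost_m2], ids[lost_m3]),
                       species = c(rep("M2", length(lost_m2)),
                                   rep("M3", length(lost_m3))))

  stages <- c("eggs", "J2", "J3", "J3J4", "female", "male")
  activity <- matrix(1, nf, length(stages), dimnames = list(ids, stages))
  if (stage_archetypes) {
    # four archetype profiles on ancestral families (cluster I-IV analogues)
    arch <- list(always_high = rep(4, 6),
                 moderate_dropout = c(2, 2, 0, 2, 2, 0),
                 low = rep(0.25, 6),
                 stage_restricted = c(4, 0.25, 0.25, 0.25, 0.25, 4))
    targets <- anc[seq_len(min(12, length(anc)))]
    for (j in seq_along(targets))
      activity[targets[j], ] <- arch[[((j - 1) %% 4) + 1]]
  }

  library_spec(species, families, fractions, losses = losses,
               stages = stages, activity = activity, ...)
}

#' Synthesize per-species family consensi and the simulation truth
#'
#' Generates one ancestral consensus per family (random sequence at the
#' family's A+T fraction) and mutates it independently in each species
#' carrying the family at half the specified pairwise divergence, so the
#' expected divergence between two species consensi matches the spec.
#' Copy numbers are derived from the genomic fractions and genome sizes.
#'
#' @param spec a [library_spec()].
#' @param seed integer RNG seed; identical seeds give identical truth.
#' @return an object of class `sat_truth` with elements `spec`,
#'   `ancestral`, `consensi` (families x species character matrix, NA
#'   where absent), `copy_number`, `presence`, `genes` (background gene
#'   pool), `gene_weights` and `seed`.
#' @export
synthesize_library <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "library_spec"))
  fam <- spec$families
  nf <- nrow(fam); ns <- nrow(spec$species)
  withr::with_seed(as.integer(seed), {
    ancestral <- character(nf)
    consensi <- matrix(NA_character_, nf, ns,
                       dimnames = dimnames(spec$presence))
    for (i in seq_len(nf)) {
      ancestral[i] <- random_dna(fam$unit_length[i], fam$at_fraction[i])
      for (s in which(spec$presence[i, ])) {
        consensi[i, s] <- mutate_seq(ancestral[i], fam$divergence[i] / 2)
      }
    }
    genes <- stats::setNames(
      vapply(seq_len(spec$n_background_genes), function(i)
        random_dna(spec$background_gene_length, at = 0.55), ""),
      c("GAPDH_like",
        sprintf("gene%02d", seq_len(spec$n_background_genes - 1L))))
  })
  gw <- seq_len(spec$n_background_genes)^-0.7
  gw <- gw / sum(gw)
  copy_number <- round(spec$fractions *
                         matrix(rep(spec$species$genome_size, each = nf), nf) /
                         fam$unit_length)
  mode(copy_number) <- "integer"
  structure(list(spec = spec, ancestral = ancestral, consensi = consensi,
                 copy_number = copy_number, presence = spec$presence,
                 genes = genes, gene_weights = gw, seed = as.integer(seed)),
            class = "sat_truth")
}

#' Expected transcript fractions for a species and stage
#'
#' Passive model: a family's expected transcript fraction equals its
#' genomic fraction times its stage activity multiplier; the background
#' gene pool absorbs the remainder of the library.
#'
#' @param truth a `sat_truth`.
#' @param species species name.
#' @param stage stage label.
#' @return named numeric vector of per-family expected fractions
#'   (absent families 0).
#' @export
expected_transcript_fractions <- function(truth, species, stage) {
  spec <- truth$spec
  stopifnot(species %in% spec$species$name, stage %in% spec$stages)
  tf <- spec$fractions[, species] * spec$activity[, stage]
  tf[!truth$presence[, species]] <- 0
  if (sum(tf) >= 0.5)
    stop("satellite transcript fractions would dominate the library")
  tf
}

#' Simulate low-coverage genomic reads for one species
#'
#' Builds a genome mosaic with one contiguous tandem array per present
#' family (copies mutated at the intra-array rate) placed in random
#' order and separated by random background sequence, then draws
#' uniformly positioned single-end reads with uniform strand and
#' substitution errors.
#'
#' @param truth a `sat_truth` from [synthesize_library()].
#' @param species species name.
#' @param coverage fold genome coverage (> 0).
#' @param read_length read length in bp (>= 50).
#' @param error_rate per-base substitution error rate.
#' @param seed integer seed.
#' @param keep_genome also return the full genome mosaic string.
#' @return list with `reads` (named character vector), `start`,
#'   `strand`, `origin` (family id of the array containing the read
#'   midpoint, or "background"), `layout` (array coordinates),
#'   `species`, `n_reads`, and optionally `genome`.
#' @export
generate_genome_reads <- function(truth, species, coverage = 0.25,
                                  read_length = 100L, error_rate = 0.01,
                                  seed = 1L, keep_genome = FALSE) {
  stopifnot(inherits(truth, "sat_truth"), coverage > 0, read_length >= 50)
  spec <- truth$spec
  si <- match(species, spec$species$name)
  if (is.na(si)) stop("unknown species: ", species)
  G <- spec$species$genome_size[si]
  n_reads <- round(coverage * G / read_length)
  exp_sat <- spec$fractions[, si] * n_reads
  if (all(exp_sat[truth$presence[, si]] < 1))
    warning("coverage so low that expected satellite reads < 1 for every family")

  withr::with_seed(as.integer(seed), {
    present <- which(truth$presence[, si])
    arrays <- lapply(present, function(i) {
      paste(mutate_copies(truth$consensi[i, si], truth$copy_number[i, si],
                          spec$intra_divergence), collapse = "")
    })
    names(arrays) <- rownames(truth$presence)[present]
    ord <- sample(length(arrays))
    arrays <- arrays[ord]
    sat_bp <- sum(nchar(arrays))
    if (sat_bp >= G) stop("satellite arrays exceed genome size")
    bg_total <- G - sat_bp
    nseg <- length(arrays) + 1L
    gaps <- as.vector(rmultinom(1L, bg_total, rep(1, nseg)))
    background <- random_dna(bg_total, spec$background_at)
    bg_end <- cumsum(gaps)
    bg_start <- c(1L, head(bg_end, -1L) + 1L)
    pieces <- character(2L * length(arrays) + 1L)
    pieces[seq(1L, by = 2L, length.out = nseg)] <-
      substring(background, bg_start, bg_end)
    pieces[seq(2L, by = 2L, length.out = length(arrays))] <- unlist(arrays)
    genome <- paste(pieces, collapse = "")
    arr_len <- nchar(unlist(arrays))
    arr_start <- cumsum(gaps[seq_along(arrays)]) +
      c(0L, cumsum(head(arr_len, -1L))) + 1L
    layout <- data.frame(family = names(arrays), start = arr_start,
                         end = arr_start + arr_len - 1L)

    start <- sample.int(G - read_length + 1L, n_reads, replace = TRUE)
    reads <- substring(genome, start, start + read_length - 1L)
    minus <- sample(c(FALSE, TRUE), n_reads, replace = TRUE)
    reads[minus] <- revcomp(reads[minus])
    reads <- apply_read_errors(reads, error_rate)
    names(reads) <- sprintf("%s_r%06d", species, seq_len(n_reads))
  })

  mid <- start + read_length %/% 2L
  iv <- findInterval(mid, layout$start)
  origin <- rep("background", n_reads)
  inarr <- iv >= 1L & mid <= c(layout$end, 0L)[pmax(iv, 1L)]
  origin[inarr] <- layout$family[iv[inarr]]

  out <- list(reads = reads, start = start, strand = ifelse(minus, "-", "+"),
              origin = origin, layout = layout, species = species,
              n_reads = n_reads, read_length = as.integer(read_length),
              coverage = coverage, seed = as.integer(seed))
  if (keep_genome) out$genome <- genome
  out
}

#' Simulate a transcriptome library for one species and stage
#'
#' Read counts are multinomial over the planted families (expected
#' fraction = genomic fraction x stage multiplier) and a dominant
#' background gene pool absorbing the rest of the library. Family reads
#' are windows of monomer concatemers; passive families (multiplier 1)
#' therefore have expected log2(transcript fraction / genomic
#' fraction) = 0.
#'
#' @param truth a `sat_truth`.
#' @param species species name.
#' @param stage stage label (must exist in the spec).
#' @param library_size number of reads (> 0).
#' @param read_length read length (default 101, as in HiSeq libraries).
#' @param error_rate per-base substitution error rate.
#' @param seed integer seed.
#' @return list with `reads`, `counts` (true per-family read counts),
#'   `gene_counts`, `expected_fractions`, `species`, `stage`.
#' @export
generate_transcriptome_reads <- function(truth, species, stage,
                                         library_size = 1e5, read_length = 101L,
                                         error_rate = 0.002, seed = 1L) {
  stopifnot(inherits(truth, "sat_truth"), library_size > 0)
  spec <- truth$spec
  tf <- expected_transcript_fractions(truth, species, stage)
  gw <- truth$gene_weights * (1 - sum(tf))
  if (sum(tf) == 0 && length(truth$genes) == 0L)
    stop("no transcribable families and empty background gene pool")

  withr::with_seed(as.integer(seed), {
    counts <- as.vector(rmultinom(1L, library_size, c(tf, gw)))
    fam_counts <- stats::setNames(counts[seq_along(tf)], names(tf))
    gene_counts <- stats::setNames(counts[-seq_along(tf)], names(truth$genes))
    si <- match(species, spec$species$name)
    reads <- character(0)
    for (i in which(fam_counts > 0L)) {
      n_cop <- ceiling((2L * read_length) / spec$families$unit_length[i]) + 1L
      template <- paste(mutate_copies(truth$consensi[i, si], n_cop,
                                      spec$intra_divergence), collapse = "")
      st <- sample.int(nchar(template) - read_length + 1L, fam_counts[i],
                       replace = TRUE)
      rd <- substring(template, st, st + read_length - 1L)
      minus <- sample(c(FALSE, TRUE), length(rd), replace = TRUE)
      rd[minus] <- revcomp(rd[minus])
      reads <- c(reads, rd)
    }
    for (g in which(gene_counts > 0L)) {
      gl <- nchar(truth$genes[g])
      st <- sample.int(max(gl - read_length + 1L, 1L), gene_counts[g],
                       replace = TRUE)
      reads <- c(reads, substring(truth$genes[g], st,
                                  pmin(st + read_length - 1L, gl)))
    }
    reads <- apply_read_errors(reads, error_rate)
    reads <- reads[sample(length(reads))]
    names(reads) <- sprintf("%s_%s_t%06d", species, stage, seq_along(reads))
  })

  list(reads = reads, counts = fam_counts, gene_counts = gene_counts,
       expected_fractions = tf, species = species, stage = stage,
       library_size = as.integer(library_size), seed = as.integer(seed))
}
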