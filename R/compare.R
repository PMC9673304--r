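# Cross-species satellitome comparison: coverage-matched pooling of
# species read sets, co-clustering, abundance/presence matrices, catalog
# naming by decreasing comparative abundance, and variant grouping by
# the >65% identity rule.

#' Pool coverage-matched subsamples from per-species read sets
#'
#' Draws `round(coverage x genome_size / read_length)` reads per species
#' without replacement (seeded) so every species contributes the same
#' genome coverage, and pools them with species tags retained.
#'
#' @param readsets named list of per-species read vectors.
#' @param coverage fold coverage (> 0).
#' @param genome_sizes named numeric vector of genome sizes (bp).
#' @param read_length read length; inferred from the reads if missing.
#' @param seed integer seed.
#' @return list with `reads` (pooled character vector), `species`
#'   (per-read tags), `n_per_species`.
#' @export
pool_subsamples <- function(readsets, coverage, genome_sizes,
                            read_length = NULL, seed = 1L) {
  stopifnot(is.list(readsets), length(readsets) >= 1L, coverage > 0)
  spp <- names(readsets)
  stopifnot(!is.null(spp), all(spp %in% names(genome_sizes)))
  if (is.null(read_length)) read_length <- nchar(readsets[[1]][1])
  need <- round(coverage * genome_sizes[spp] / read_length)
  have <- vapply(readsets, length, 1L)
  if (any(need > have)) {
    bad <- spp[need > have]
    stop("insufficient reads for requested coverage; deficits: ",
         paste(sprintf("%s (need %d, have %d)", bad, need[bad], have[bad]),
               collapse = ", "))
  }
  withr::with_seed(as.integer(seed), {
    picks <- lapply(spp, function(s) sort(sample.int(have[s], need[s])))
  })
  names(picks) <- spp
  reads <- unlist(lapply(spp, function(s) readsets[[s]][picks[[s]]]),
                  use.names = TRUE)
  species <- rep(spp, need[spp])
  list(reads = reads, species = species, n_per_species = need[spp],
       picks = picks)
}

#' Genomic abundance of a cluster
#'
#' @param hits number of reads contributing to the cluster.
#' @param total_reads number of reads analyzed.
#' @return abundance as a percentage of the genome.
#' @export
compute_abundance <- function(hits, total_reads) {
  stopifnot(total_reads > 0, hits >= 0)
  if (any(hits > total_reads)) stop("hits exceed total reads")
  100 * hits / total_reads
}

#' Presence call from a hit count
#'
#' @param hits read hit count (>= 0).
#' @param threshold detection threshold (default 10 hits, inclusive).
#' @return logical presence.
#' @export
call_presence <- function(hits, threshold = 10L) {
  stopifnot(all(hits >= 0))
  hits >= threshold
}

#' Copy-number estimate from genomic fraction
#'
#' @param abundance_fraction genomic fraction (0-1, not percent).
#' @param genome_size genome size in bp.
#' @param unit_length repeat-unit length in bp (> 0).
#' @return estimated copy number (rounded to the nearest integer).
#' @export
estimate_copy_number <- function(abundance_fraction, genome_size,
                                 unit_length) {
  stopifnot(unit_length > 0)
  round(abundance_fraction * genome_size / unit_length)
}

#' Name catalog families by decreasing comparative abundance
#'
#' Families are numbered `Sat01`, `Sat02`, ... by decreasing total
#' pooled abundance; ties are broken by larger unit length, then by the
#' lexicographic canonical consensus. A secondary `display_order` groups
#' families by shared appearance from smaller to larger genomes.
#'
#' @param abundance families x species matrix of abundances (%).
#' @param unit_lengths per-family unit lengths.
#' @param consensi per-family consensus sequences.
#' @param genome_sizes named per-species genome sizes (bp), used only
#'   for the display grouping; column order is used when missing.
#' @return data.frame with `catalog_id`, `family` (input rowname),
#'   `total_abundance`, `unit_length`, `display_order`, in catalog
#'   order.
#' @export
catalog_families <- function(abundance, unit_lengths, consensi,
                             genome_sizes = NULL) {
  stopifnot(is.matrix(abundance), nrow(abundance) >= 1L)
  fam <- rownames(abundance)
  if (is.null(fam)) fam <- paste0("fam", seq_len(nrow(abundance)))
  total <- rowSums(abundance)
  canon <- vapply(consensi, function(s)
    canonical_rotation(s, strict = !grepl("[^ACGT]", s)), "")
  ord <- order(-total, -unit_lengths, canon)
  width <- max(2L, nchar(length(fam)))
  out <- data.frame(catalog_id = sprintf(paste0("Sat%0", width, "d"),
                                         seq_along(fam)),
                    family = fam[ord],
                    total_abundance = total[ord],
                    unit_length = unit_lengths[ord],
                    stringsAsFactors = FALSE)
  # display grouping: smallest genome in which the family appears, then
  # breadth of sharing, then abundance
  gs <- genome_sizes
  if (is.null(gs)) gs <- stats::setNames(seq_len(ncol(abundance)),
                                         colnames(abundance))
  sp_small <- colnames(abundance)[order(gs[colnames(abundance)])]
  pres <- abundance[ord, sp_small, drop = FALSE] > 0
  first_sp <- apply(pres, 1L, function(p) which(p)[1])
  breadth <- rowSums(pres)
  out$display_order <- order(order(first_sp, -breadth, -out$total_abundance))
  rownames(out) <- NULL
  out
}

#' Group satellite variants by the >65% identity rule
#'
#' All consensus sequences are compared pairwise with rotation- and
#' strand-aware global-alignment identity; variant groups are the
#' connected components of the "identity strictly above `min_identity`"
#' relation. Singleton families are not reported.
#'
#' @param consensi named character vector of consensus sequences
#'   (>= 2).
#' @param min_identity identity cutoff in percent (default 65; the rule
#'   is strict `>`).
#' @return list of variant groups, each a list with `members` (names)
#'   and `min_pairwise_identity`; empty list when no multi-member group
#'   exists.
#' @export
group_variants <- function(consensi, min_identity = 65) {
  stopifnot(length(consensi) >= 2L)
  ids <- names(consensi)
  if (is.null(ids)) ids <- paste0("fam", seq_along(consensi))
  n <- length(consensi)
  idm <- matrix(100, n, n, dimnames = list(ids, ids))
  lens <- nchar(consensi)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    # identity is at most min(len)/max(len): matches cannot exceed the
    # shorter sequence and alignment columns are at least the longer
    bound <- 100 * min(lens[i], lens[j]) / max(lens[i], lens[j])
    idm[i, j] <- idm[j, i] <- if (bound <= min_identity) bound else
      pairwise_identity(consensi[[i]], consensi[[j]], circular = TRUE)
  }
  adj <- which(idm > min_identity & upper.tri(idm), arr.ind = TRUE)
  if (nrow(adj) == 0L) return(list())
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[adj[, 1]], to = ids[adj[, 2]]),
    directed = FALSE, vertices = ids)
  comp <- igraph::components(g)
  groups <- split(ids, comp$membership)
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  out <- lapply(groups, function(m) {
    sub <- idm[m, m, drop = FALSE]
    list(members = sort(m),
         min_pairwise_identity = min(sub[upper.tri(sub)]))
  })
  unname(out[order(-vapply(out, function(g) length(g$members), 1L),
                   vapply(out, function(g) g$members[1], ""))])
}

#' Comparative satellitome analysis across species
#'
#' Runs the full cross-species comparison: coverage-matched pooling,
#' co-mining of the pooled tagged reads, per-species hit attribution
#' (each read contributes to exactly one cluster), abundance and
#' presence matrices, catalog naming, species-specific consensus
#' rebuilding and variant grouping.
#'
#' @param readsets named list of per-species read vectors.
#' @param genome_sizes named per-species genome sizes (bp).
#' @param coverage fold coverage for the pooled analysis (default
#'   0.25).
#' @param threshold presence detection threshold in hits (default 10).
#' @param variant_identity identity cutoff (%) for variant grouping.
#' @param seed integer seed for the subsampling.
#' @param per_species_consensus rebuild a species-specific consensus
#'   from each species' member reads (pooled consensus reported, with a
#'   flag, when a species has fewer than 3 member reads).
#' @param ... mining parameters passed to [mine_satellites()].
#' @return object of class `satellitome_comparison`: `catalog`,
#'   `abundance` and `presence` and `hits` matrices (catalog order),
#'   `consensi` (pooled, catalog-named), `species_consensi` (matrix,
#'   NA where unsupported), `variant_groups`, `mining`, `params`.
#' @export
compare_satellitomes <- function(readsets, genome_sizes, coverage = 0.25,
                                 threshold = 10L, variant_identity = 65,
                                 seed = 1L, per_species_consensus = TRUE,
                                 ...) {
  pooled <- pool_subsamples(readsets, coverage, genome_sizes, seed = seed)
  mining <- mine_satellites(pooled$reads, species = pooled$species, ...)
  fams <- mining$families
  if (nrow(fams) == 0L)
    stop("no satellite families recovered from the pooled reads")
  hits <- mining$species_hits
  spp <- colnames(hits)
  totals <- pooled$n_per_species[spp]
  abundance <- sweep(hits, 2L, totals, function(h, t) 100 * h / t)
  presence <- hits >= threshold

  cat_df <- catalog_families(abundance, fams$unit_length, mining$consensi,
                             genome_sizes = genome_sizes[spp])
  ord <- match(cat_df$family, rownames(hits))
  relabel <- function(m) {
    m <- m[ord, , drop = FALSE]
    rownames(m) <- cat_df$catalog_id
    m
  }
  hits <- relabel(hits); abundance <- relabel(abundance)
  presence <- relabel(presence)
  consensi <- stats::setNames(mining$consensi[ord], cat_df$catalog_id)

  species_consensi <- NULL
  if (per_species_consensus) {
    species_consensi <- matrix(NA_character_, nrow(cat_df), length(spp),
                               dimnames = list(cat_df$catalog_id, spp))
    sp_flag <- species_consensi
    for (i in seq_len(nrow(cat_df))) {
      cl <- mining$clusters[[cat_df$family[i]]]
      period <- nchar(consensi[i])
      for (s in spp) {
        mem <- cl$members[pooled$species[cl$members] == s]
        if (length(mem) >= 3L) {
          rec <- tryCatch(
            derive_consensus(unname(pooled$reads[mem]), period),
            error = function(e) NULL)
          if (!is.null(rec) && rec$unit_length == period) {
            species_consensi[i, s] <- rec$sequence
            next
          }
        }
        if (presence[i, s]) species_consensi[i, s] <- consensi[i]
        sp_flag[i, s] <- "pooled"
      }
    }
    attr(species_consensi, "flag") <- sp_flag
  }

  variant_groups <- if (nrow(cat_df) >= 2L)
    group_variants(consensi, min_identity = variant_identity) else list()

  structure(list(catalog = cat_df, abundance = abundance,
                 presence = presence, hits = hits, consensi = consensi,
                 species_consensi = species_consensi,
                 variant_groups = variant_groups, mining = mining,
                 params = list(coverage = coverage, threshold = threshold,
                               variant_identity = variant_identity,
                               seed = seed,
                               n_per_species = pooled$n_per_species)),
            class = "satellitome_comparison")
}

#' Match a recovered catalog to simulation truth
#'
#' Each recovered consensus is assigned to the best-matching planted
#' family by circular strand-aware identity; used to validate mining
#' and comparison results against a `sat_truth`.
#'
#' @param consensi named character vector of recovered consensi.
#' @param truth a `sat_truth`.
#' @param min_identity minimum identity (%) for a match.
#' @return data.frame `family` (recovered), `truth_id`, `identity`,
#'   `length_ratio` (recovered unit length / planted unit length).
#' @export
match_catalog_to_truth <- function(consensi, truth, min_identity = 80) {
  stopifnot(inherits(truth, "sat_truth"))
  planted <- truth$ancestral
  names(planted) <- truth$spec$families$id
  out <- lapply(seq_along(consensi), function(i) {
    # compare against planted units of compatible length only
    lr <- nchar(consensi[i]) / nchar(planted)
    cand <- which(abs(lr - round(lr)) < 0.12 & round(lr) >= 1)
    if (!length(cand)) cand <- seq_along(planted)
    ids <- vapply(cand, function(j) {
      mult <- max(1, round(nchar(consensi[i]) / nchar(planted[j])))
      # best identity to any planted per-species consensus (the actual
      # read templates); the ancestral unit is a fallback
      refs <- stats::na.omit(c(truth$consensi[j, ], planted[j]))
      max(vapply(refs, function(rf)
        pairwise_identity(consensi[i], strrep(rf, mult), circular = TRUE),
        0))
    }, 0)
    best <- cand[which.max(ids)]
    data.frame(family = names(consensi)[i],
               truth_id = names(planted)[best],
               identity = max(ids),
               length_ratio = nchar(consensi[i]) / nchar(planted[best]))
  })
  res <- do.call(rbind, out)
  res[res$identity >= min_identity, , drop = FALSE]
}
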