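# Pipeline orchestration: configuration, stage sequencing with
# stage-derived seeds, TSV/JSON/FASTA outputs with checksums, and the
# coverage sweep.

#' Build a pipeline configuration
#'
#' @param species data.frame with `name`, `ploidy`, `genome_size` (and
#'   optionally per-species FASTQ paths in a `reads` column; when
#'   absent the simulation stage generates reads).
#' @param outdir output directory.
#' @param coverage pooled analysis coverage (default 0.25).
#' @param threshold_hits presence detection threshold.
#' @param variant_identity variant-grouping identity cutoff (%).
#' @param k_clusters stage-clustering group count.
#' @param seed master seed; per-stage streams are derived from it.
#' @param library_spec optional `library_spec` for the simulation stage
#'   (a default spec scaled to the configured genome sizes otherwise).
#' @param read_length genomic read length.
#' @param transcriptome_size reads per simulated transcriptome library.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(species, outdir, coverage = 0.25,
                            threshold_hits = 10L, variant_identity = 65,
                            k_clusters = 4L, seed = 1L,
                            library_spec = NULL, read_length = 100L,
                            transcriptome_size = 5e4) {
  stopifnot(is.data.frame(species),
            all(c("name", "ploidy", "genome_size") %in% names(species)),
            coverage > 0)
  if ("reads" %in% names(species)) {
    missing <- species$reads[!file.exists(species$reads)]
    if (length(missing))
      stop("configured read files not found: ",
           paste(missing, collapse = ", "))
  }
  structure(list(species = species, outdir = outdir, coverage = coverage,
                 threshold_hits = as.integer(threshold_hits),
                 variant_identity = variant_identity,
                 k_clusters = as.integer(k_clusters),
                 seed = as.integer(seed), library_spec = library_spec,
                 read_length = as.integer(read_length),
                 transcriptome_size = as.integer(transcriptome_size)),
            class = "pipeline_config")
}

#' Demo pipeline configuration
#'
#' Three species with 5-Mb-scale genomes and a 12-family nested library
#' (6 ancestral, 4 gained, 2 private), sized so a full run completes in
#' minutes.
#'
#' @param outdir output directory.
#' @param seed master seed.
#' @return a `pipeline_config`.
#' @export
demo_config <- function(outdir = tempfile("satcomp_demo"), seed = 1L) {
  species <- data.frame(name = c("M1", "M2", "M3"),
                        ploidy = c("2n", "3n", "4n"),
                        genome_size = c(4e6, 5e6, 6e6))
  fam <- data.frame(
    id = sprintf("Fam%02d", 1:12),
    unit_length = c(60, 172, 85, 180, 45, 120, 75, 250, 90, 60, 150, 35),
    at_fraction = rep(c(0.72, 0.76, 0.80), 4),
    divergence = rep(0.027, 12),
    signature = c(rep("M1+M2+M3", 6), rep("M2+M3", 4), "M2", "M3"))
  fractions <- 0.006 * seq_len(12)^-0.9
  spec <- library_spec(species, fam, fractions)
  pipeline_config(species, outdir, seed = seed, library_spec = spec)
}

# deterministic per-stage seed stream derived from the master seed
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}

.write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", names(provenance), " = ",
                      unlist(provenance)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full satellitome pipeline
#'
#' Executes simulate (when no read paths are configured), mine/compare,
#' history, expression and features stages, writing TSV/JSON/FASTA
#' outputs under the configured directory. Each stage draws its
#' randomness from a stream derived from the master seed and the stage
#' name, so reruns with an identical configuration are byte-identical
#' and stages can be reasoned about independently.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run (dependencies must have run
#'   before, or their outputs are recomputed).
#' @return object of class `run_report`: per-stage outputs, parameter
#'   echo and md5 checksums of every file written.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "compare", "history",
                                    "expression", "features")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  report <- list(config = config[setdiff(names(config), "library_spec")])
  spp <- config$species$name
  gsz <- stats::setNames(config$species$genome_size, spp)

  # --- simulate ---------------------------------------------------------
  readsets <- NULL; truth <- NULL
  if ("reads" %in% names(config$species)) {
    readsets <- lapply(stats::setNames(config$species$reads, spp), read_fastq)
  } else if ("simulate" %in% stages) {
    spec <- config$library_spec
    if (is.null(spec))
      spec <- default_library_spec(
        genome_scale = mean(gsz) / mean(c(100e6, 189e6, 297e6, 304e6)))
    truth <- synthesize_library(spec, seed = stage_seed(config$seed, "simulate"))
    simdir <- file.path(config$outdir, "sim")
    dir.create(simdir, showWarnings = FALSE)
    readsets <- list()
    for (s in truth$spec$species$name) {
      rr <- generate_genome_reads(truth, s, coverage = config$coverage * 1.2,
                                  read_length = config$read_length,
                                  seed = stage_seed(config$seed,
                                                    paste0("reads_", s)))
      readsets[[s]] <- rr$reads
      f <- file.path(simdir, paste0(s, ".fastq"))
      write_fastq(rr$reads, f)
      files <- c(files, f)
    }
    f <- file.path(simdir, "truth.tsv")
    .write_tsv(data.frame(family = truth$spec$families$id,
                          truth$spec$fractions), f)
    files <- c(files, f)
    spp <- truth$spec$species$name
    gsz <- stats::setNames(truth$spec$species$genome_size, spp)
  }
  if (is.null(readsets)) stop("no reads available: configure paths or enable simulate")

  # --- compare (mining + matrices) -------------------------------------
  cmp <- compare_satellitomes(readsets, gsz, coverage = config$coverage,
                              threshold = config$threshold_hits,
                              variant_identity = config$variant_identity,
                              seed = stage_seed(config$seed, "compare"))
  prov <- list(coverage = config$coverage, threshold = config$threshold_hits,
               seed = config$seed)
  f1 <- file.path(config$outdir, "abundance.tsv")
  .write_tsv(data.frame(family = rownames(cmp$abundance),
                        round(cmp$abundance, 3)), f1, prov)
  f2 <- file.path(config$outdir, "presence.tsv")
  .write_tsv(data.frame(family = rownames(cmp$presence),
                        1L * cmp$presence), f2, prov)
  f3 <- file.path(config$outdir, "catalog.fasta")
  write_fasta(stats::setNames(cmp$consensi, sprintf(
    "%s|len=%d|AT=%.2f", names(cmp$consensi),
    nchar(cmp$consensi),
    vapply(cmp$consensi, at_content, 0) / 100)), f3)
  f4 <- file.path(config$outdir, "variant_groups.tsv")
  vg <- if (length(cmp$variant_groups))
    data.frame(group = rep(seq_along(cmp$variant_groups),
                           vapply(cmp$variant_groups,
                                  function(g) length(g$members), 1L)),
               family = unlist(lapply(cmp$variant_groups, `[[`, "members")))
  else data.frame(group = integer(0), family = character(0))
  .write_tsv(vg, f4, list(variant_identity = config$variant_identity))
  files <- c(files, f1, f2, f3, f4)
  report$compare <- list(n_families = nrow(cmp$catalog))

  # --- history ----------------------------------------------------------
  hist <- NULL
  if ("history" %in% stages && ncol(cmp$presence) >= 2L) {
    part <- partition_by_signature(cmp$presence)
    hist <- infer_history(part, species_order_hint = spp)
    f <- file.path(config$outdir, "history.json")
    jsonlite::write_json(list(chain = hist$chain,
                              n_events = hist$n_events,
                              gains = hist$gains,
                              losses = hist$losses,
                              total_losses = hist$total_losses,
                              homoplasy = hist$homoplasy),
                         f, auto_unbox = TRUE, pretty = TRUE)
    f2 <- file.path(config$outdir, "signatures.tsv")
    .write_tsv(data.frame(signature = names(part$counts),
                          n_families = as.integer(part$counts)), f2)
    files <- c(files, f, f2)
    report$history <- list(chain = hist$chain, n_events = hist$n_events)
  }

  # --- expression -------------------------------------------------------
  if ("expression" %in% stages && !is.null(truth)) {
    refs <- lapply(seq_along(cmp$consensi), function(i)
      prepare_reference(cmp$consensi[[i]], read_length = 101L,
                        family = names(cmp$consensi)[i]))
    libs <- list()
    for (s in spp) {
      tr <- generate_transcriptome_reads(
        truth, s, stage = "J2", library_size = config$transcriptome_size,
        seed = stage_seed(config$seed, paste0("rna_", s)))
      libs[[s]] <- tr$reads
    }
    absent <- !cmp$presence[, spp, drop = FALSE]
    em <- expression_matrix(libs, refs, background = truth$genes,
                            absent = absent)
    f <- file.path(config$outdir, "rpkm.tsv")
    .write_tsv(data.frame(family = rownames(em$rpkm), round(em$rpkm, 3)), f)
    files <- c(files, f)
    # activity ratios on estimated genomic fractions
    ratios <- matrix(NA_real_, nrow(em$hits), length(spp),
                     dimnames = list(rownames(em$hits), spp))
    for (s in spp) {
      gf <- cmp$abundance[, s] / 100
      tf <- em$hits[, s] / em$total_mapped[s]
      ok <- !is.na(tf) & gf > 0
      ratios[ok, s] <- activity_ratio(tf[ok], gf[ok])
    }
    act <- call_active(ratios)
    f <- file.path(config$outdir, "activity.tsv")
    .write_tsv(data.frame(family = rownames(ratios), round(ratios, 3),
                          candidate = act$table$candidate,
                          cross_species_active = act$table$cross_species_active),
               f)
    files <- c(files, f)
    report$expression <- list(n_candidates = length(act$candidates))
  }

  # --- features ---------------------------------------------------------
  if ("features" %in% stages) {
    cons <- cmp$consensi
    feat <- data.frame(family = names(cons),
                       unit_length = nchar(cons),
                       at_percent = round(vapply(cons, at_content, 0), 1))
    box <- cenpb_box()
    feat$cenpb_box_hits <- vapply(cons, function(s)
      nrow(motif_scan(disambiguate(s), box)), 1L)
    f <- file.path(config$outdir, "features.tsv")
    .write_tsv(feat, f)
    files <- c(files, f)
    report$features <- list(n_with_cenpb_like = sum(feat$cenpb_box_hits > 0))
  }

  report$files <- data.frame(path = files,
                             md5 = unname(tools::md5sum(files)))
  f <- file.path(config$outdir, "run_report.json")
  jsonlite::write_json(list(
    parameters = list(coverage = config$coverage,
                      threshold_hits = config$threshold_hits,
                      variant_identity = config$variant_identity,
                      seed = config$seed),
    stages = stages,
    files = report$files), f, auto_unbox = TRUE, pretty = TRUE)
  report$comparison <- cmp
  report$history_result <- hist
  structure(report, class = "run_report")
}

#' Mining yield across genome coverages
#'
#' Repeats subsampling and mining at each coverage on fresh subsamples
#' of the same read sets and reports recovered family counts — the
#' coverage-selection diagnostic run before committing to a working
#' coverage.
#'
#' @param readsets named list of per-species read vectors.
#' @param genome_sizes named per-species genome sizes.
#' @param coverages at least two positive fold-coverages.
#' @param seed integer seed.
#' @param ... mining parameters passed to [mine_satellites()].
#' @return data.frame `coverage`, `n_families`.
#' @export
coverage_sweep <- function(readsets, genome_sizes,
                           coverages = c(0.125, 0.25, 0.5), seed = 1L,
                           ...) {
  stopifnot(length(coverages) >= 2L)
  if (any(coverages <= 0)) stop("coverages must be positive")
  out <- lapply(seq_along(coverages), function(i) {
    pooled <- pool_subsamples(readsets, coverages[i], genome_sizes,
                              seed = seed + i)
    mm <- mine_satellites(pooled$reads, species = pooled$species, ...)
    data.frame(coverage = coverages[i], n_families = nrow(mm$families))
  })
  do.call(rbind, out)
}
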