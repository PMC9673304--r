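# satDNA transcription profiling: concatemer mapping references,
# best-hit read assignment, RPKM, log profiles, the
# transcription-to-genome activity ratio, active-family calls, Pearson
# correlation of profiles and stage clustering.

#' Build a concatemer mapping reference for a monomer
#'
#' Units shorter than 50 bp are concatenated until the reference
#' reaches 100 bp; units of 50 bp or more are concatenated until the
#' reference is at least `unit_length + read_length` so
#' junction-spanning reads map fully.
#'
#' @param consensus a `consensus_record` or a single sequence.
#' @param read_length library read length in bp.
#' @param family optional family id (taken from names otherwise).
#' @return object of class `mapping_reference`: `family`, `sequence`,
#'   `unit_length`, `copies`.
#' @export
prepare_reference <- function(consensus, read_length, family = NULL) {
  if (inherits(consensus, "consensus_record")) {
    seqc <- consensus$sequence
  } else {
    seqc <- as.character(consensus)
  }
  unit_length <- nchar(seqc)
  stopifnot(unit_length >= 20L)
  seqc <- disambiguate(toupper(seqc))
  target <- if (unit_length < 50L) 100L else unit_length + read_length
  copies <- ceiling(target / unit_length)
  structure(list(family = if (is.null(family)) NA_character_ else family,
                 sequence = strrep(seqc, copies),
                 unit_length = as.integer(unit_length),
                 copies = as.integer(copies)),
            class = "mapping_reference")
}

# forward-strand k-mer index over a set of references
.reference_index <- function(seqs, k) {
  parts <- lapply(seq_along(seqs), function(i) {
    d <- seq_kmer_codes(seqs[[i]], k)
    d[, ref := i]
    d
  })
  idx <- data.table::rbindlist(parts)
  data.table::setkey(idx, code)
  idx
}

# per-read k-mer anchors on both orientations: for "+" the forward code
# at read position pos; for "-" the code of the reverse-complemented
# k-mer, positioned within revcomp(read). Anchors are taken every
# `stride` positions; seed-and-vote assignment does not need every
# window.
.read_anchor_dt <- function(reads, k, stride = 1L) {
  m <- encode_reads(reads)
  L <- nrow(m); n <- ncol(m)
  if (L < k) stop("reads shorter than k")
  W <- L - k + 1L
  pow <- 4^(k - 1)
  f <- rep(0, n); r <- rep(0, n)
  for (j in seq_len(k)) f <- f * 4 + m[j, ]
  for (j in rev(seq_len(k))) r <- r * 4 + (3 - m[j, ])
  Fm <- matrix(0, W, n); Rm <- matrix(0, W, n)
  Fm[1L, ] <- f; Rm[1L, ] <- r
  if (W > 1L) for (w in 2:W) {
    jn <- w + k - 1L
    f <- (f %% pow) * 4 + m[jn, ]
    r <- (r - (3 - m[w - 1L, ])) / 4 + (3 - m[jn, ]) * pow
    Fm[w, ] <- f; Rm[w, ] <- r
  }
  keep <- seq(1L, W, by = stride)
  Fm <- Fm[keep, , drop = FALSE]; Rm <- Rm[keep, , drop = FALSE]
  rd <- rep(seq_len(n), each = length(keep))
  w <- rep(keep, n)
  data.table::rbindlist(list(
    data.table::data.table(read = rd, code = as.vector(Fm), pos = w,
                           orient = "+"),
    data.table::data.table(read = rd, code = as.vector(Rm),
                           pos = W - w + 1L, orient = "-")))
}

#' Map reads to satellite references by best hit
#'
#' Reads are assigned by seed k-mers (both strands) followed by an
#' ungapped identity check at the anchored offset; each read counts
#' once, for its best reference, with ties resolved toward the lowest
#' catalog position. Reads below `min_identity` stay unassigned. A
#' `background` reference set (e.g. the gene pool) competes for reads
#' and contributes to the mapped-read total without producing family
#' hits.
#'
#' @param reads character vector of uniform-length reads.
#' @param references list of [prepare_reference()] objects (or named
#'   character vector of reference sequences), in catalog order.
#' @param background optional named character vector of background
#'   reference sequences.
#' @param min_identity minimum ungapped identity (%) over the read.
#' @param k seed k-mer size.
#' @param min_votes minimum seed k-mer hits before a read is scored.
#' @param stride spacing between seed k-mer positions along each read.
#' @return list with `counts` (per-family hits), `background_hits`,
#'   `total_mapped` (satellite + background assignments), `unassigned`.
#' @export
map_reads <- function(reads, references, background = NULL,
                      min_identity = 80, k = 13L, min_votes = 2L,
                      stride = 3L) {
  if (length(references) == 0L) stop("empty reference set")
  if (inherits(references, "mapping_reference"))
    references <- list(references)
  if (is.character(references)) {
    references <- lapply(seq_along(references), function(i)
      structure(list(family = names(references)[i],
                     sequence = references[[i]],
                     unit_length = nchar(references[[i]])),
                class = "mapping_reference"))
  }
  fam_ids <- vapply(references, function(r)
    if (is.na(r$family)) "ref" else r$family, "")
  fam_ids <- make.unique(fam_ids)
  seqs <- lapply(references, `[[`, "sequence")
  nsat <- length(seqs)
  if (!is.null(background)) seqs <- c(seqs, as.list(background))
  idx <- .reference_index(seqs, k)

  counts <- stats::setNames(integer(nsat), fam_ids)
  if (length(reads) == 0L)
    return(list(counts = counts, background_hits = 0L, total_mapped = 0L,
                unassigned = 0L))

  anchors <- .read_anchor_dt(unname(reads), k, stride = stride)
  hits <- idx[anchors, on = "code", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L)
    return(list(counts = counts, background_hits = 0L, total_mapped = 0L,
                unassigned = length(reads)))
  # pos = reference position of the seed, i.pos = read position
  hits[, offset := pos - i.pos]
  vt <- hits[, .(votes = .N), by = .(read, ref, orient, offset)]
  data.table::setorder(vt, read, -votes, ref, orient, offset)
  best <- vt[vt[, .I[1], by = read]$V1]
  best <- best[votes >= min_votes]
  if (nrow(best) == 0L)
    return(list(counts = counts, background_hits = 0L, total_mapped = 0L,
                unassigned = length(reads)))

  rl <- nchar(reads[1])
  refchar <- vapply(seqs, identity, "")
  reflen <- nchar(refchar)
  oriented <- character(nrow(best))
  plus <- best$orient == "+"
  oriented[plus] <- reads[best$read[plus]]
  if (any(!plus)) oriented[!plus] <- revcomp(reads[best$read[!plus]])
  d <- best$offset
  s1 <- pmax(1L, d + 1L)
  e1 <- pmin(reflen[best$ref], d + rl)
  asub <- substr(oriented, s1 - d, e1 - d)
  bsub <- substring(refchar[best$ref], s1, e1)
  ident <- numeric(nrow(best))
  for (i in seq_len(nrow(best))) {
    span <- e1[i] - s1[i] + 1L
    ident[i] <- if (span < k) 0 else
      ungapped_identity(asub[i], bsub[i]) * span / rl
  }
  pass <- ident * 100 >= min_identity
  assigned <- best$ref[pass]
  sat <- assigned[assigned <= nsat]
  if (length(sat)) {
    tb <- tabulate(sat, nbins = nsat)
    counts <- counts + as.integer(tb)
  }
  bg_hits <- sum(assigned > nsat)
  list(counts = counts, background_hits = bg_hits,
       total_mapped = sum(counts) + bg_hits,
       unassigned = length(reads) - length(assigned))
}

#' RPKM of a satellite family
#'
#' Reads per kilobase of repeat unit per million mapped reads:
#' `hits / (total_mapped/1e6) / (unit_length/1000)`. Normalization uses
#' the single-unit length, never the concatenated reference length.
#'
#' @param hits satellite hit count.
#' @param total_mapped total mapped reads in the library (> 0).
#' @param unit_length repeat-unit length in bp (> 0).
#' @return RPKM value.
#' @export
#' @examples
#' rpkm(100, 1e6, 100)  # 1000
rpkm <- function(hits, total_mapped, unit_length) {
  stopifnot(total_mapped > 0)
  if (any(unit_length <= 0)) stop("unit_length must be positive")
  hits / (total_mapped / 1e6) / (unit_length / 1000)
}

#' Build an expression matrix over libraries
#'
#' Maps each library against the satellite references (plus the
#' background pool), and records hits and RPKM per family; cells for
#' families absent from a species genome are masked (`NA`).
#'
#' @param libraries named list of read vectors (one per library).
#' @param references list of [prepare_reference()] objects in catalog
#'   order.
#' @param background optional background reference sequences.
#' @param absent optional families x libraries logical mask of
#'   genome-absent cells.
#' @param ... passed to [map_reads()].
#' @return object of class `expression_matrix`: `hits`, `rpkm`,
#'   `log2rpkm` matrices (families x libraries), `total_mapped` per
#'   library, `mask`.
#' @export
expression_matrix <- function(libraries, references, background = NULL,
                              absent = NULL, ...) {
  fam_ids <- vapply(references, `[[`, "", "family")
  units <- vapply(references, `[[`, 1L, "unit_length")
  nlib <- length(libraries)
  hits <- matrix(NA_real_, length(fam_ids), nlib,
                 dimnames = list(fam_ids, names(libraries)))
  totals <- stats::setNames(numeric(nlib), names(libraries))
  for (j in seq_len(nlib)) {
    mp <- map_reads(libraries[[j]], references, background = background, ...)
    hits[, j] <- mp$counts
    totals[j] <- mp$total_mapped
  }
  rp <- sweep(sweep(hits, 2L, totals / 1e6, "/"), 1L, units / 1000, "/")
  if (!is.null(absent)) {
    hits[absent] <- NA; rp[absent] <- NA
  }
  structure(list(hits = hits, rpkm = rp, log2rpkm = log_profile(rp),
                 total_mapped = totals, mask = absent,
                 unit_lengths = stats::setNames(units, fam_ids)),
            class = "expression_matrix")
}

#' log2(RPKM + 1) profile
#'
#' The +1 pseudo-count keeps zero-RPKM present-in-genome cells at 0;
#' masked (genome-absent) cells stay `NA`.
#'
#' @param m RPKM matrix (or `expression_matrix`).
#' @return matrix of log2(RPKM + 1) values.
#' @export
log_profile <- function(m) {
  if (inherits(m, "expression_matrix")) m <- m$rpkm
  log2(m + 1)
}

#' Transcription-to-genome activity ratio
#'
#' `log2(transcript_fraction / genomic_fraction)`: 0 for purely passive
#' transcription, positive when a family produces more transcript than
#' its genomic share. A transcript fraction of exactly 0 returns
#' `-Inf` (a sentinel distinct from masked cells).
#'
#' @param transcript_fraction family share of total transcripts (0-1).
#' @param genomic_fraction family share of the genome (0-1, > 0).
#' @return log2 ratio.
#' @export
activity_ratio <- function(transcript_fraction, genomic_fraction) {
  stopifnot(all(genomic_fraction > 0),
            all(transcript_fraction >= 0))
  log2(transcript_fraction / genomic_fraction)
}

#' Call actively transcribed families from an activity table
#'
#' `candidate`: positive ratio in at least one species where the family
#' is present. `cross_species_active`: positive ratio in all species
#' where the family is present in the genome (`NA` cells = absent, not
#' evaluated).
#'
#' @param ratios families x species matrix of activity ratios, `NA`
#'   where the family is absent from the species genome.
#' @return list with `candidates`, `cross_species_active` (family ids)
#'   and the per-family logical `table`.
#' @export
call_active <- function(ratios) {
  stopifnot(length(dim(ratios)) == 2L)
  fam <- rownames(ratios)
  if (is.null(fam)) fam <- paste0("fam", seq_len(nrow(ratios)))
  cand <- apply(ratios, 1L, function(r) any(r > 0, na.rm = TRUE))
  cross <- apply(ratios, 1L, function(r) {
    r <- r[!is.na(r)]
    length(r) > 0L && all(r > 0)
  })
  list(candidates = fam[cand], cross_species_active = fam[cross],
       table = data.frame(family = fam, candidate = cand,
                          cross_species_active = cross))
}

#' Pearson correlation of two expression profiles
#'
#' Pairs with any masked (`NA`) value are removed; at least 3 complete
#' pairs and nonzero variance in both vectors are required (`NA`
#' returned otherwise, with a warning for zero variance).
#'
#' @param x,y numeric vectors of equal length.
#' @return product-moment correlation coefficient.
#' @export
#' @examples
#' pearson(c(1, 2, 3), c(1, 3, 2))  # 0.5
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "pearson")
}

#' Hierarchical stage clustering of expression profiles
#'
#' Family rows of a log2 expression matrix are clustered with Euclidean
#' distance and complete linkage, and the tree is cut into `k` groups.
#' `hclust` ties are resolved by row order, so the assignment is
#' deterministic for a given matrix.
#'
#' @param m families x stages matrix of log2 RPKM values.
#' @param k number of clusters (default 4).
#' @return object of class `stage_clustering`: `assignment` (named
#'   integer vector), `tree` (the `hclust` object), `k`, `distance`,
#'   `linkage`.
#' @export
cluster_stages <- function(m, k = 4L) {
  stopifnot(length(dim(m)) == 2L)
  if (k > nrow(m)) stop("k exceeds the number of families")
  if (is.null(rownames(m))) rownames(m) <- paste0("fam", seq_len(nrow(m)))
  hc <- hclust(dist(m, method = "euclidean"), method = "complete")
  structure(list(assignment = cutree(hc, k = k), tree = hc, k = as.integer(k),
                 distance = "euclidean", linkage = "complete"),
            class = "stage_clustering")
}
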