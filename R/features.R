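# Sequence-level characterization of satellite monomers: alignment
# identity, base composition, unit-length histograms, fuzzy IUPAC motif
# scanning on the monomer circle, and per-column conservation profiles.

# identity from the edit-optimal global alignment, as normalized edit
# similarity: (L - distance)/L with L the longer sequence, so every
# gap or substitution costs one mismatched column. Optimal edit paths
# are not unique, but the distance is, which keeps this symmetric and
# deterministic.
.adist_identity <- function(a, b) {
  d <- utils::adist(a, b)
  L <- pmax(nchar(a), nchar(b))
  as.numeric(100 * pmax(L - d, 0) / L)
}

#' Pairwise global-alignment identity between two sequences
#'
#' Identity is computed from the edit-optimal global alignment as
#' `(L - distance) / L` with `L` the longer sequence length, so gaps
#' and substitutions both count as mismatched columns and the measure
#' is symmetric. In circular mode the best value over all rotations of
#' `a` is taken; with `strand = "both"` the reverse complement of `b`
#' is also tried.
#'
#' @param a,b DNA sequences (single strings).
#' @param circular treat `a` as a circular monomer.
#' @param strand `"both"` (default, strand-aware) or `"forward"`.
#' @return identity in percent (0-100).
#' @export
#' @examples
#' pairwise_identity("ACGT", "ACGA")          # 75
#' pairwise_identity("AAAA", "TTTT")          # 100 (reverse complement)
pairwise_identity <- function(a, b, circular = FALSE,
                              strand = c("both", "forward")) {
  strand <- match.arg(strand)
  stopifnot(nzchar(a), nzchar(b))
  a <- toupper(a); b <- toupper(b)
  targets <- if (strand == "both") c(b, revcomp(b)) else b
  if (!circular) return(max(vapply(targets, .adist_identity, 0, a = a)))
  n <- nchar(a)
  rots <- substring(paste0(a, a), seq_len(n), seq_len(n) + n - 1L)
  best <- 0
  for (tg in targets) {
    ids <- .adist_identity(rots, tg)
    best <- max(best, ids)
  }
  best
}

#' A+T content of a sequence
#'
#' IUPAC ambiguity codes are excluded from both numerator and
#' denominator.
#'
#' @param seq DNA string.
#' @return A+T percentage (0-100).
#' @export
at_content <- function(seq) {
  stopifnot(nzchar(seq))
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  acgt <- ch %in% .BASES
  if (!any(acgt)) return(NaN)
  100 * sum(ch %in% c("A", "T")) / sum(acgt)
}

#' Repeat-unit length histogram over closed bins
#'
#' @param lengths integer vector of unit lengths, or a data.frame with a
#'   `unit_length` column (e.g. a mining/catalog table).
#' @param bins list of `c(lo, hi)` ranges, closed on both ends;
#'   overlapping bins are rejected.
#' @return named integer vector of counts per bin.
#' @export
length_distribution <- function(lengths, bins) {
  if (is.data.frame(lengths)) lengths <- lengths$unit_length
  stopifnot(length(lengths) > 0, length(bins) > 0)
  bm <- do.call(rbind, bins)
  stopifnot(ncol(bm) == 2, all(bm[, 1] <= bm[, 2]))
  if (nrow(bm) > 1) {
    o <- order(bm[, 1])
    if (any(bm[o, 1][-1] <= bm[o, 2][-nrow(bm)]))
      stop("overlapping bins")
  }
  cnt <- vapply(bins, function(b) sum(lengths >= b[1] & lengths <= b[2]), 0L)
  names(cnt) <- vapply(bins, function(b) paste0(b[1], "-", b[2]), "")
  cnt
}

# logical: does concrete/IUPAC base `x` satisfy IUPAC pattern char `p`
.iupac_match <- function(x, p) {
  ex <- .IUPAC_EXPAND[[x]]
  ep <- .IUPAC_EXPAND[[p]]
  if (is.null(ex) || is.null(ep)) stop("invalid IUPAC character")
  length(intersect(ex, ep)) > 0L
}

#' Construct a fuzzy IUPAC motif pattern
#'
#' @param pattern IUPAC string (length >= 5).
#' @param max_mismatches allowed mismatches per hit.
#' @param both_strands scan both strands.
#' @return object of class `motif_pattern`.
#' @export
motif_pattern <- function(pattern, max_mismatches = 4L, both_strands = TRUE) {
  pattern <- toupper(pattern)
  stopifnot(nchar(pattern) >= 5L)
  if (grepl("[^ACGTRYSWKMBDHVN]", pattern)) stop("invalid IUPAC pattern")
  structure(list(pattern = pattern,
                 max_mismatches = as.integer(max_mismatches),
                 both_strands = isTRUE(both_strands)),
            class = "motif_pattern")
}

#' The human CENP-B box as a motif pattern
#' @inheritParams motif_pattern
#' @return a `motif_pattern` for YTTCGTTGGAARCGGGA.
#' @export
cenpb_box <- function(max_mismatches = 4L, both_strands = TRUE) {
  motif_pattern("YTTCGTTGGAARCGGGA", max_mismatches, both_strands)
}

#' Scan a monomer circle for fuzzy motif hits
#'
#' The monomer is doubled so junction-spanning hits are found; start
#' positions are reported 0-based on the monomer circle and hits
#' duplicated by the doubling are removed. IUPAC degeneracy in the
#' pattern counts as a match; a window hits when its mismatch count is
#' at most `pattern$max_mismatches`.
#'
#' @param seq monomer sequence (A/C/G/T).
#' @param pattern a [motif_pattern()].
#' @return data.frame with `start` (0-based), `strand`, `mismatches`,
#'   `identity` (matched positions / pattern length); zero rows when no
#'   hit.
#' @export
motif_scan <- function(seq, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop("motif_scan() expects an ACGT monomer")
  L <- nchar(seq)
  m <- nchar(pattern$pattern)
  doubled <- paste0(seq, seq)
  pats <- list(`+` = pattern$pattern)
  if (pattern$both_strands) pats$`-` <- revcomp(pattern$pattern)

  hits <- list()
  starts <- seq_len(L)                      # circle starts, dedup by design
  if (m > 2L * L) return(.empty_motif_hits())
  starts <- starts[starts + m - 1L <= 2L * L]
  sch <- strsplit(doubled, "", fixed = TRUE)[[1]]
  for (st in names(pats)) {
    pch <- strsplit(pats[[st]], "", fixed = TRUE)[[1]]
    mm <- integer(length(starts))
    for (j in seq_len(m)) {
      allowed <- .IUPAC_EXPAND[[pch[j]]]
      mm <- mm + !(sch[starts + j - 1L] %in% allowed)
    }
    ok <- which(mm <= pattern$max_mismatches)
    if (length(ok))
      hits[[st]] <- data.frame(start = starts[ok] - 1L, strand = st,
                               mismatches = mm[ok],
                               identity = (m - mm[ok]) / m)
  }
  if (!length(hits)) return(.empty_motif_hits())
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_motif_hits <- function() {
  data.frame(start = integer(0), strand = character(0),
             mismatches = integer(0), identity = numeric(0))
}

#' Positionwise identity of a motif hit to a reference box
#'
#' @param hit_seq the matched sequence (e.g. a 17-mer).
#' @param reference_box a [motif_pattern()] or IUPAC string of the same
#'   length.
#' @param orientation `"forward"` or `"revcomp"`; with `"revcomp"` the
#'   hit is reverse-complemented before comparison.
#' @return fraction of IUPAC-compatible positions (0-1).
#' @export
motif_identity <- function(hit_seq, reference_box,
                           orientation = c("forward", "revcomp")) {
  orientation <- match.arg(orientation)
  refp <- if (inherits(reference_box, "motif_pattern"))
    reference_box$pattern else toupper(reference_box)
  hit <- toupper(hit_seq)
  if (orientation == "revcomp") hit <- revcomp(hit)
  if (nchar(hit) != nchar(refp)) stop("length mismatch")
  h <- strsplit(hit, "", fixed = TRUE)[[1]]
  p <- strsplit(refp, "", fixed = TRUE)[[1]]
  mean(mapply(.iupac_match, h, p))
}

#' Per-column variability profile of an alignment
#'
#' For each alignment column the identity fraction is the frequency of
#' the modal state; gaps (`-`) are a fifth state, and all-gap columns
#' score 1 but are flagged. Conserved windows are maximal runs of at
#' least `window_min` columns with identity at least `min_identity`.
#'
#' @param aligned character vector of >= 3 aligned sequences of equal
#'   length (gaps as `-`).
#' @param window_min minimum window width in columns.
#' @param min_identity minimum column identity inside a window.
#' @return object of class `variability_profile`: `identity` (per
#'   column), `windows` (data.frame `start`, `end`, `mean_identity`,
#'   1-based), `all_gap` (logical per column), `n_seq`.
#' @export
variability_profile <- function(aligned, window_min = 15L,
                                min_identity = 0.95) {
  stopifnot(length(aligned) >= 3L)
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1L) stop("ragged alignment")
  mat <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  nc <- ncol(mat); n <- nrow(mat)
  ident <- numeric(nc); all_gap <- logical(nc)
  for (j in seq_len(nc)) {
    tb <- table(mat[, j])
    ident[j] <- max(tb) / n
    all_gap[j] <- identical(names(tb), "-")
  }
  ok <- ident >= min_identity
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= window_min
  windows <- data.frame(start = starts[keep], end = ends[keep])
  windows$mean_identity <- vapply(seq_len(nrow(windows)), function(i)
    mean(ident[windows$start[i]:windows$end[i]]), 0)
  structure(list(identity = ident, windows = windows, all_gap = all_gap,
                 n_seq = n),
            class = "variability_profile")
}
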