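# Low-level sequence utilities: random sequence generation, mutation,
# reverse complement, canonical rotation and 2-bit k-mer encoding.
# K-mers are encoded as doubles (exact up to 2^53, so any k <= 26) which
# keeps the hot paths (graph building, read mapping) off string hashing.

.BASES <- c("A", "C", "G", "T")

.IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# sorted base-set -> ambiguity code, e.g. "AG" -> "R"
.IUPAC_CODE <- local({
  keys <- vapply(.IUPAC_EXPAND, function(b) paste(sort(b), collapse = ""), "")
  stats::setNames(names(.IUPAC_EXPAND), keys)
})

# ASCII lookup: A->0, C->1, G->2, T->3, everything else NA
.BASE_INT <- local({
  v <- rep(NA_integer_, 127L)
  v[utf8ToInt("A")] <- 0L; v[utf8ToInt("C")] <- 1L
  v[utf8ToInt("G")] <- 2L; v[utf8ToInt("T")] <- 3L
  v
})

#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences (IUPAC codes allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

#' Random DNA sequence at a given A+T fraction
#'
#' @param n sequence length in bp.
#' @param at target A+T fraction (expected, not exact).
#' @return a single character string of length `n`.
#' @export
random_dna <- function(n, at = 0.5) {
  stopifnot(n >= 1, at >= 0, at <= 1)
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

# n mutated copies of a monomer; per-site substitution probability `rate`.
# Substitutions only; a mutated site always changes to a different base.
mutate_copies <- function(unit, n, rate) {
  if (n == 0L) return(character(0))
  L <- nchar(unit)
  base <- strsplit(unit, "", fixed = TRUE)[[1]]
  m <- matrix(rep(base, each = n), nrow = n)
  if (rate > 0) {
    nmut <- rbinom(1L, n * L, rate)
    if (nmut > 0) {
      idx <- sample.int(n * L, nmut)
      shift <- sample.int(3L, nmut, replace = TRUE)
      m[idx] <- .BASES[((match(m[idx], .BASES) - 1L + shift) %% 4L) + 1L]
    }
  }
  do.call(paste0, lapply(seq_len(L), function(j) m[, j]))
}

# deterministic disambiguation: each IUPAC code becomes the first base
# of its expansion (used where downstream code needs plain ACGT)
disambiguate <- function(seq) {
  if (!grepl("[^ACGT]", seq)) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  amb <- !(ch %in% .BASES)
  ch[amb] <- vapply(.IUPAC_EXPAND[ch[amb]], `[[`, "", 1L)
  paste(ch, collapse = "")
}

# single-sequence substitution mutagenesis
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  mutate_copies(seq, 1L, rate)
}

# substitution sequencing errors applied in place to a read vector
apply_read_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  L <- nchar(reads)
  nerr <- rbinom(length(reads), L, rate)
  todo <- which(nerr > 0L)
  for (i in todo) {
    pos <- sample.int(L[i], nerr[i])
    ch <- substring(reads[i], pos, pos)
    shift <- sample.int(3L, nerr[i], replace = TRUE)
    new <- .BASES[((match(ch, .BASES) - 1L + shift) %% 4L) + 1L]
    for (j in seq_along(pos)) substr(reads[i], pos[j], pos[j]) <- new[j]
  }
  reads
}

#' Canonical rotation of a circular sequence
#'
#' Returns the lexicographically smallest string among all rotations of
#' `seq` and all rotations of its reverse complement, giving every
#' monomer a unique strand- and phase-independent representation.
#' Idempotent by construction.
#'
#' @param seq a single DNA string.
#' @param strict reject non-ACGT characters (default). With
#'   `strict = FALSE` IUPAC ambiguity codes are tolerated.
#' @return the canonical rotation of `seq`.
#' @export
#' @examples
#' canonical_rotation("GTAC")  # "ACGT"
#' canonical_rotation("TTTT")  # "AAAA" (reverse complement wins)
canonical_rotation <- function(seq, strict = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  if (!nzchar(s)) stop("canonical_rotation() requires a non-empty sequence")
  bad <- if (strict) "[^ACGT]" else "[^ACGTRYSWKMBDHVN]"
  if (grepl(bad, s)) stop("canonical_rotation(): unexpected characters in sequence")
  n <- nchar(s)
  rots <- function(x) substring(paste0(x, x), seq_len(n), seq_len(n) + n - 1L)
  min(c(rots(s), rots(revcomp(s))))
}

# integer matrix (L x n) of base codes for uniform-length reads
encode_reads <- function(reads) {
  L <- unique(nchar(reads))
  stopifnot(length(L) == 1L)
  m <- vapply(reads, function(r) .BASE_INT[utf8ToInt(r)], integer(L),
              USE.NAMES = FALSE)
  if (anyNA(m)) stop("reads must contain only A/C/G/T")
  if (is.null(dim(m))) m <- matrix(m, nrow = L)
  m
}

# canonical (strand-collapsed) k-mer codes for uniform-length reads.
# Returns a data.table with one row per distinct (read, kmer) pair.
canonical_kmer_dt <- function(reads, k) {
  m <- encode_reads(reads)
  L <- nrow(m); n <- ncol(m)
  if (L < k) stop("reads shorter than k")
  W <- L - k + 1L
  pow <- 4^(k - 1)
  f <- rep(0, n); r <- rep(0, n)
  for (j in seq_len(k)) f <- f * 4 + m[j, ]
  for (j in rev(seq_len(k))) r <- r * 4 + (3 - m[j, ])
  out <- matrix(0, W, n)
  out[1L, ] <- pmin(f, r)
  if (W > 1L) for (w in 2:W) {
    jn <- w + k - 1L
    f <- (f %% pow) * 4 + m[jn, ]
    r <- (r - (3 - m[w - 1L, ])) / 4 + (3 - m[jn, ]) * pow
    out[w, ] <- pmin(f, r)
  }
  dt <- data.table::data.table(read = rep(seq_len(n), each = W),
                               kmer = as.vector(out))
  unique(dt, by = c("read", "kmer"))
}

# forward-strand k-mer codes with positions for a single sequence
# (used for reference indexing and read phasing)
seq_kmer_codes <- function(seq, k) {
  v <- .BASE_INT[utf8ToInt(seq)]
  if (anyNA(v)) stop("sequence must contain only A/C/G/T")
  L <- length(v)
  if (L < k) return(data.table::data.table(code = numeric(0), pos = integer(0)))
  W <- L - k + 1L
  pow <- 4^(k - 1)
  f <- 0
  codes <- numeric(W)
  for (j in seq_len(k)) f <- f * 4 + v[j]
  codes[1L] <- f
  if (W > 1L) for (w in 2:W) {
    f <- (f %% pow) * 4 + v[w + k - 1L]
    codes[w] <- f
  }
  data.table::data.table(code = codes, pos = seq_len(W))
}

# ungapped identity between two equal-length strings
ungapped_identity <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra == rb) / length(ra)
}

# FASTA / FASTQ I/O -----------------------------------------------------

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read sequences from FASTA
#' @param path input file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write reads to FASTQ (Phred+33, constant quality)
#' @param reads named character vector of reads.
#' @param path output file.
#' @param quality_char quality character used for every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  con <- file(path, open = "wt")
  on.exit(close(con))
  qual <- strrep(quality_char, nchar(reads))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), con)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#' @param path input file.
#' @return named character vector of reads.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
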