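# Shared fixtures and independent oracles for the suite. Everything is
# generated in code; no stored data.

# single-species library for mining-recovery runs: 30 families with
# uniformly spaced genomic fractions 1e-4..6e-3, unit lengths 30-300 bp
# interleaved across the abundance range, A+T 0.70-0.80
make_mining_spec <- function(n = 30L, genome_size = 20e6) {
  species <- data.frame(name = "S1", ploidy = "2n", genome_size = genome_size)
  fam <- data.frame(
    id = sprintf("Fam%02d", seq_len(n)),
    unit_length = round(seq(30, 300, length.out = n))[order(rep_len(1:5, n))],
    at_fraction = rep_len(seq(0.70, 0.80, by = 0.02), n),
    divergence = rep(0.027, n), signature = "S1")
  library_spec(species, fam, seq(1e-4, 6e-3, length.out = n))
}

# four-species nested library in which every family clears the 10-hit
# detection threshold: 6 ancestral (2 with planted losses in the
# intermediate species), 3 + 3 hybridization-gained subsets, 2 private
make_nested_spec <- function(scale = 0.03) {
  species <- data.frame(
    name = c("M1", "M2", "M3", "M4"), ploidy = c("2n", "<3n", "<4n", "4n"),
    genome_size = round(c(100e6, 189e6, 297e6, 304e6) * scale))
  sig <- c(rep("M1+M2+M3+M4", 6), rep("M2+M3+M4", 3), rep("M3+M4", 3),
           "M3", "M4")
  sig[5] <- "M1+M3+M4"   # planted loss in M2
  sig[6] <- "M1+M2+M4"   # planted loss in M3
  fam <- data.frame(
    id = sprintf("Fam%02d", 1:14),
    unit_length = c(60, 172, 95, 250, 45, 130, 80, 180, 55, 300, 70, 160,
                    110, 35),
    at_fraction = rep_len(seq(0.70, 0.80, by = 0.02), 14),
    divergence = rep(0.027, 14), signature = sig)
  library_spec(species, fam, seq(5e-3, 1.5e-3, length.out = 14),
               losses = data.frame(id = c("Fam05", "Fam06"),
                                   species = c("M2", "M3")))
}

# reads tiled across a (possibly mutated) tandem array
tiled_reads <- function(unit, copies, read_length = 100L, by = 7L,
                        copy_divergence = 0, error_rate = 0) {
  arr <- paste(satcomp:::mutate_copies(unit, copies, copy_divergence),
               collapse = "")
  starts <- seq(1L, nchar(arr) - read_length, by = by)
  reads <- substring(arr, starts, starts + read_length - 1L)
  satcomp:::apply_read_errors(reads, error_rate)
}

# presence matrix of the in-study nested subset design: 39 families in
# all four species, 20 gained with the first hybridization, 21 with the
# second, one private family per derived species
nested_design_presence <- function() {
  spp <- c("M1", "M2", "M3", "M4")
  rows <- c(rep(list(c(1, 1, 1, 1)), 39),
            rep(list(c(0, 1, 1, 1)), 20),
            rep(list(c(0, 0, 1, 1)), 21),
            list(c(0, 1, 0, 0)), list(c(0, 0, 1, 0)), list(c(0, 0, 0, 1)))
  m <- do.call(rbind, rows) > 0
  dimnames(m) <- list(sprintf("Mel%02d", seq_len(nrow(m))), spp)
  m
}

# ---- independent oracles --------------------------------------------

# brute-force Dollo on a chain order: every (gain position, loss set)
# assignment per family is enumerated explicitly
oracle_dollo_order <- function(pres, ord) {
  n <- ncol(pres)
  pos <- pres[, ord, drop = FALSE]
  total <- 0L
  for (i in seq_len(nrow(pos))) {
    best <- Inf
    for (g in seq_len(n)) {
      for (lossbits in 0:(2^(n - g + 1) - 1)) {
        lost <- as.logical(bitwAnd(lossbits, 2^(seq_len(n - g + 1) - 1)))
        state <- rep(FALSE, n)
        state[seq(g, n)] <- !lost
        if (identical(unname(state), unname(pos[i, ])))
          best <- min(best, sum(lost))
      }
    }
    if (!is.finite(best)) return(NA_integer_)  # unexplainable (all-absent)
    total <- total + as.integer(best)
  }
  total
}

# minimum over all chain orders
oracle_dollo <- function(pres) {
  n <- ncol(pres)
  perms <- satcomp:::.permutations(n)
  min(vapply(seq_len(nrow(perms)), function(i)
    oracle_dollo_order(pres, perms[i, ]), integer(1)))
}

# exhaustive sliding-window motif scan with per-character IUPAC sets
oracle_motif_scan <- function(seq, pattern, max_mm, both_strands = TRUE) {
  expand <- satcomp:::.IUPAC_EXPAND
  L <- nchar(seq)
  doubled <- paste0(seq, seq)
  pats <- list(`+` = pattern)
  if (both_strands) pats$`-` <- satcomp::revcomp(pattern)
  out <- list()
  for (st in names(pats)) {
    p <- strsplit(pats[[st]], "")[[1]]
    m <- length(p)
    for (i in seq_len(L)) {
      if (i + m - 1L > 2L * L) next
      w <- strsplit(substr(doubled, i, i + m - 1L), "")[[1]]
      mm <- 0L
      for (j in seq_len(m)) if (!(w[j] %in% expand[[p[j]]])) mm <- mm + 1L
      if (mm <= max_mm)
        out[[length(out) + 1L]] <- data.frame(start = i - 1L, strand = st,
                                              mismatches = mm)
    }
  }
  if (!length(out)) return(data.frame(start = integer(0),
                                      strand = character(0),
                                      mismatches = integer(0)))
  o <- do.call(rbind, out)
  o <- o[order(o$start, o$strand), , drop = FALSE]
  rownames(o) <- NULL
  o
}

# string-based canonical k-mers of one read (checks the 2-bit encoding)
oracle_read_kmers <- function(read, k) {
  n <- nchar(read) - k + 1L
  km <- substring(read, seq_len(n), seq_len(n) + k - 1L)
  sort(unique(pmin(km, satcomp::revcomp(km))))
}

random_seq <- function(n, at = 0.5) satcomp::random_dna(n, at)
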