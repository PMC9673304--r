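# Satellite discovery from unassembled reads: k-mer similarity graph,
# connected-component clustering with an optional deterministic label
# propagation refinement, tandem period estimation by autocorrelation of
# a greedily assembled representative contig, and monomer consensus
# building by phasing reads onto a seed unit.

#' Build a read similarity graph from shared canonical k-mers
#'
#' Two reads are joined by an edge iff they share at least `min_shared`
#' distinct canonical (strand-collapsed) k-mers. K-mers occurring in
#' more than `mask_freq` of all reads (with an absolute floor of
#' `mask_floor` reads, so small inputs are never masked) are treated as
#' low-complexity and ignored; k-mers private to a single read carry no
#' pairing information and are dropped.
#'
#' @param reads character vector of uniform-length A/C/G/T reads.
#' @param k odd k-mer size in 11..31.
#' @param min_shared minimum number of distinct shared k-mers per edge.
#' @param mask_freq high-frequency masking threshold (fraction of reads).
#' @param mask_floor absolute minimum read count before masking applies.
#' @param species optional per-read species/sample tags.
#' @return object of class `sat_graph`: `edges` (data.table `from`,
#'   `to`, `weight`), `n_reads`, `ids`, `species`, parameters.
#' @export
build_similarity_graph <- function(reads, k = 17L, min_shared = 5L,
                                   mask_freq = 0.01, mask_floor = 100L,
                                   species = NULL) {
  stopifnot(k %% 2L == 1L, k >= 11L, k <= 31L)
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  empty <- data.table::data.table(from = integer(0), to = integer(0),
                                  weight = integer(0))
  if (length(reads) == 0L)
    return(structure(list(edges = empty, n_reads = 0L, ids = character(0),
                          species = species, k = k, min_shared = min_shared,
                          mask_freq = mask_freq),
                     class = "sat_graph"))
  if (any(nchar(reads) < k)) stop("reads shorter than k")

  dt <- canonical_kmer_dt(unname(reads), k)
  cnt <- dt[, .N, by = kmer]
  mask_max <- max(as.numeric(mask_floor), mask_freq * length(reads))
  keep <- cnt[N >= 2L & N <= mask_max, kmer]
  dt <- dt[kmer %in% keep]
  data.table::setkey(dt, kmer)

  if (nrow(dt) == 0L) {
    edges <- empty
  } else {
    # batch the per-kmer pair expansion to bound memory
    gs <- dt[, .N, by = kmer]
    gs[, cost := as.numeric(N)^2]
    gs[, batch := cumsum(cost) %/% 3e7]
    parts <- list()
    for (b in unique(gs$batch)) {
      sub <- dt[kmer %in% gs[batch == b, kmer]]
      p <- sub[sub, on = "kmer", allow.cartesian = TRUE][read < i.read]
      if (nrow(p))
        parts[[length(parts) + 1L]] <-
          p[, .(n = .N), by = .(from = read, to = i.read)]
    }
    if (length(parts)) {
      pc <- data.table::rbindlist(parts)[, .(weight = sum(n)),
                                         by = .(from, to)]
      edges <- pc[weight >= min_shared]
    } else edges <- empty
  }
  structure(list(edges = edges, n_reads = length(reads), ids = ids,
                 species = species, k = k, min_shared = min_shared,
                 mask_freq = mask_freq),
            class = "sat_graph")
}

# deterministic label propagation: nodes visited in id order adopt the
# most frequent neighbour label, ties broken by the smallest label
label_propagation <- function(edges, nodes, max_iter = 20L) {
  lab <- stats::setNames(nodes, nodes)
  adj <- split(c(edges$to, edges$from), c(edges$from, edges$to))
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    for (v in nodes) {
      nb <- adj[[as.character(v)]]
      if (is.null(nb)) next
      tb <- table(lab[as.character(nb)])
      best <- names(tb)[tb == max(tb)]
      new <- min(as.integer(best))
      if (new != lab[as.character(v)]) {
        lab[as.character(v)] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

#' Cluster a similarity graph into repeat clusters
#'
#' Clusters are connected components of the graph, optionally refined by
#' a deterministic label-propagation pass; components smaller than
#' `min_cluster_size` are discarded. Graph density 2E/(N(N-1)) and
#' per-species read counts are recorded per cluster.
#'
#' @param graph a `sat_graph`.
#' @param min_cluster_size minimum member count.
#' @param refine apply the deterministic label-propagation refinement.
#' @return list of `repeat_cluster` objects (fields `members` (indices),
#'   `ids`, `size`, `density`, `species_counts`), ordered by decreasing
#'   size then smallest member.
#' @export
cluster_graph <- function(graph, min_cluster_size = 10L, refine = FALSE) {
  stopifnot(inherits(graph, "sat_graph"))
  e <- graph$edges
  if (nrow(e) == 0L) return(list())
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$from), to = as.character(e$to)),
    directed = FALSE)
  comp <- igraph::components(g)
  node <- as.integer(igraph::V(g)$name)
  member <- comp$membership
  if (refine) {
    lab <- integer(max(node))
    for (cid in seq_len(comp$no)) {
      nodes <- sort(node[member == cid])
      sub <- e[from %in% nodes & to %in% nodes]
      lp <- label_propagation(sub, nodes)
      # offset keeps labels unique across components
      lab[nodes] <- cid * 100000L + as.integer(factor(lp))
    }
    member <- lab[node]
  }
  groups <- split(node, member)
  groups <- groups[vapply(groups, length, 1L) >= min_cluster_size]
  if (length(groups) == 0L) return(list())

  clusters <- lapply(groups, function(nodes) {
    nodes <- sort(nodes)
    ne <- nrow(e[from %in% nodes & to %in% nodes])
    n <- length(nodes)
    sp <- NULL
    if (!is.null(graph$species)) sp <- table(graph$species[nodes])
    structure(list(members = nodes, ids = graph$ids[nodes], size = n,
                   density = 2 * ne / (n * (n - 1)),
                   species_counts = sp),
              class = "repeat_cluster")
  })
  ord <- order(-vapply(clusters, `[[`, 1L, "size"),
               vapply(clusters, function(cl) cl$members[1], 1L))
  unname(clusters[ord])
}

# greedy tandem-aware assembly of a representative contig from cluster
# reads; reads are indexed on both strands and appended by the
# best-supported k-mer-anchored overlap. Reads spanning an array
# boundary can derail a walk into flanking sequence where it stalls, so
# several walks from different seed reads are attempted and the longest
# contig is kept.
assemble_tandem_contig <- function(reads, k = 17L, target_len = 1500L,
                                   min_overlap_identity = 0.75,
                                   min_overlap = 30L, max_iter = 300L,
                                   max_restarts = 4L) {
  reads <- unname(reads)
  both <- c(reads, revcomp(reads))
  lens <- nchar(both)
  idx <- data.table::rbindlist(lapply(seq_along(both), function(i) {
    d <- seq_kmer_codes(both[i], k)
    d[, read := i]
    d
  }))
  data.table::setkey(idx, code)

  walk <- function(seed) {
    contig <- reads[seed]
    for (it in seq_len(max_iter)) {
      if (nchar(contig) >= target_len) break
      tail_len <- min(90L, nchar(contig))
      tail_seq <- substr(contig, nchar(contig) - tail_len + 1L, nchar(contig))
      tk <- seq_kmer_codes(tail_seq, k)
      tk[, cpos := pos + nchar(contig) - tail_len]  # contig coords
      hits <- idx[tk, on = "code", nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(hits) == 0L) break
      # implied read start position on the contig
      hits[, rstart := cpos - pos + 1L]
      hits[, ext := rstart + lens[read] - 1L - nchar(contig)]
      cand <- hits[ext > 0L & rstart >= 1L &
                     nchar(contig) - rstart + 1L >= min_overlap,
                   .(votes = .N), by = .(read, rstart, ext)]
      if (nrow(cand) == 0L) break
      # among well-supported overlaps, extend as far as possible
      cand <- cand[votes >= max(5, 0.5 * max(votes))]
      data.table::setorder(cand, -ext, -votes, read)
      extended <- FALSE
      for (ci in seq_len(min(nrow(cand), 200L))) {
        r <- cand$read[ci]; rs <- cand$rstart[ci]
        ov <- nchar(contig) - rs + 1L
        a <- substr(contig, rs, nchar(contig))
        b <- substr(both[r], 1L, ov)
        if (nchar(a) != nchar(b)) next
        if (ungapped_identity(a, b) >= min_overlap_identity) {
          contig <- paste0(contig, substr(both[r], ov + 1L, lens[r]))
          extended <- TRUE
          break
        }
      }
      if (!extended) break
    }
    contig
  }

  ord <- order(-nchar(reads), seq_along(reads))
  n_try <- min(max_restarts, length(reads))
  seeds <- ord[unique(pmax(1L, round(seq(1, length(reads),
                                         length.out = n_try))))]
  best <- ""
  for (s in seeds) {
    ctg <- walk(s)
    if (nchar(ctg) > nchar(best)) best <- ctg
    if (nchar(best) >= target_len) break
  }
  best
}

#' Estimate the tandem monomer period of a cluster
#'
#' Assembles a representative contig from the cluster reads and scans
#' offsets (10..500 bp by default) for the smallest shift maximizing
#' self-identity of the contig against itself (autocorrelation). When no
#' offset reaches `self_identity` the cluster is reported non-tandem
#' (period `NA`). When several offsets tie within `tie_eps` the smallest
#' (the minimal period) is returned.
#'
#' @param cluster_reads character vector of cluster member reads.
#' @param min_offset,max_offset offset scan range in bp.
#' @param self_identity minimum self-match identity to call a tandem.
#' @param tie_eps identity tolerance for the minimal-period rule.
#' @param k k-mer size used during contig assembly.
#' @param target_len contig length the assembler aims for.
#' @return list with `period` (integer or NA), `identity` (self-match
#'   at the period), `contig`, and `low_confidence` (TRUE when the
#'   contig spans fewer than two periods).
#' @export
estimate_monomer_period <- function(cluster_reads, min_offset = 10L,
                                    max_offset = 500L, self_identity = 0.70,
                                    tie_eps = 0.02, k = 17L,
                                    target_len = 1500L) {
  stopifnot(length(cluster_reads) >= 1L)
  contig <- assemble_tandem_contig(cluster_reads, k = k,
                                   target_len = target_len)
  v <- utf8ToInt(contig)
  n <- length(v)
  hi <- min(max_offset, n - 20L)
  if (hi < min_offset)
    return(list(period = NA_integer_, identity = NA_real_, contig = contig,
                low_confidence = TRUE))
  offs <- min_offset:hi
  ident <- vapply(offs, function(p) mean(v[seq_len(n - p)] == v[(p + 1L):n]),
                  0)
  best <- max(ident)
  if (best < self_identity)
    return(list(period = NA_integer_, identity = best, contig = contig,
                low_confidence = FALSE))
  cand <- offs[ident >= best - tie_eps & ident >= self_identity]
  period <- min(cand)
  # a greedy contig can be a locally exact copy of the same reads, which
  # inflates self-identity at the assembly cycle length; when a (near-)
  # divisor of the chosen offset scores nearly as well it is the true
  # minimal unit and is preferred. Divisors below the scan floor are
  # checked directly so short monomers (e.g. pentamers) are reported.
  self_id <- function(p) mean(v[seq_len(n - p)] == v[(p + 1L):n])
  if (period > 3L) {
    dd <- 2:(period - 1L)
    divs <- dd[abs(period - round(period / dd) * dd) <= 2L]
    if (length(divs)) {
      div_id <- vapply(divs, self_id, 0)
      hit <- divs[div_id >= pmax(self_identity, best - 0.1)]
      if (length(hit)) period <- min(hit)
    }
  }
  list(period = as.integer(period),
       identity = self_id(period),
       contig = contig,
       low_confidence = n < 2L * period)
}

#' Derive a canonical monomer consensus from cluster reads
#'
#' A seed unit is cut from the representative contig; every read is
#' phased against a concatemer of the seed unit (best strand, modal
#' k-mer-anchored offset) and votes ungapped into the period-length
#' column space. The column-majority base is taken (IUPAC code on exact
#' ties) and the result is normalized with [canonical_rotation()].
#'
#' @param cluster_reads character vector of member reads.
#' @param period monomer period in bp.
#' @param contig optional pre-assembled contig (assembled if missing).
#' @param k k-mer size for phasing anchors.
#' @param min_support minimum number of phased reads (error below).
#' @return object of class `consensus_record`: `sequence`,
#'   `unit_length`, `support` (reads used), `at_fraction`.
#' @export
derive_consensus <- function(cluster_reads, period, contig = NULL,
                             k = 17L, min_support = 3L) {
  stopifnot(period >= 1L)
  if (is.null(contig))
    contig <- assemble_tandem_contig(cluster_reads, k = k,
                                     target_len = max(1500L, 3L * period))
  if (nchar(contig) < period) stop("contig shorter than the period")
  unit <- substr(contig, 1L, period)
  max_rl <- max(nchar(cluster_reads))
  ncop <- ceiling((max_rl + period) / period) + 1L
  ref <- strrep(unit, ncop)
  ridx <- seq_kmer_codes(ref, k)
  data.table::setkey(ridx, code)

  counts <- matrix(0L, 4L, period, dimnames = list(.BASES, NULL))
  support <- 0L
  for (rd in cluster_reads) {
    best <- NULL
    for (sq in c(rd, revcomp(rd))) {
      kk <- seq_kmer_codes(sq, k)
      hh <- ridx[kk, on = "code", nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(hh) == 0L) next
      off <- hh$pos - hh$i.pos           # ref start offset of the read - 1
      tb <- table(off %% period)
      nvotes <- max(tb)
      if (is.null(best) || nvotes > best$n) {
        d <- as.integer(names(tb)[which.max(tb)])
        best <- list(seq = sq, d = d, n = nvotes)
      }
    }
    if (is.null(best) || best$n < 2L) next
    b <- .BASE_INT[utf8ToInt(best$seq)] + 1L
    col <- ((best$d + seq_along(b) - 1L) %% period) + 1L
    for (j in seq_along(b)) counts[b[j], col[j]] <- counts[b[j], col[j]] + 1L
    support <- support + 1L
  }
  if (support < min_support)
    stop("low support: fewer than ", min_support, " phased reads")

  cons <- vapply(seq_len(period), function(j) {
    cc <- counts[, j]
    if (sum(cc) == 0L) return("N")
    mx <- which(cc == max(cc))
    if (length(mx) == 1L) .BASES[mx]
    else .IUPAC_CODE[[paste(sort(.BASES[mx]), collapse = "")]]
  }, "")
  seqc <- paste(cons, collapse = "")
  strict <- !grepl("[^ACGT]", seqc)
  seqc <- canonical_rotation(seqc, strict = strict)
  structure(list(sequence = seqc, unit_length = nchar(seqc),
                 support = support, at_fraction = at_content(seqc) / 100),
            class = "consensus_record")
}

#' Mine satellite families from a read set
#'
#' Full discovery pass: similarity graph, clustering, tandem filtering
#' by density and period, and consensus derivation per tandem cluster.
#'
#' @param reads character vector (or named vector) of uniform-length
#'   reads; a `species` attribute/argument tags reads by sample.
#' @param k,min_shared,mask_freq graph parameters, see
#'   [build_similarity_graph()].
#' @param min_cluster_size minimum cluster size.
#' @param refine deterministic label-propagation refinement.
#' @param min_density minimum cluster graph density for a satellite call.
#' @param self_identity autocorrelation identity for the tandem call.
#' @param species optional per-read species tags.
#' @return object of class `sat_mining`: `families` data.frame
#'   (`family`, `unit_length`, `at_fraction`, `support`, `n_reads`,
#'   `density`), `consensi` (named character), `clusters` (the
#'   underlying `repeat_cluster`s for retained families),
#'   `species_hits` (families x species matrix of member read counts,
#'   when species tags were provided), `n_reads_total`, `params`.
#' @export
mine_satellites <- function(reads, k = 17L, min_shared = 5L,
                            min_cluster_size = 10L, mask_freq = 0.01,
                            refine = FALSE, min_density = 0.2,
                            self_identity = 0.70, species = NULL) {
  g <- build_similarity_graph(reads, k = k, min_shared = min_shared,
                              mask_freq = mask_freq, species = species)
  cls <- cluster_graph(g, min_cluster_size = min_cluster_size,
                       refine = refine)
  fams <- list(); consensi <- character(0); kept <- list()
  for (cl in cls) {
    if (cl$density < min_density) next
    crd <- unname(reads[cl$members])
    pe <- estimate_monomer_period(crd, self_identity = self_identity, k = k)
    if (is.na(pe$period)) next
    rec <- tryCatch(derive_consensus(crd, pe$period, contig = pe$contig,
                                     k = k),
                    error = function(e) NULL)
    if (is.null(rec)) next
    id <- sprintf("fam%03d", length(fams) + 1L)
    fams[[id]] <- data.frame(family = id, unit_length = rec$unit_length,
                             at_fraction = rec$at_fraction,
                             support = rec$support, n_reads = cl$size,
                             density = cl$density)
    consensi[id] <- rec$sequence
    kept[[id]] <- cl
  }
  families <- if (length(fams)) do.call(rbind, fams) else
    data.frame(family = character(0), unit_length = integer(0),
               at_fraction = numeric(0), support = integer(0),
               n_reads = integer(0), density = numeric(0))
  rownames(families) <- NULL
  species_hits <- NULL
  if (!is.null(species) && length(kept)) {
    spp <- sort(unique(species))
    species_hits <- matrix(
      unlist(lapply(kept, function(cl)
        as.integer(table(factor(species[cl$members], levels = spp))))),
      nrow = length(kept), ncol = length(spp), byrow = TRUE,
      dimnames = list(names(kept), spp))
  }
  structure(list(families = families, consensi = consensi, clusters = kept,
                 species_hits = species_hits, n_reads_total = length(reads),
                 params = list(k = k, min_shared = min_shared,
                               min_cluster_size = min_cluster_size,
                               mask_freq = mask_freq, refine = refine,
                               min_density = min_density,
                               self_identity = self_identity)),
            class = "sat_mining")
}
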