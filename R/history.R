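# Hybridization/polyploidization history from satDNA presence/absence:
# signature partition and Dollo parsimony on a linear species chain
# (maternal recipient plus successive paternal donors).

#' Partition families by their species-presence signature
#'
#' @param presence families x species logical matrix (or 0/1).
#' @return object of class `subset_partition`: `signatures` (named list
#'   signature -> family ids, ordered by decreasing species-set size),
#'   `counts`, `species`, `presence`.
#' @export
partition_by_signature <- function(presence) {
  stopifnot(length(dim(presence)) == 2L, nrow(presence) >= 1L)
  pres <- presence > 0
  if (is.null(rownames(pres))) rownames(pres) <- paste0("fam", seq_len(nrow(pres)))
  empty <- rowSums(pres) == 0L
  if (any(empty)) {
    warning(sum(empty), " all-absent families excluded from partition")
    pres <- pres[!empty, , drop = FALSE]
    if (nrow(pres) == 0L) stop("no present families")
  }
  sig <- apply(pres, 1L, function(p)
    paste(colnames(pres)[p], collapse = "+"))
  buckets <- split(rownames(pres), sig)
  sizes <- vapply(strsplit(names(buckets), "+", fixed = TRUE), length, 1L)
  o <- order(-sizes, names(buckets))
  buckets <- buckets[o]
  structure(list(signatures = buckets,
                 counts = vapply(buckets, length, 1L),
                 species = colnames(pres), presence = pres),
            class = "subset_partition")
}

# per-family minimal single-gain explanation on a fixed chain order:
# gain at the earliest present position, every later absent position a
# loss (standard Dollo on a chain)
.chain_explain <- function(pos_present, n) {
  g <- min(pos_present)
  losses <- setdiff(seq(g, n), pos_present)
  list(gain = g, losses = losses)
}

#' Infer the most parsimonious hybridization history on a species chain
#'
#' Searches species chain orders (exhaustively for up to
#' `max_exhaustive` species) under Dollo parsimony: each family is
#' gained exactly once on the chain (at the step of its earliest
#' present species) and may be lost independently in downstream
#' species. The order minimizing total losses (then the number of
#' hybridization events) is selected; ties are broken by the hint
#' order, else lexicographically by the species-name sequence.
#'
#' A post-ancestral chain step counts as a hybridization event when its
#' gained subset contains at least one family also present in a species
#' later on the chain; a private-only terminal gain is reported as a
#' within-lineage amplification, not a hybridization event. Families
#' whose single-gain explanation needs two or more losses and whose
#' chain presence splits into two or more runs are flagged as
#' homoplasy-prone and excluded from event attribution.
#'
#' @param partition a [partition_by_signature()] result or a presence
#'   matrix.
#' @param species_order_hint optional species chain used to break ties.
#' @param force_order optional species chain to evaluate as-is (no
#'   order search); gains and losses are reconstructed on that chain.
#' @param max_exhaustive maximum species count for the exhaustive
#'   order search (hard limit 8).
#' @return object of class `hybridization_history`: `chain`, `gains`
#'   (per chain position), `events` (data.frame with `position`,
#'   `species`, `n_gained`, `hybridization`), `n_events`
#'   (post-ancestral hybridization events), `losses` (data.frame
#'   `family`, `species`), `total_losses`, `homoplasy` (family ids),
#'   `objective`.
#' @export
infer_history <- function(partition, species_order_hint = NULL,
                          force_order = NULL, max_exhaustive = 6L) {
  if (!inherits(partition, "subset_partition"))
    partition <- partition_by_signature(partition)
  pres <- partition$presence
  spp <- partition$species
  n <- length(spp)
  if (n < 1L) stop("no species")
  if (n == 1L) {
    return(structure(list(chain = spp,
                          gains = stats::setNames(list(rownames(pres)), spp),
                          events = data.frame(position = 1L, species = spp,
                                              n_gained = nrow(pres),
                                              hybridization = FALSE),
                          n_events = 0L,
                          losses = data.frame(family = character(0),
                                              species = character(0)),
                          total_losses = 0L, homoplasy = character(0),
                          objective = c(losses = 0, events = 0)),
                     class = "hybridization_history"))
  }
  if (is.null(force_order)) {
    if (n > min(max_exhaustive, 8L))
      stop("exhaustive chain search supports at most ",
           min(max_exhaustive, 8L), " species")
    perms <- .permutations(n)
  } else {
    stopifnot(setequal(force_order, spp))
    perms <- matrix(match(force_order, spp), nrow = 1L)
  }
  score_order <- function(ord) {
    pos <- pres[, spp[ord], drop = FALSE]
    total_losses <- 0L
    gain_pos <- integer(nrow(pos))
    last_pos <- integer(nrow(pos))
    for (i in seq_len(nrow(pos))) {
      pp <- which(pos[i, ])
      ex <- .chain_explain(pp, n)
      gain_pos[i] <- ex$gain
      last_pos[i] <- max(pp)
      total_losses <- total_losses + length(ex$losses)
    }
    # hybridization events: post-root steps gaining a family that is
    # also present downstream
    ev <- vapply(2:n, function(p)
      any(gain_pos == p & last_pos > p), TRUE)
    list(losses = total_losses, events = sum(ev),
         gain_pos = gain_pos, last_pos = last_pos)
  }
  scored <- lapply(seq_len(nrow(perms)), function(i)
    score_order(perms[i, ]))
  losses <- vapply(scored, `[[`, 0L, "losses")
  events <- vapply(scored, `[[`, 0, "events")
  best <- which(losses == min(losses))
  best <- best[events[best] == min(events[best])]
  chains <- lapply(best, function(i) spp[perms[i, ]])
  pick <- 1L
  if (!is.null(species_order_hint)) {
    hit <- which(vapply(chains, function(ch)
      identical(ch, species_order_hint), TRUE))
    if (length(hit)) pick <- hit[1]
    else pick <- order(vapply(chains, paste, "", collapse = "\r"))[1]
  } else {
    pick <- order(vapply(chains, paste, "", collapse = "\r"))[1]
  }
  chain <- chains[[pick]]
  sc <- scored[[best[pick]]]

  fam <- rownames(pres)
  gains <- lapply(seq_len(n), function(p) fam[sc$gain_pos == p])
  names(gains) <- chain
  pos <- pres[, chain, drop = FALSE]
  loss_list <- list()
  homoplasy <- character(0)
  for (i in seq_len(nrow(pos))) {
    pp <- which(pos[i, ])
    ex <- .chain_explain(pp, n)
    if (length(ex$losses)) {
      loss_list[[length(loss_list) + 1L]] <-
        data.frame(family = fam[i], species = chain[ex$losses])
      runs <- sum(diff(c(-1L, pp)) > 1L)
      if (length(ex$losses) >= 2L && runs >= 2L)
        homoplasy <- c(homoplasy, fam[i])
    }
  }
  losses_df <- if (length(loss_list)) do.call(rbind, loss_list) else
    data.frame(family = character(0), species = character(0))

  keep <- !(fam %in% homoplasy)
  ev_flag <- vapply(seq_len(n), function(p) {
    if (p == 1L) return(FALSE)
    idx <- which(sc$gain_pos == p & keep)
    length(idx) > 0L && any(sc$last_pos[idx] > p)
  }, TRUE)
  events_df <- data.frame(position = seq_len(n), species = chain,
                          n_gained = vapply(gains, length, 1L),
                          hybridization = ev_flag)

  structure(list(chain = chain, gains = gains, events = events_df,
                 n_events = sum(ev_flag),
                 losses = losses_df, total_losses = sc$losses,
                 homoplasy = homoplasy,
                 objective = c(losses = sc$losses, events = sc$events)),
            class = "hybridization_history")
}

# all permutations of 1..n as a matrix (n! x n)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Proportionality of satDNA totals to a genomic covariate
#'
#' Pearson correlation between per-species satDNA totals (count or
#' summed abundance) and a covariate such as genome size or gene
#' number, plus the per-species total/covariate ratios.
#'
#' @param totals named per-species totals (>= 3 species).
#' @param covariates named per-species covariate values.
#' @return list with `correlation` (NA when the covariate is constant)
#'   and `ratios` (data.frame `species`, `total`, `covariate`,
#'   `ratio`).
#' @export
ploidy_proportionality <- function(totals, covariates) {
  stopifnot(length(totals) >= 3L, length(covariates) == length(totals))
  if (!is.null(names(covariates)) && !is.null(names(totals)))
    covariates <- covariates[names(totals)]
  r <- if (stats::sd(covariates) == 0 || stats::sd(totals) == 0) NA_real_
       else pearson(as.numeric(totals), as.numeric(covariates))
  list(correlation = r,
       ratios = data.frame(species = names(totals),
                           total = as.numeric(totals),
                           covariate = as.numeric(covariates),
                           ratio = as.numeric(totals) / as.numeric(covariates)))
}
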