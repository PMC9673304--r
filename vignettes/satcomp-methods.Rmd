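---
title: "Comparative satellitome analysis with satcomp: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative satellitome analysis with satcomp: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satcomp)
```

## The problem

Satellite DNAs (satDNAs) are noncoding sequences organized as long
arrays of tandemly repeated units (monomers). The collection of
distinct satDNA families in a genome — the satellitome — is both the
fastest-evolving and the worst-assembled part of most genomes, so it
is characterized directly from unassembled low-coverage reads:
reads sharing sequence are clustered, tandem clusters are recognized,
and each family is summarized by a monomer consensus, a unit length and
a genomic abundance.

satcomp implements that workflow end to end for *comparative* studies
of closely related species: a shared catalog is mined from pooled
coverage-matched reads, per-species abundance and presence matrices are
derived, a most-parsimonious hybridization/polyploidization history is
inferred from presence/absence on a species chain, satDNA transcription
is profiled from RNA-seq-like libraries, and conserved sequence
features (CENP-B box-like motifs, conserved windows such as splice
leader exons) are characterized. A seeded synthetic-data generator
reproduces the statistical structure such studies assume — nested
satDNA libraries added by successive hybridizations — and provides the
ground truth for every claim the test suite makes.

## Simulation model

`library_spec()` describes a species chain (the maternal lineage
order) and a set of families, each with a unit length (30–300 bp in
the default catalog, concentrated at 50–90 and 170–190 bp), an A+T
fraction (0.70–0.80), a genomic fraction, an interspecies divergence
and an explicit presence signature. `default_library_spec()` encodes
the full study-condition design: four species with ploidies 2n, <3n,
<4n, 4n and genome sizes 100/189/297/304 Mb (scalable), a nested
library of 39 ancestral families plus subsets of 20 and 21 gained by
two successive hybridizations, one species-specific family per derived
species (83 total), and four planted losses in the two intermediate
species — the hypotriploid/hypotetraploid signature. Genomic fractions
decay as a power law from 0.613% to a floor of 0.002%; abundance ranks
are interleaved across the subsets with a stride permutation because
comparative catalogs show every subset spanning the abundance range,
and planted losses sit on abundant ancestral families so that loss is
an observable event rather than a statement about undetectable
families.

`synthesize_library()` draws one ancestral consensus per family
(random sequence at the family's A+T fraction) and mutates it
independently in each carrying species at *half* the specified
divergence, so the expected pairwise divergence between two species'
consensi equals the specified value (2.7% for most families, a tail to
21%). Within a genome, array copies are mutated at an intra-array rate
of 2% — concerted evolution keeps intraspecific variability below the
interspecific one, and these values reproduce that ordering.

`generate_genome_reads()` builds a genome mosaic with one contiguous
array per family (the simplest layout preserving abundance and tandem
periodicity; real array structure is unknown at these scales), placed
in random order inside random background sequence at A+T 0.70, then
draws uniformly positioned single-end reads with uniform strand and
substitution-only errors (the dominant Illumina error mode; indels are
deliberately excluded, which keeps the phased-consensus model exact).
Reads are byte-identical across runs with the same seed.

`generate_transcriptome_reads()` implements the passive-transcription
null: a family's expected transcript fraction equals its genomic
fraction times a per-stage activity multiplier (1 = passive), with a
50-gene background pool — one GAPDH-like reference gene included —
absorbing the rest of the library, so satellite transcript fractions
stay realistically small. Four stage-archetype multiplier patterns
(always-high, moderate-with-dropout, low, stage-restricted) give the
stage-clustering step a recoverable truth.

What the generator does *not* emulate: higher-order repeat structure,
interspersed or decayed array copies, transposable elements, indel
sequencing errors, paired-end reads, positional transcription biases,
and rRNA carryover. Passing tests therefore demonstrate correctness of
the algorithms under the stated statistical model, not performance on
any particular real library.

## Mining model

`build_similarity_graph()` joins two reads when they share at least
`min_shared = 5` distinct canonical (strand-collapsed) k-mers with
`k = 17`. K-mers are 2-bit-encoded and processed with data.table, so
0.25x subsamples of tens of megabases are practical. K-mers occurring
in more than 1% of all reads (with an absolute floor of 100 reads so
that small inputs are never masked) are treated as low-complexity hubs
and ignored — A+T-rich background otherwise welds families together.
Defaults were chosen so that a 10-read cluster — the smallest cluster
that can clear the 10-hit presence threshold — can form a connected
component.

Clusters are connected components, optionally refined by a
deterministic label-propagation pass (nodes visited in id order, ties
to the smallest label). Refinement is off by default: reads of a
long-monomer family tile the monomer circle and form ring-like
components that naive community detection fragments, and fragment
clusters below `min_cluster_size = 10` would silently delete real
families. Cluster graph density 2E/(N(N-1)) is recorded; clusters
below density 0.2 are not called satellites.

`estimate_monomer_period()` greedily assembles a representative contig
from the cluster reads (k-mer-anchored overlaps, best-supported
extension, several restart seeds because array-boundary reads can
derail a walk into flanking sequence) and scans shift offsets 10–500 bp
for the smallest offset maximizing self-identity; below 70%
self-identity the cluster is reported non-tandem. Because a greedy
contig can be a locally *exact* copy of the same reads, self-identity
can peak at an assembly cycle length that is a multiple of the true
period; a divisor that scores within 0.1 of the maximum is therefore
preferred, and divisors below the scan floor are checked directly so
very short monomers are reported at their minimal period.

`derive_consensus()` phases every read (best strand, modal
k-mer-anchored offset) onto a seed unit cut from the contig and votes
ungapped into the period-length column space; the column-majority base
is taken, exact ties become IUPAC codes, and the result is normalized
by `canonical_rotation()` — the lexicographically smallest string
among all rotations of the sequence and its reverse complement — so
consensi are comparable across runs, strands and phases.

## Cross-species comparison

`pool_subsamples()` draws `coverage x genome_size / read_length` reads
per species (0.25x by default — the working coverage selected by
`coverage_sweep()`-style diagnostics), keeping species tags.
Co-clustering the pooled reads yields clusters in which each read
contributes exactly once; per-species hit counts give abundance
(`100 x hits / reads analyzed`) and presence (`hits >= 10`, boundary
inclusive). Copy numbers follow from
`fraction x genome_size / unit_length`. Families are numbered `Sat01…`
by decreasing total abundance (ties: longer unit, then lexicographic
canonical consensus), with a secondary display order grouping families
by shared appearance from smaller to larger genomes. Species-specific
consensi are rebuilt from each species' member reads, falling back to
the pooled consensus (flagged) below 3 supporting reads.

`group_variants()` connects families whose rotation- and strand-aware
global-alignment identity exceeds 65% (strict), and reports connected
components with at least two members. Identity is the normalized edit
similarity `(L - d)/L` with `L` the longer length and `d` the
edit-optimal global alignment distance — gaps and substitutions both
cost one mismatched column; this is symmetric and deterministic,
whereas a matches/columns decomposition of an optimal edit path is
not unique. One caveat worth knowing: the *null* of this
rotation-maximized measure for unrelated short A+T-rich monomers sits
near 58–60% with a tail that can cross 65%, so automated >65% groups
of short units deserve the same curation published catalogs apply.

## Hybridization history

`infer_history()` searches species chain orders (exhaustive up to six
species) under Dollo parsimony on a chain: each family is gained once,
at the chain position of its earliest present species, and absences
downstream of the gain are losses. The selected order minimizes total
losses, then the number of hybridization events; ties are broken by
the caller's hint order, else lexicographically. The type contract —
total losses minimal over admissible chain orders — pins this
objective; minimizing gained-family counts first would degenerately
favor placing the largest satellitome at the root.

A post-ancestral chain step counts as a *hybridization event* only
when its gained subset contains at least one family also present in a
downstream species: a subset that persists into descendant genomes is
evidence of germline donor input, whereas a private-only terminal gain
is equally explained by within-lineage amplification and is reported
as such. On the nested design (39/20/21 plus species-specific sets)
this yields exactly two post-ancestral hybridization events, with the
species-specific sets attributed to amplification. Families whose
single-gain explanation needs two or more losses *and* whose chain
presence splits into two or more runs are flagged homoplasy-prone and
excluded from event attribution, never silently merged.

Two identifiability caveats, both visible in the test designs: the
last two chain positions are distinguished only by asymmetries in
private families and losses (a design whose two terminal species carry
symmetric single privates is genuinely order-ambiguous, which is why
sister species appear as a split in hybridization schemes), and chain
inference is only meaningful over families above the detection
threshold, so scaled-down validation uses libraries whose families
all clear it.

## Transcription profiling

Reads are assigned by seed-and-vote k-mer mapping (k = 13, anchors
every third position, both strands) followed by an ungapped identity
check at the anchored offset; a read counts once, for its best
reference, with ties toward the lowest catalog number — the published
analyses ran aligners in report-all mode, and counting every alignment
would multiple-count reads across concatenated monomers. The identity
floor is 80%, tolerating the ~2.7% interspecies divergence plus
sequencing error without absorbing unrelated reads. References are
monomer concatemers: units under 50 bp are repeated to at least
100 bp, longer units to unit length plus read length, so
junction-spanning reads map fully; RPKM normalization always uses the
single-unit length. The mapped-read denominator counts all assigned
reads (satellite plus background pool); log profiles use
`log2(RPKM + 1)` so zero expression in a present family is 0 while
genome-absent cells stay masked (`NA`).

The activity ratio `log2(transcript fraction / genomic fraction)` is 0
in expectation for passive families by construction. Per-species
ratios are estimated from counts pooled across a species' libraries
(the pooled estimator is nearly unbiased even for rare families, where
per-library log averages are badly Jensen-biased and zero counts give
`-Inf`); the calibration criterion is therefore stated on the
across-family mean of these per-family ratios. `call_active()` labels
a family a candidate on a positive ratio in any species and
cross-species-active on positive ratios in *all* species where it is
present in the genome. Note a structural property of that rule: under
the exact passive null the point estimate exceeds zero with
probability approaching one half per species, so the expected false
cross-species-active rate is about `mean(0.5^k)` over families present
in `k` species (~14% for the nested design) — a rate no library depth
reduces. Comparative designs relying on these calls get their error
control from requiring concordance across species and stages, not from
the per-species call itself.

Stage clustering is hierarchical (Euclidean distance, complete
linkage) on family rows of the log2 matrix, cut into four groups, all
via `stats::hclust`/`cutree`, so the assignment is deterministic given
the matrix.

## Sequence features

`motif_scan()` scans the doubled monomer on both strands so
junction-spanning hits are found once, with IUPAC degeneracy counting
as a match and a default mismatch allowance of 4 for 17-mers
(CENP-B box-like discovery keeps hits >= 76% identical while spanning
the 36–74% monomer-divergence regime); positions are 0-based on the
monomer circle internally and 1-based in TSV output.
`motif_identity()` compares a hit to a reference box positionwise
after applying the stated orientation (satellite motifs are reported
as reverse complements relative to the human box).
`variability_profile()` scores each alignment column by the frequency
of its modal state with gaps as a fifth state (all-gap columns score 1
but are flagged), and reports maximal runs of at least 15 columns at
identity >= 0.95 as conserved windows — the form in which splice
leader exons and Sm binding sites show up inside otherwise divergent
monomers. The annotated window length is user-supplied.

## Validation scale and reproducibility

The suite validates: mining recovery on five seeded 20-Mb, 0.25x
simulations with 30 families at fractions 1e-4 to 6e-3 (≥90% of
families recovered at the correct period modulo multiples and
consensus identity ≥95%; the smallest family expects five reads and
is structurally undetectable below the 10-read cluster floor);
presence-matrix, chain and planted-loss recovery on 14-family
four-species nested libraries (genome sizes 3–9.1 Mb) in which every
family clears the detection threshold; and activity calibration on
20 libraries of 1e5 reads. These sizes keep the full suite within
minutes on one core while leaving every detectability margin explicit
rather than tuned. All randomness flows through user-supplied integer
seeds; `run_pipeline()` derives one stream per stage from the master
seed and stage name, so identical configurations are byte-identical
and stages remain independently reproducible.

## Known limitations

Substitution-only consensus building cannot represent length variants
within a family; families split by very high interspecies divergence
are reconciled only through the variant-grouping step; the linear
chain model deliberately excludes general trees (and labels ploidy
from user annotation, never inference); mapping is ungapped after
seeding, appropriate for short reads against short monomer references
but not for indel-rich data; and the >65% variant rule inherits the
elevated chance-similarity null of short A+T-rich monomers discussed
above.
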