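---
title: "Delineating a GH13 subfamily from conserved sequence regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating a GH13 subfamily from conserved sequence regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gh13sub)
```

## The problem

The α-amylase family GH13 is the largest polyspecific glycoside hydrolase
family, subdivided into dozens of numbered subfamilies. Family membership and
subfamily placement are decided almost entirely from sequence: up to seven
short, indel-free conserved sequence regions (CSRs) laid out along the
catalytic (β/α)~8~-barrel, a catalytic triad of aspartate (nucleophile, β4),
glutamate (proton donor, β5) and aspartate (transition-state stabilizer, β7),
and, for particular groups, diagnostic residues inside those regions. The
pentapeptide of CSR-V is the classical marker: `QPDLN` for the
oligo-1,6-glucosidase group, `MPKLN` for the neopullulanase group, and the
intermediary `MPDxN` shared by GH13_36 and the more recently delineated
GH13_46 group of cyclomaltodextrinase-like proteins, which additionally carry
an immunoglobulin-like N-terminal domain, a WW dipeptide on helix α3 between
CSR-V and CSR-II, an "aromatic" Y-x-Y end of CSR-II (x one of G/S/P), and a
glutamate directly after the proton donor in CSR-III.

`gh13sub` turns that delineation procedure into a reproducible pipeline:
curate candidates by the three membership criteria, locate the CSRs, score
the subfamily signature, compute alignment conservation and logo statistics,
and build bootstrapped distance trees. A synthetic-sequence generator with
ground-truth labels makes every stage testable offline.

## Membership criteria and their thresholds

A candidate is kept when all three classical criteria hold, evaluated in
this order (the first failure is reported):

1. **N-terminal domain** — the region upstream of the located CSR-VI must
   align locally (BLOSUM62, gap open 11 / extend 1) to the reference
   N-domain. The score threshold is a *fraction of the reference N-domain's
   self-score*, default 0.25. A ratio is used because an absolute score
   threshold would depend on the length and composition of the reference;
   0.25 comfortably separates homologous N-domains (ratios near 0.8 even at
   10% divergence) from unrelated sequence (ratios below 0.1).
2. **Seven CSRs** — each region must be located with confidence at least
   0.35 of the template self-score (see below). The WW stretch is a
   *signature* feature, not a membership criterion: genuine family members
   outside the GH13_46/GH13_45 groups lack it.
3. **Catalytic triad** — the residues at the fixed in-window offsets
   (CSR-II position 5, CSR-III position 5, CSR-IV position 6) must read
   exactly D, E, D.

Deduplication keeps one sequence per organism string (whitespace
normalized): the longest sequence wins, ties go to the lexicographically
smallest accession. Records without an organism are never merged. Signal
peptides are not predicted; sequences are analysed as stored.

## Locating the conserved regions

Each window is found by exhaustive *ungapped* scanning: the BLOSUM62 sum of
the template against every candidate start inside a band of ±40 residues
around the projected position, where the projection carries over the
reference's inter-window spacing from the previously located window. CSRs
are short indel-free motifs, so ungapped scoring is exact and fast, and the
±40 slack absorbs the between-subfamily length variation of domain B. The
confidence of a window is its score divided by the template self-score;
the default acceptance threshold of 0.35 is deliberately permissive so that
distant subfamilies remain locatable (needed for family-wide comparisons)
while random sequence is rejected. Both thresholds are exposed as arguments.

Two details matter for robustness:

* The seven CSRs form the projection chain; the 2-residue WW template is
  located afterwards, confined to the gap between the located CSR-V and
  CSR-II. Anchoring the chain on a 2-residue template is unstable (it can
  latch onto the `GW` start of CSR-II in neopullulanase-like sequences and
  derail the CSR-II search).
* Equal-scoring windows resolve to the start closest to the projected
  position, then to the smallest start. A pure smallest-start rule can be
  pulled one position off the true window when a point mutation creates an
  equal-scoring overlap (e.g. a tryptophan appearing directly before the
  real WW); the projection-first rule keeps recovery exact while remaining
  fully deterministic.

Coordinates are 1-based inclusive everywhere — internal structures, reports
and the anchor table — matching R string semantics; a single convention
avoids off-by-one drift.

The shipped reference is **synthetic**: a deterministic 602-residue
GH13_46-profile sequence built by the package's own generator (files and
functions are named accordingly). The real cyclomaltodextrinase query the
procedure was designed around is not redistributable inside the package;
any user-supplied reference plus anchor TSV can replace the surrogate.

## The signature verdict

Four features are scored per sequence: intermediary CSR-V (`MPDxN`),
aromatic CSR-II end (`Y[GSP]Y`), glutamate after the proton donor, and the
WW stretch. The GH13_46 call requires a valid triad, the intermediary
CSR-V, and a score of at least 3 of 4. The literature lists the exclusive
features but no decision rule, so the rule is the package's own: requiring
CSR-V plus most features tolerates the documented single FW variant of the
WW stretch while keeping neopullulanase- and oligo-1,6-glucosidase-like
sequences out (their CSR-V class already disqualifies them). The threshold
is exposed (`min_score`).

## Conservation statistics

* A column of a multiple alignment is `IDENTICAL` if gap-free with one
  residue; `STRONG_SIMILAR` if gap-free and contained in one Clustal strong
  group (STA, NEQK, NHQK, NDEQ, QHRK, MILV, MILF, HY, FYW); `GAPPED` if it
  contains any gap; otherwise `OTHER`. Percent identity/similarity are the
  column counts over the consensus length. Columns with gaps never count as
  conserved, matching Clustal's asterisk/colon semantics. The convention is
  documented rather than canonical: published percent values depend on the
  aligner and annotation convention used.
* Logo information content per column is $IC_j = \log_2 20 - H_j$ with
  $H_j$ the Shannon entropy of the observed residue frequencies. No
  pseudocounts and no small-sample correction are applied: at the set sizes
  the pipeline targets (~100 sequences) the correction is negligible, and
  the analytic test values (invariant column $= \log_2 20 \approx 4.32$
  bits, uniform $= 0$, 50/50 $= \log_2 20 - 1$) stay exact.
* Pairwise identity is computed over mutually ungapped columns; pairs with
  no overlap are reported missing.

## Alignment

The bundled aligner is deterministic and download-free. When every input
sequence has a located CSR set it uses **anchored blocks**: the seven CSR
windows become fixed, gap-free columns shared by the whole set, and each
inter-window segment (plus the N-terminal region and the C-terminal tail)
is left-justified and padded to its widest occurrence. This mirrors how
family-wide GH13 alignments are curated in practice — computer alignments
are manually adjusted so the CSRs line up — and it is exact for sets whose
members share a common architecture. When windows cannot be located for all
sequences, the aligner falls back to a classical center-star: the center is
the sequence sharing the most 4-mers with the rest, all others are globally
aligned to it (BLOSUM62, gap open 15 / extend 2), and pairwise alignments
are merged under once-a-gap-always-a-gap with insertions left-aligned.
Neither path replaces a progressive aligner for real, indel-rich data;
`align_sequences(method = "external")` shells out to `mafft` (or any
command with FASTA-in/FASTA-out semantics) for that purpose.

## Distances, trees, bootstrap, clusters

Distances are pairwise-deletion p-distances (mismatches over mutually
ungapped columns) or Poisson-corrected $-\ln(1-p)$, capped at
$-\ln(10^{-6})$ when $p$ reaches 1. Trees are built by standard
neighbor-joining — exact on additive matrices — with two documented
conventions: equal-scoring joins resolve to the smallest taxon-index pair,
and negative branch lengths are clamped to zero with the deficit moved to
the sibling edge. This distance/NJ machinery is a deliberate, desk-scale
stand-in for maximum-likelihood tree searches (WAG model) used in the
delineation literature: the claim under test is *cluster separation* of a
candidate subfamily, not edge-for-edge topology, and NJ on well-separated
groups answers that question in seconds. Bootstrap support resamples
alignment columns with replacement (default 100 replicates; the literature
convention is 500) and counts, per internal edge, the replicate trees
containing the same bipartition; bipartitions are canonicalized against the
lexicographically smallest taxon so keys agree across replicate trees.
Fixed seeds give bit-identical supports.

`cut_clusters(tree, k)` removes edges in decreasing length order (ties by
edge index) until the taxa fall into `k` groups. Removing only *internal*
edges cannot produce singleton-heavy partitions (an n-taxon tree has n−3 of
them), so the rule considers all edges; for well-separated groups the
longest edges are the inter-group internal edges and the two rules agree.

## The synthetic generator

`simulate_gh13_set()` emits sequences with the architecture the analysis
assumes: signal peptide (20 aa), a fixed 100-aa N-domain, the eight windows
embedded in profile-specific linkers, and a tail filling the sequence to a
length drawn uniformly from 588–616 residues (the span reported for the
GH13_46-like set the package models). Four profiles are available:
`GH13_46`, `OLIGO16` (`QPDLN`), `NEOPUL` (`MPKLN`) and `RANDOM` (a
divergent family member with no subfamily signature). Each profile is a
fixed skeleton; per-sequence variation comes from:

* `linker_mutation_rate` (default 0.10) — uniform substitutions outside the
  windows;
* `csr_mutation_rate` (default 0.03) — resampling of *non-diagnostic*
  window positions within the consensus residue's Clustal strong group.
  Diagnostic positions (the `MPDxN` anchor residues, the WW pair, the
  CSR-II terminal tyrosines, the post-donor glutamate, the triad) are
  invariant in the profile, emulating the near-invariance these sites show
  in the real subfamily; departures from them are modelled as explicit,
  countable corruptions (`BREAK_TRIAD`, `WW_TO_FW`, `DROP_CSR:<name>`,
  `DROP_NDOMAIN`) applied to a chosen number of records.

What the generator deliberately does **not** emulate: phylogenetic
correlation within a profile (sequences are a star around the skeleton),
indels inside windows or linkers (corruptions aside), subfamily-specific
N-domains (all profiles share one, so the N-domain filter passes for all),
and realistic amino-acid background composition (linkers are uniform).
Passing tests therefore demonstrate the correctness of the *procedure* —
filters reject exactly what they should, windows are recovered at known
coordinates, signatures and tree cuts recover planted labels — not
performance on real, indel-rich database sequences, for which the external
aligner and user-supplied references exist.

## Problem sizes and numerical choices

The test-suite and acceptance runs use 108-sequence single-profile sets
(the size of the modelled subfamily), 4×30 mixtures, 50 random additive
6-taxon matrices for the NJ oracle, and 25–100 bootstrap replicates —
sizes chosen so a full run completes in well under a minute while keeping
every statistic stable at the asserted thresholds. Tolerances: NJ path
lengths reproduce additive inputs to 1e-9; analytic logo values to 1e-9;
frequency rows sum to 1 within 1e-9. Deterministic tie-breaks are stated
next to each algorithm above; all stochastic steps take explicit seeds.

## Known limitations

* The anchored aligner assumes a shared domain architecture; sequences with
  large insertions between CSRs will accumulate padding columns.
* The verdict rule (intermediary CSR-V + ≥3/4 features) is a pragmatic
  decision rule, not a fitted classifier; borderline families sharing
  `MPDLN` (e.g. GH13_36-like sequences) are distinguished by tree
  placement, not by the verdict alone — the flags are all exported so
  downstream analysis can arbitrate.
* NJ trees approximate, and do not reproduce, published
  maximum-likelihood topologies; only cluster-level statements are made.
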