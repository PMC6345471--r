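---
title: "Designing mini-barcodes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing mini-barcodes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minibar)
```

## Overview

`minibar` estimates the shortest, most informative sub-region of a
species-labelled barcode alignment and carries that estimate through to a
deployable marker: a validated fragment, a pair of degenerate primers, and
an in-silico cross-amplification panel. This vignette explains the models
behind each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the procedure is genuinely underdetermined.

## The distance model

All divergences are Kimura 2-parameter distances,

$$d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q),$$

with $P$ and $Q$ the transition and transversion fractions over the sites
where *both* sequences carry an unambiguous base (pairwise deletion). K2P is
the de-facto standard for barcode work because it is the model used by the
major barcode repositories, and the package deliberately offers no
alternative models.

Two situations make a pairwise distance undefined and both yield a missing
value rather than an error, so that a scan over degraded data stays total:

* **saturation** — a log argument $\le 0$ (e.g. $P = 1$);
* **insufficient overlap** — fewer usable sites than
  `min_sites_frac` × region length (default 0.5). The floor exists because
  window-scale comparisons of heavily gapped or ambiguous records can
  otherwise produce wild distances from a handful of sites.

Missing pairs are excluded from window means, from the intra/inter
partition, and from candidate ranking; their counts are carried on the
distance object and surfaced as warnings. Before neighbor joining, taxa
involved in missing pairs are dropped greedily (most-missing first, with a
warning) rather than imputed — determinism and transparency over data
rescue. Negative NJ branch estimates are clamped to zero, the standard
practice, with pre-clamp values retained as an attribute.

## The window scan

Windows of lengths 100–230 bp (step 10 between lengths, shift 10 along the
alignment — all configurable) are scored on three criteria: mean K2P
distance (higher is more informative), the proportion of zero
non-conspecific distances (lower means fewer indistinguishable heterospecific
pairs), and the fraction of the full-length reference NJ tree's non-trivial
bipartitions recovered by the window's NJ tree. A species-level variant of
the congruence ("shallow": restricted to reference splits whose smaller side
is a set of conspecific individuals) is reported alongside, since those are
the clades that matter for identification.

How the three criteria combine into a "top two per length" is genuinely
open; the package uses the **sum of ranks** within each length class
(average ranks on ties, missing congruence ranked worst, composite ties to
the smaller start). Rank aggregation is scale-free, which matters because
the three criteria are incommensurable (a distance, a proportion and a
fraction of clades). The retained candidates are named `"<length>_a"`,
`"<length>_b"` in rank order.

Final arbitration between candidates is by tree comparison against the
reference: the K-score — pair every split of either tree (terminal branches
included, since a split absent from one tree is informative about branch
lengths too), rescale the comparison tree by the least-squares factor
$K = \sum b_i b'_i / \sum b'^2_i$, and take
$\sqrt{\sum (b_i - K b'_i)^2}$ — with the Robinson–Foulds distance as the
first tie-break, then greater length, then smaller start. The K-score is
preferred as the finer-grained statistic: RF is integer-valued and saturates
quickly at these taxon counts. All trees, including the reference, are
neighbor-joining trees on K2P distances: the selection signal is tree
*(in)congruence* between a window and the full-length data, which NJ
captures at a fraction of the cost of likelihood tree search, and NJ keeps
the scan deterministic.

Efficiency note: the scan precomputes cumulative per-pair transition /
transversion / usable-site counts over columns, so every window's full
distance matrix is obtained in O(pairs) time independent of window length.

## Barcode gap and separability

The barcode gap is computed on the raw empirical multisets — no trimming —
as min(interspecific) − max(intraspecific); a positive gap means the two
classes do not overlap at all. Because extremes are brittle, separability is
additionally summarised by the Jeffries–Matusita statistic computed from the
Bhattacharyya distance between the two classes summarised as univariate
normals (sample SDs, $n-1$):

$$B = \frac{1}{8}(\mu_1-\mu_2)^2\frac{2}{\sigma_1^2+\sigma_2^2}
  + \frac{1}{2}\ln\frac{\sigma_1^2+\sigma_2^2}{2\sigma_1\sigma_2}.$$

Two J-M conventions coexist in the literature — $\sqrt{2(1-e^{-B})}$, which
saturates at $\sqrt2 \approx 1.414$, and $2(1-e^{-B})$, which saturates
at 2 — and reported values under one convention are routinely compared
against the other's threshold. The package therefore always reports both,
labelled. Standard deviations are floored at $10^{-6}$ so a degenerate
(constant) class cannot blow up the ratio term; two constant classes with
equal means give 0 by continuity. Histogram bins default to a width of 0.01
on the distance axis, matching how these distributions are usually drawn.

## Primer design and in-silico PCR

The package reconstructs primers from the data (published studies report
primers but rarely the rule that produced them): per column the consensus is
the IUPAC code covering every unambiguous base at frequency ≥
`freq_threshold` (default 0.05, i.e. a variant carried by ≥ 5 % of
sequences is accommodated as degeneracy; rarer variants are left to the
mismatch budget). Gaps are excluded from the denominator; a column with no
qualifying base becomes `N`. Candidate placements of length 18–25 within a
60-column flank on each side of the selected window are scored by
degeneracy (ascending, capped at 32), then number of non-degenerate bases in
the 3′-terminal 3 positions, then proximity to the window; the reverse
primer is emitted as the reverse complement of its sense-strand consensus.
Melting temperatures are Wallace-rule ranges over the extreme degenerate
expansions — an ordering heuristic, not a thermodynamic prediction.

In-silico PCR slides each primer over each (ungapped) target: a site is
accepted when mismatches ≤ `max_mismatch` (default 2) *and* the 3′-terminal
`clamp_len` positions (default 2) match exactly — PCR is far more sensitive
to 3′ mismatches than internal ones. Success requires the forward site
upstream of the reverse site and a product length within `len_bounds`
(default 50–2000 bp). Failures are classified
(`no_fwd_site`, `no_rev_site`, `three_prime_mismatch`, `orientation`,
`length_out_of_bounds`) and returned as results, mirroring how an
amplification panel records per-sample outcomes.

## The synthetic-data generator

`simulate_dataset()` emulates the structure that makes mini-barcode design
work: clusters of near-identical conspecific sequences, divergent species,
one hypervariable window, and conserved flanks immediately around it where
primers can sit. Species radiate from a common ancestral sequence on a
**star phylogeny** and individuals from their species ancestor — sufficient
for every statistic the pipeline computes, and it keeps the calibration
closed-form. Each branch applies one multinomial substitution step per
site; a substitution is a transition with probability $\kappa/(\kappa+2)$
(default $\kappa = 2$), else a uniformly chosen transversion. The per-site
substitution probability is found by bisection (tolerance $10^{-6}$) so
that the *expected pairwise K2P distance over the whole alignment* equals
the requested `d_inter` (between species, default 0.15) or `d_intra`
(within species, default 0.005) — values chosen inside the ranges typically
reported for COI barcode datasets of crustaceans. Calibration requiring a
per-site probability above 0.75 is refused as infeasible.

Default layout (all configurable): 658 columns like the standard COI
barcode; the planted hypervariable window at columns 109–338 (230 bp)
evolving at 3× the background rate; 80 bp conserved flanks (0.2×)
immediately up- and downstream; background rate elsewhere. With 20 species
× 3 individuals this gives a 60-sequence alignment on which the default
scan takes a few seconds; all simulation-based tests and the acceptance
computation run at this scale.

What the generator does **not** emulate: codon structure and third-position
rate patterns, indels and alignment error, ambiguity codes (an option can
inject `N`s to exercise pairwise deletion), phylogeographic structure
within species, and non-star species phylogenies. Passing tests on
synthetic data therefore demonstrate that the estimator recovers a planted
signal under its own model assumptions — not that any particular real
alignment contains such a signal.

## Degenerate inputs and tie-breaking

* All-zero distance matrices produce a zero-length NJ tree; comparisons
  against an all-zero comparison tree flag $K$ as missing and fall back to
  $\sqrt{\sum b_i^2}$.
* Windows with fewer than three usable taxa are scored with missing
  congruence and flagged, never dropped from the report.
* Equal composite scores go to the smaller window start; equal K-scores to
  the lower RF, then the longer window, then the smaller start. All
  tie-breaks are deterministic, and the whole scan is reproducible
  byte-for-byte from the same inputs.
* NJ agglomeration order on exact ties follows the (deterministic) order of
  the underlying `ape::nj` implementation.

## Known limitations

The fragment estimator inherits the limits of its ingredients: NJ tree
congruence can plateau when many windows resolve the same shallow clades;
the J-M statistic assumes roughly normal distance classes and will flatter
strongly multimodal interspecific distributions; Wallace-rule Tm is crude;
and in-silico amplification says nothing about polymerase kinetics or
template quality. For taxonomically broad reference sets, the single global
barcode gap reported here can hide species-pair-level overlap — per-species
gap analysis is deliberately out of scope.
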