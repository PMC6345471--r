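# minibar

Design and in-silico validation of DNA mini-barcodes from a species-labelled
barcode alignment.

## The problem

Full-length DNA barcodes (typically the 658 bp COI region in animals) often
fail to amplify from degraded or fragmented DNA — museum specimens, ethanol-
stored plankton, larval stages such as lobster phyllosomas — and are longer
than many metabarcoding reads. A *mini-barcode* is a short (~100–300 bp)
sub-region of the standard barcode that retains enough species-diagnostic
signal to delimit taxa while being amplifiable from degraded templates.
`minibar` is for molecular ecologists and barcoding practitioners who have a
curated, aligned reference set and want to locate that sub-region, quantify
its reliability, and obtain primers for it.

## The method

Given an aligned set of sequences with species labels, the package:

1. **Scans sliding windows** (default lengths 100–230 bp in 10 bp
   increments, shifted by 10 bp) and scores each window by three criteria:
   high mean Kimura 2-parameter (K2P) distance
   `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` (P, Q = transition,
   transversion fractions under pairwise deletion); few zero pairwise
   non-conspecific distances; and high congruence between the window's
   neighbor-joining tree and the full-length reference NJ tree. The top two
   windows per length (sum of ranks) are retained as candidate fragments.
2. **Arbitrates between candidates** by comparing each window tree with the
   reference tree: the Robinson–Foulds symmetric difference (topology) and
   the K-score (topology + branch lengths after least-squares rescaling,
   `K = Σ b·b′ / Σ b′²`, `k_score = sqrt(Σ (b − K·b′)²)`). The fragment with
   the lowest K-score (ties: lower RF, longer, leftmost) wins.
3. **Validates the winner** by barcode-gap analysis: the gap is
   `min(interspecific) − max(intraspecific)` K2P distance, and class
   separability is summarised by the Jeffries–Matusita statistic
   `JM = sqrt(2(1 − e^(−B)))` (asymptote √2 ≈ 1.414; the `2(1 − e^(−B))`
   convention, asymptote 2, is also reported), with `B` the Bhattacharyya
   distance between the two distance classes.
4. **Designs degenerate IUPAC primers** in the conserved flanks of the
   winning fragment (threshold consensus, minimal degeneracy, 3′-clamp
   scoring) and **tests them by in-silico PCR** against every input sequence
   (mismatch budget + exact 3′ clamp), the computational analog of a
   cross-species amplification panel.

A seeded simulator generates species-structured alignments (near-identical
conspecifics, divergent species, conserved flanks, one planted hypervariable
window under a K2P substitution process) so the entire pipeline can be
exercised and benchmarked without sequence downloads.

## Worked example

```r
library(minibar)

sim <- simulate_dataset(simulation_config(), seed = 1)  # 20 species x 3
res <- run_full_design(sim$alignment)
print(res)
```

```
Mini-barcode design report
  input: 60 sequences, 20 species, 658 columns
Best mini-barcode fragment: 230_a (columns 111-340, 230 bp)
  K-score = 0.047654, RF = 34 vs full-length reference tree
  barcode gap: 0.1992 (present); J-M sqrt = 1.414, two = 2
  primers: F 5'-ATAKATARCTGAATCATT-3' / R 5'-AGCTTGATAGCCCCKATA-3'
  in-silico PCR: 60/60 targets, 20/20 species amplified
```

The scan retained 28 candidate fragments (top two for each of the 14 window
lengths) and selected the 230 bp window at columns 111–340 — recovering the
hypervariable region planted at columns 109–338 by the simulator. The
barcode gap of 0.199 (no overlap between intra- and interspecific K2P
distances) and a saturated Jeffries–Matusita statistic (1.414 under the
square-root convention, 2.000 under the two-form) mark the fragment as a
reliable diagnostic marker, and the primer pair designed in its conserved
flanks amplifies all 20 simulated species in silico.

`summary(res)`, `plot(res, "scan")` and `plot(res, "gap")` show the
candidate table, the per-window score profile and the distance histograms;
`write_design_artifacts(res, "out/")` writes all tables, trees, FASTA slices
and a JSON summary. Real alignments enter through
`read_alignment("my_barcodes.fasta")` (headers `id|Genus_species`). A thin
command-line front end with `simulate`, `stats`, `scan`, `gap`, `design`,
`ispcr` and `run` subcommands is installed at `inst/cli/minibar.R`.

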