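---
title: "Quantifying m6A methylome dynamics in 2C-like cells: models and design"
author: "m6adyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying m6A methylome dynamics in 2C-like cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6adyn)
```

## The biological question

Mouse embryonic stem cell cultures harbour a rare, transient subpopulation —
2C-like cells (2CLCs) — that re-expresses markers of the two-cell embryo
(Zscan4 genes, the MERVL endogenous retrovirus) before returning to the
pluripotent state. MeRIP-seq compares an antibody-enriched (IP) library with
a total-RNA (input) library to localise N6-methyladenosine (m6A) on
transcripts. `m6adyn` implements the downstream analysis that connects the
m6A methylome of 2CLCs to the behaviour of zygotic-genome-activation (ZGA)
transcripts: where m6A peaks sit on genes and repeat elements, which genes
are methylated in which state, how methylation couples to differential
expression and to the exit from the 2C-like state, and how fast methylated
transcripts decay once transcription is blocked.

Every stage can be run on synthetic data whose ground truth is known, so the
pipeline's operating characteristics (peak recall, enrichment sign patterns,
test calibration) are measurable rather than assumed.

## Coordinates and containers

All coordinates are 0-based, half-open — BED's native convention — and
GTF-like input is shifted on read. Interval sets are plain data.frames;
coverage is a `coverage_track` (fixed-width bins per chromosome plus a
library size); gene models carry exon vectors and CDS bounds from which a
3-bp stop-codon interval is derived exactly.

## Peak calling from IP vs input

For every sliding window of `window_bins` bins (default 2 × 50 bp), the IP
count is compared with a null mean equal to the input count scaled by the
library-size ratio, floored at 1 read. Two refinements keep the false-call
rate at its nominal level on realistic, overdispersed coverage:

1. **Excess dispersion.** Sequencing coverage is not Poisson. The caller
   estimates a genome-wide excess-dispersion coefficient `d` from the
   Poisson residuals of all windows (MAD within deciles of the null mean,
   then a regression of excess variance on the mean), and tests against
   NB(λ, 1/d). On Poisson data `d` fits ≈ 0 and the test reduces to the
   exact Poisson tail; `dispersion = 0` forces the pure Poisson test.
2. **Conditional ratio test.** At low coverage the scaled-input mean is
   itself noisy; the exact conditional test of two Poisson rates (binomial:
   IP out of IP + input with the library-size proportion) absorbs that
   noise. The window p-value is the less significant of the two tests, so
   both the high-coverage and the low-coverage failure modes are guarded.

Windows are BH-adjusted together; significant windows (q < 0.05) within one
bin's gap merge into peaks, with the summit at the maximum-IP bin and fold
enrichment `(IP RPM + 1)/(input RPM + 1)` over the merged span. On the
default simulation (fold 8, NB dispersion 0.1) this yields pooled precision
≈ 0.93 and recall ≈ 0.97 against the planted peaks, and under a fold-1 null
the called-peak genome fraction stays ≈ 0.01–0.04.

A deliberate omission: no local-lambda background and no fragment-model
shift — downstream stages consume only peak intervals, and external peak
BEDs can be substituted everywhere.

## The shuffle-null enrichment score

The enrichment statistic is the observed count of peaks per feature class
against the mean count over randomised peak placements. A peak counts
toward a class when **more than 50% of the peak's length** lies inside the
class's interval union (the threshold is strict, and the fraction is of the
peak — the natural reading of counting "peaks overlapping a region").
Shuffling preserves each peak's chromosome, length and strand and places
starts uniformly; draws may overlap each other and exclude nothing. The
score is

  E = log2((O + 0.5) / (Ē + 0.5)),

with Ē averaged over `n_draws` (default 100; a single-draw mode mimics a
one-shot shuffle tool). The pseudo-count 0.5 keeps empty classes finite; a
class with no intervals is reported with score 0 and a `degenerate` flag.
An empirical enrichment p-value `(1 + #draws ≥ O)/(1 + n_draws)` accompanies
the score. Feature classes are TSS windows (± 100 bp), 5'UTR / CDS / 3'UTR
(exonic bases partitioned at the CDS bounds, strand-aware), stop-codon
windows (± 200 bp, the one flank size the upstream analyses print), introns,
and the intergenic complement; TE classes (DNA/SINE/LINE/LTR) or LINE/LTR
families group repeat copies.

Chromosome-preserving placement was chosen over genome-wide placement
because it conditions on the peak's chromosomal context; with equal-length
chromosomes (the synthetic default) the two nulls coincide.

## Per-gene methylation status, intensity, and profiles

A gene is m6A⁺ when at least one peak passes the same >50% rule against the
union of its exons and stop-codon window. Intensity is
`log2((IP RPM + 1)/(input RPM + 1))` summed over either the stop ± 200 bp
window or the gene's assigned peaks — both variants are used upstream
without an explicit formula, so both are implemented and labelled in the
output. Metagene profiles excise introns, flip minus-strand genes so
position runs 5'→3', rescale to a fixed number of bins and average
RPM-normalised per-bp signal across features; full-length MERVL copies use
their genomic span. Replicate concordance follows the top-2000-by-CV
convention: CV is computed on the linear fold enrichment, Pearson
correlation on the log intensities of the selected genes.

## Differential expression and m6A dynamics

DEGs are called per gene from CPM-normalised replicates: Welch's t on
log2(CPM + 1), BH correction, and the printed strict cut-offs FC > 2 and
FDR < 0.05. CPM rather than FPKM is the default because the synthetic
transcripts have arbitrary lengths; the fold-change contrast is unaffected
by within-gene length constants. Dynamics classification is the pure
mapping of the (2CLC, ESC) status pair: gain (+,−), keep (+,+), lose (−,+),
none (−,−). The association of methylation with ZGA membership among
up-regulated DEGs is the 2×2 Fisher exact test; the per-class fold-change
contrasts use the rank-sum test. By default the class contrast uses all
classified genes (matching the fold-change-by-class box-plot reading); an
`up_only` switch restricts to up-DEGs.

## Statistical primitives

The rank-sum and Fisher tests are implemented from first principles with
exact small-sample modes, because their small-n behaviour is itself under
test: the rank-sum test enumerates all C(n, nx) labelings when n ≤ 12 and
no ties are present (midranks plus tie-corrected, continuity-corrected
normal approximation otherwise), and the Fisher test sums hypergeometric
probabilities not exceeding the observed table's. Benjamini–Hochberg is the
step-up procedure aligned to input order; the odds ratio uses a Haldane
correction only when a cell is zero. R's own implementations serve as
independent cross-checks in the test suite, never as the implementation.

## Single-cell state assignment

The three states of the 2CLC → pluripotent transition are defined
biologically by marker expression: 2CLC-marker-high cells, cells expressing
both marker sets (transient), and pluripotency-marker-high cells. After
per-cell `ln(1 + 10^4 * count / total)` normalisation, each cell gets one
score per marker set (mean normalised expression). Thresholds come from an
equal-variance two-component Gaussian mixture fitted to each score
distribution by EM, thresholding at the midpoint of the component means; if
the components collapse (means closer than a tenth of the score range) the
60th percentile is used instead. Equal variances are deliberate: with an
unconstrained fit the narrow high-expression mode can swallow the split
point. Cells are 2CLC if only the 2CLC score clears its threshold,
pluripotent in the mirror case, transient otherwise. Graph-based clustering
is intentionally out of scope — the marker definition *is* the cluster
identity here — though `select_hvg` (variance standardised against a
running-median mean–variance trend) is retained as a utility.

The state contrast compares per-gene fold changes
`(mean_pluripotent + ε)/(mean_2CLC + ε)` (ε = 0.01 guards empty means)
between m6A⁺ and m6A⁻ ZGA gene sets by rank-sum on log2 FC.

## Decay and ΔΔCt

qPCR relative expression is `2^-ΔΔCt` against a reference gene and a
calibrator sample. Actinomycin-D courses are fitted as first-order decay:
least squares of ln(value) against time through the origin after
normalising the course to 1 at t = 0 — closed-form, deterministic, and
adequate for multiplicative noise; a free-intercept mode exists but is not
the default. k is clipped at zero, t½ = ln 2 / k (infinite when k = 0), and
genes undecayed in both conditions get a flagged ratio of 1. The inhibitor
contrast compares t½(inhibitor)/t½(ctrl) between m6A⁺ and m6A⁻ sets by
rank-sum on log ratios.

## The synthetic-data generator

The generator emulates exactly the structure the analysis assumes, with
ground truth emitted alongside every dataset:

- **Genome & annotation** — default 2 chromosomes × 100 kb, 20 coding genes
  (2–4 exons, valid CDS, non-empty UTRs, stop codon inside the last exon),
  40 TE copies in intergenic space with MERVL as a long (full-length
  flagged) LTR family.
- **Methylation** — per gene per condition, Bernoulli with probability 0.8
  for ZGA (or otherwise activated) genes in 2CLC and 0.3 elsewhere; LTR
  copies 0.8 vs 0.1 for other repeat classes. True peaks (200 bp) sit in
  the stop-codon window with probability 0.6, otherwise uniformly over
  CDS/3'UTR — so the stop-codon enrichment ordering is recoverable but not
  hard-coded.
- **Coverage** — negative-binomial bins (dispersion 0.1) with means
  proportional to host-transcript expression, times fold 8 inside true
  peaks in IP libraries only, renormalised to 2 × 10⁵ reads per library.
  Because both libraries are depth-matched, the *measured* peak IP/input
  ratio is the configured fold diluted by the extra IP mass — the tests
  therefore check the fold relative to the non-peak background, which is
  exact.
- **Expression** — Poisson counts with log-normal replicate noise; ZGA
  genes 8× up in 2CLC, pluripotency genes 8× up in ESC, and 30% of "other"
  genes also activated so the up-DEG set contains non-ZGA members (without
  which the 2×2 association table would be degenerate).
- **Single cells** — Poisson counts along a latent position u ∈ {0, ½, 1}.
  Marker genes follow the state definitions (2CLC markers high for u < 1,
  pluripotency markers high for u > 0, so transient cells express both);
  non-marker ZGA genes decline as exp(−k·u·T) with k the
  methylation-dependent decay rate (0.5 vs 0.2 h⁻¹) and T = 6 h the
  effective time the transition spans — the single number that converts
  per-hour rates into a per-transition decline, chosen once as a plausible
  exit timescale.
- **Decay courses** — exp(−k t) at t = 0, 1, 2, 4, 8 h with 10% log-normal
  noise at t > 0; the inhibitor halves k for m6A⁺ genes only.
- **Sequence** — random DNA with GGACT (an RRACH instance) planted every
  40 bp inside true peaks, enough for the fixed-motif density check; no
  other sequence realism is attempted.

What the generator does *not* emulate: isoform structure, GC/mappability
bias, ambient RNA and doublets, batch effects, graded (non-binary)
methylation stoichiometry, and transcription during the decay chase.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated generative assumptions, not robustness to every
artefact of real libraries.

## Numerical choices

- Enrichment pseudo-count ε = 0.5; intensity and fold-enrichment
  pseudo-count 1 RPM; state-FC pseudo-mean ε = 0.01 — each recorded in its
  output.
- Strict inequalities at all printed cut-offs (FC > 2, FDR < 0.05, > 50%
  overlap).
- Deterministic tie-breaks: gene id in rankings and HVG selection; BH
  q-values are clamped to never undercut their p-value by floating-point
  error.
- All randomness flows through explicit seeds; shuffles assign placements
  in a canonical peak order so results are invariant to input permutation.
- Exact rank-sum enumeration switches to the normal approximation at
  n > 12 or with ties (exact mode refuses midrank ties).

## Problem sizes

The test suite and the acceptance script run the toy scale throughout: the
default 200 kb genome for interval, coverage and enrichment stages;
300-gene panels (4 × 500 kb) for differential-expression and association
experiments; 150-gene panels with 120 cells for the single-cell chain;
50–200 replicate seeds for power and calibration estimates; 1000 shuffle
draws for the analytic-oracle comparison and 1000 resampled tables for test
calibration. These sizes give the quoted operating characteristics
reproducibly on a single CPU in minutes.

## Known limitations

- The window caller is a stand-in for a full peak caller: no summit
  refinement below bin resolution, no broad/narrow distinction, and exact
  reproduction of any external tool's peak set is a non-goal.
- The >50% rule is applied to the peak's length; the upstream description
  does not say which side the fraction refers to, and the feature-side
  reading would change counts for features smaller than half a peak.
- One shuffle-null variant (chromosome-preserving) is implemented; a
  genome-wide placement null would differ on genomes with heterogeneous
  chromosomes.
- ΔΔCt assumes perfect doubling efficiency; decay fitting assumes a single
  exponential compartment.
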