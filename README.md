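# m6adyn

Analysis of N6-methyladenosine (m6A) RNA methylation dynamics in 2C-like
cells (2CLCs) from MeRIP-seq coverage, for epigenomics and stem-cell
researchers working with IP/input methylome data and its coupling to
transcript behaviour.

2CLCs are a rare embryonic-stem-cell subpopulation that transiently
re-expresses two-cell-embryo markers (Zscan4, the MERVL retrotransposon).
`m6adyn` implements the statistics that connect their m6A methylome to
zygotic-genome-activation (ZGA) transcript dynamics:

- **Peak calling** from binned IP vs input coverage: a sliding-window count
  test against the library-scaled input mean (pseudo-mean 1 read), with a
  robustly estimated excess-dispersion NB null combined with the exact
  conditional Poisson-ratio test, BH correction across windows, and merging
  of significant windows into peaks.
- **Shuffle-null enrichment**: the enrichment score of peaks over gene
  features (TSS, 5'UTR, CDS, stop codon, 3'UTR, intron, intergenic) and TE
  classes/families (DNA/SINE/LINE/LTR; MERVL, L1, ...),

  `E = log2((O + 0.5) / (Ē + 0.5))`,

  where `O` counts peaks with more than 50% of their length inside the
  feature union and `Ē` is the mean count over chromosome- and
  length-preserving uniform shuffles. `E > 0` means enrichment.
- **Methylation status and intensity** per gene (`m6A⁺` iff ≥ 1 assigned
  peak; intensity `log2((IP RPM + 1)/(input RPM + 1))` over the stop ± 200 bp
  window or the gene's peaks), metagene profiles, replicate concordance on
  top-CV genes, set overlaps.
- **Dynamics**: DEGs at the strict cut-offs FC > 2 and FDR < 0.05
  (Welch's t on log2 CPM + BH), the gain/keep/lose/none classification of
  the per-gene (2CLC, ESC) status pair, and the Fisher-exact association of
  methylation with ZGA membership among up-regulated DEGs.
- **Single-cell transition**: ln-normalisation, marker-score state
  assignment (2CLC / transient / pluripotent via a 2-component Gaussian fit
  per score), cluster means, and the rank-sum contrast showing m6A⁺ ZGA
  transcripts decline faster from 2CLC to pluripotent than m6A⁻ ones.
- **Decay**: ΔΔCt relative expression (`2^-ΔΔCt`) and first-order decay
  fits (`t½ = ln 2 / k`) of actinomycin-D time courses, with
  methyltransferase-inhibitor half-life-ratio contrasts.
- **Statistical primitives** written from first principles with exact
  small-sample modes: two-tailed Wilcoxon rank-sum (full enumeration at
  n ≤ 12), Fisher's exact 2×2, Benjamini–Hochberg, Welch's t, Pearson r.
- **A synthetic-data generator** reproducing the statistical structure the
  analysis assumes — stop-codon-proximal peaks with planted RRACH motifs,
  preferential methylation of ZGA transcripts and LTR/MERVL copies,
  three-state single-cell transitions, exponential decay courses — with
  ground truth for scoring every stage.

## Worked example

Simulate a toy methylome (2 chromosomes × 100 kb, 20 genes, 40 TE copies),
call peaks, and score feature enrichment:

```r
library(m6adyn)

sim   <- simulate_annotation(sim_config(seed = 1))
ip    <- simulate_coverage(sim, "2CLC", "IP")
input <- simulate_coverage(sim, "2CLC", "input")

peaks <- call_peaks(ip, input)
nrow(peaks)
#> [1] 18

feats <- derive_features(sim$genes, sim$genome)
enrichment_table(peaks, feats, sim$genome, seed = 2, n_draws = 100)
#>      feature observed expected   score empirical_p
#> 1        TSS        0     0.34 -0.7485      1.0000
#> 2       UTR5        0     0.00  0.0000      1.0000
#> 3        CDS        4     1.13  1.4651      0.0594
#> 4 stop_codon        5     0.82  2.0589      0.0099
#> 5       UTR3        0     0.01 -0.0286      1.0000
#> 6     intron        0     1.30 -1.8480      1.0000
#> 7 intergenic       12    15.03 -0.3131      0.9703

status <- gene_m6a_status(peaks, sim$genes, condition = "2CLC")
sum(status$status)
#> [1] 6

peak_benchmark(peaks, sim$truth$peaks[sim$truth$peaks$condition == "2CLC", ])
#> precision 1, recall 1
```

The stop-codon window carries the strongest positive enrichment
(score 2.06, empirical p = 0.0099: 5 peaks observed where uniform placement
expects 0.82) and intergenic space is depleted — the signature of an mRNA
methylation mark concentrated near stop codons. The 12 "intergenic" peaks
are the methylated TE copies, which lie outside gene spans. Six of the 20
genes are m6A⁺, matching the planted truth exactly here (the caller's
precision and recall are both 1 on this seed).

Spike-in QC reproduces the GLuc/CLuc double-ratio arithmetic:

```r
qc <- simulate_spike_in(sim$cfg, true_enrichment = 10)
spike_in_qc(qc$gluc_ip, qc$gluc_input, qc$cluc_ip, qc$cluc_input)$ratio
#> [1] 11.14   # passes the default threshold of 5
```

See the vignette (`vignettes/m6a-methylome-analysis.Rmd`) for the models,
parameter choices and design rationale of every stage.

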