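# mrpr

Synthetic-data re-implementation of the computational analyses used to
characterize a prophage **master repressor**: a DNA-binding protein that
silences the lytic genes of a temperate phage by binding a conserved ~15-bp
operator element repeated across the prophage genome. The package is for
computational biologists who want the analysis chain behind such a
characterization as reusable, tested R functions — and for anyone who needs
a convolution-based bacterial peak caller, a ZOOPS-EM motif finder, HDX-MS
reduction rules, or textbook ITC/nanoDSF fits without a vendor pipeline.

Four analysis stages, each paired with a generator that produces its inputs
with known ground truth:

| Stage | Core method | Key functions |
|---|---|---|
| ChAP-seq peak calling | mean-subtracted Ricker kernel `w(x) ∝ (1 − x²/σ²)e^{−x²/2σ²}` with adaptive width (σ = half the median half-height width of candidate peaks), derivative-sign summit detection, background normalization, replicate merging | `estimate_expected_width()`, `build_kernel()`, `call_peaks()`, `normalize_and_merge()` |
| Operator-motif discovery | zero-or-one-occurrence-per-sequence (ZOOPS) EM over both strands, phase-shift refinement, χ²-penalized width selection, log-odds genome scanning | `discover_motif()`, `scan_genome()`, `write_meme()` |
| HDX-MS reduction | six-criterion peptide QC, dual-protease merging, shortest-peptide / closest-C-terminus residue assignment, differential profiles | `filter_and_merge()`, `residue_uptake()`, `differential_uptake()` |
| Binding & stability fits | one-set-of-sites (Wiseman) isotherm `B = ½[(X+nM+K_d) − √((X+nM+K_d)² − 4XnM)]` with displaced-volume correction; Boltzmann sigmoid `low + (high−low)/(1+e^{(T_m−T)/slope})`, T_m = inflection | `isotherm_heats()`, `fit_itc()`, `fit_dsf()` |

Everything takes and returns tibbles, fitted objects have `tidy()` /
`glance()` methods, and each result type has an `autoplot()`.

## Worked example

`run_demo()` chains the sequencing arm end to end: it builds a 130 kb
prophage-sized genome with ten planted operator sites (15-bp consensus,
mutated 10% per position), simulates three replicate coverage tracks
(20× enrichment on 50× Poisson background), calls and merges peaks,
discovers the motif, and scans the genome:

```r
library(mrpr)
demo <- run_demo(seed = 1)
print(demo)
#> == synthetic ChAP-seq demo ==
#> seed: 1
#> genome: 130000 bp, 10 planted sites
#> expected peak width: 233 bp
#> merged peaks: 10
#> motif: width 15 bp, consensus TGTTCACTAAAGGAC
#> genome hits at threshold: 9
#> summit recovery: max |distance| = 0 bp
```

All ten planted sites come back as merged peaks, every summit lands on its
planted center, and motif discovery over widths 8–20 selects exactly the
planted 15-mer (`default_consensus()`). The merged peak table carries the
convolution score, the background-normalized intensity and the replicate
support:

```r
head(demo$peaks[, c("start", "end", "summit", "conv_score",
                    "normalized_intensity", "n_replicates")], 3)
#>   start   end summit conv_score normalized_intensity n_replicates
#> 1  4321  4598   4459    111515.               29224.            3
#> 2 20684 20961  20822    111699.               29226.            3
#> 3 32846 33123  32984    111807.               29278.            3
```

The biophysics arm fits simulated titrations and melt curves back to their
generating truths:

```r
fit <- fit_itc(simulate_itc(itc_params(n = 1, kd = 0.238, dh = -10), seed = 4))
print(fit)
#> <itc_fit> one set of sites
#>   n  = 1.003 +/- 0.011
#>   Kd = 0.2599 +/- 0.044 uM
#>   dH = -9.902 +/- 0.15 kcal/mol

fit_dsf(simulate_dsf(tm = 47.8, noise_sd = 0.002, seed = 4))
#> <dsf_fit> Boltzmann sigmoid
#>   Tm    = 47.81 +/- 0.025 degC
#>   slope = 1.96 degC
#>   baselines 0.8007 -> 0.9998
```

A single noisy titration at 2% heat noise recovers the 0.238 µM affinity
within its standard error; a single melt curve recovers the 47.8 °C melting
temperature to a few hundredths of a degree.

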