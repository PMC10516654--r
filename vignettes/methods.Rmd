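---
title: "Models and methods behind mrpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mrpr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpr)
```

`mrpr` re-implements, as reusable and tested functions, the computational
analyses used to characterize a prophage master repressor: genome-wide
binding-site detection from ChAP-seq coverage, operator-motif discovery from
the detected peaks, residue-level reduction of hydrogen/deuterium-exchange
(HDX-MS) measurements, and model fits for two biophysical assays (isothermal
titration calorimetry and nanoDSF thermal shifts). Because the original
measurements require wet-lab data, every pipeline stage comes with a
synthetic-data generator with known ground truth; the package's tests are
parameter-recovery experiments against those truths.

## Peak calling from coverage tracks

The caller operates on per-base read coverage for one contig. Its model
assumption is that a binding site produces a smooth, single-summit,
approximately Gaussian enrichment bump on a locally flat background.

**Adaptive width.** The expected peak width is estimated from the data in
three steps: all (plateau-aware) local maxima exceeding three times the
genome-wide mean coverage are candidate summits; each candidate's width is
the distance between the nearest flanking positions where coverage drops
below half the summit height; the expected width is the median of those
widths. On noise-free rectangular bumps this returns the exact rectangle
width, which the tests assert. If no candidate exceeds the threshold the
caller refuses to guess and asks for an explicit `fixed_width`.

**Kernel.** Coverage is convolved with a Ricker kernel (the negative second
derivative of a Gaussian), `w(x) = (1 - x^2/sigma^2) exp(-x^2/(2 sigma^2))`,
truncated at four sigmas. Two design choices matter here:

* *Sign.* The negative second derivative is used so that enrichment bumps
  produce positive responses; "higher than" score filters are then
  meaningful.
* *Scale.* `sigma = expected_width / 2`, so the spacing between the kernel's
  positive-lobe zero crossings (`2 sigma`) equals the expected width — the
  matched-filter reading of expanding the kernel to the expected peak width.

Truncation breaks the kernel's exact zero sum, so the weights are
mean-subtracted over the truncated support. This restores, exactly, the
invariant that the response to constant coverage is zero (asserted at
`1e-9`), which makes peak calls invariant to adding a uniform background.

**Detection, scoring, filtering.** Summits are positions where the discrete
first derivative of the convolution response changes from positive to
negative; for zero-derivative plateaus the leftmost position is taken so the
output is deterministic. Each summit's convolution score is the response at
the summit; the peak interval spans the flanking response zero crossings.
Retained peaks need raw summit coverage above `threshold_mult` (default 3)
times the genome mean — the same multiplier used for width estimation, reused
as the final filter because no separate filtering rule is part of the
procedure being modeled — plus a positive convolution score.

**Edges.** Convolution uses reflect padding by default. The chromosome the
procedure models is circular but the track is a linear representation;
reflect padding avoids inventing boundary peaks while keeping the response
length equal to the track length. Wrap-around convolution is available with
`circular = TRUE`.

**Normalization and replicate support.** Per replicate, the normalization
coefficient is the total track coverage minus the summed coverage of all
detected peaks, i.e. the coverage attributable to background. The default
(`"ratio"`) reports `raw_intensity / coefficient * 1e6` — a peak's share of
background coverage, scaled for readability — which is invariant under
global rescaling of a track, a property the tests assert. The source wording
for this step can also be read with the opposite orientation
(`coefficient / raw_intensity`); that reading is available as
`normalization = "literal"`. Peaks from different replicates are merged when
their summits lie within half the expected width; merged peaks report the
number of supporting replicates and mean intensities.

## Motif discovery and scanning

Peak sequences (±50 bp around each summit by default) feed a
position-weight-matrix (PWM) motif finder implemented as ZOOPS-EM: each
sequence contributes zero or one motif occurrence, both strands are
searched, and the occurrence prior is re-estimated each iteration. The
0-order background is estimated from the input and symmetrized over
complementary bases, which makes discovery exactly reverse-complement
symmetric (asserted to `1e-6`). PWM columns carry a Dirichlet pseudocount of
0.25 per base, so EM is a MAP-EM whose penalized objective is non-decreasing
by construction; the per-iteration trace is stored on every fitted motif and
the monotonicity asserted in each test run.

Two practical failure modes of plain EM are handled explicitly:

* *Local optima in registration.* EM frequently converges to the true motif
  shifted by one or two columns. After the best of the random restarts
  (default 10) converges, the window is shifted by ±1 and ±2 columns
  (vacated columns reset to background), EM is re-run warm-started, and any
  improvement is kept, iterating until no shift helps.
* *Width selection.* Candidate widths (default 8–20) are compared by
  `2 (LL_motif - LL_bg) - 3 w * penalty`. A background column's chance
  likelihood gain behaves like a chi-square statistic with the column's 3
  free parameters — inflated by the registration freedom, but not growing
  with the number of sequences — so the per-parameter penalty is the fixed
  critical value `qchisq(0.995, 3) / 3` rather than a BIC-style `log n`
  term. The constant was calibrated on simulations of the target regime
  (ten ~100 bp sequences, a 15-bp consensus mutated at 10% per position):
  across the calibration plateau (per-column penalties of roughly 10–13)
  the planted width is selected almost always, whereas weaker penalties
  admit chance-enriched flank columns and stronger ones trim true columns.
  A corollary worth knowing: with very few sequences (about 5 or fewer) a
  true column's gain may fall below the critical value — width selection
  deliberately loses power rather than overfitting.

Scanning computes log-odds (PWM versus background, in bits) at every
position on both strands and returns hits above a threshold; agreement with
a brute-force per-position scorer is asserted exactly. Motifs export in
MEME minimal text format so third-party scanners can consume them.

## HDX-MS data reduction

Peptide-level measurements carry the six quality-control fields used for
acceptance: identification in at least 2 of 3 non-deuterated samples,
intensity ≥ 10 000 counts, length ≤ 30 residues, ≥ 2 fragmentation
products, mass error ≤ 25 ppm, and retention-time deviation ≤ 0.5 min.
Filtering removes rows failing any criterion (idempotently), rows from both
protease digestions are concatenated, and uptake is averaged over
replicates, retaining the replicate SD.

Residue-level assignment follows the rule set of the modeled workflow
literally: a residue covered by a single peptide inherits that peptide's
uptake; with overlapping peptides the shortest covering peptide wins; among
equal-shortest peptides the one whose C-terminus lies closest to the residue
wins. Ties beyond that break to the smallest peptide id for determinism.
No proline or N-terminal exclusion and no back-exchange correction are
applied — the modeled procedure states none. The implementation is checked
against a brute-force enumerate-sort-take-first oracle on randomized peptide
maps, at 100% agreement.

Differential profiles subtract two residue-level profiles where both are
defined and classify residues as increased/decreased/unchanged by whether
`|delta|` exceeds a threshold at any labeling time. The significance
convention for such comparisons is not standardized; the default threshold
is twice the pooled replicate SD, overridable.

The HDX generator tiles a protein with overlapping peptides from two
simulated digestions and computes uptake from first-order exchange,
`d2o_fraction * (1 - exp(-k t))` per residue, summed over the peptide, at
the labeling times {10, 30, 100, 1000, 10000} s. `d2o_fraction` defaults to
0.9, matching a 10-fold dilution into heavy-water buffer. What it does not
emulate: intrinsic-rate sequence dependence, EX1 behavior, back-exchange,
proline non-exchange, or isotope-envelope effects — so passing tests show
the *reduction rules* are implemented correctly, not that the generator is a
spectral model of real HDX.

## Binding and stability models

**ITC.** The forward model is the single-class independent-sites (one set of
sites) isotherm under displaced-volume accounting: each injection dilutes
the cell contents (the expelled material is taken at the average of pre- and
post-injection concentrations), bound titrant follows the quadratic
mass-action solution, and the measured heat of injection *i* is
`Q_i - Q_{i-1} + (v_i/V0)(Q_i + Q_{i-1})/2` with `Q = V0 * dH * bound`.
The default schedule is a 200 µl cell of 20 µM macromolecule (the DNA
duplex) titrated from a 250 µM syringe in 13 injections — 0.4 µl priming
then twelve 3 µl injections. The syringe concentration is not part of the
modeled protocol's record (it was chosen there to saturate the DNA); 250 µM
delivers ~2.3 molar equivalents by the last injection, which saturates a
sub-micromolar site. The quadratic solution is verified against a
root-finding equilibrium oracle at `1e-8` relative.

The fitter runs bounded Levenberg–Marquardt least squares over
`(n, log10 Kd, dH)` — `Kd` in log space with bounds `[1e-4, 1e4]` µM, `n` in
`[0.1, 10]` — from a fixed multi-start grid, so fits are deterministic given
the data. The priming injection is excluded by default (standard practice;
its volume makes its heat unreliable in real instruments). Noise-free
round trips recover the generating parameters to `1e-6` relative; with a
true `dH` of zero the affinity is unidentifiable and the fit flags it
through a degenerate standard error rather than failing.

**nanoDSF.** Melt curves are F350/F330 fluorescence ratios on a temperature
grid; the model is the two-baseline Boltzmann sigmoid
`low + (high - low)/(1 + exp((tm - T)/slope))`, with the melting temperature
reported as the inflection point. Initialization takes `tm` from the
maximum of the smoothed derivative and the baselines from the curve ends;
curves without a detectable transition (range below ten times the
point-to-point noise) produce a classed error instead of a spurious fit.
The default simulated conditions — 20–95 °C at 0.5 °C steps, baselines
0.80–1.00, slope 2 °C, noise SD 0.002 ratio units — describe a typical
capillary-format experiment of this kind.

## Problem sizes, determinism, degenerate inputs

The recovery experiments in the test suite and acceptance script use the
study-scale scenario end to end: a 130 kb genome, ten planted operator
sites carrying a 15-bp consensus mutated at 10% per position, 20-fold
enrichment over a 50× Poisson background, three replicates; twenty
simulated titrations and melt curves per ground truth. These sizes are the
package's chosen study conditions; each block runs in seconds to about two
minutes.

All randomness flows through per-call integer seeds (replicate *r* of a
track uses `seed + r - 1`; EM restart *r* at width *w* uses a seed derived
from `seed`, *w* and *r*), so every generator and both fitters are
bit-reproducible and the global RNG state is never disturbed. Degenerate
inputs fail loudly with classed conditions: constant coverage
(`mrpr_no_candidate_error`), peaks swallowing all coverage
(`mrpr_degenerate_background_error`), transitionless melt curves and
non-converging titration fits (`mrpr_fit_error`).

## Known limitations

* The peak caller assumes single-summit peaks; closely spaced sites whose
  bumps merge into one summit are reported as one peak.
* The motif finder's selection score stands in for an E-value ranking; it
  orders widths sensibly but is not a calibrated significance statistic,
  and it needs roughly six or more occurrence-bearing sequences to have
  power.
* The ITC model covers a single site class only; sequential or multi-site
  binding is out of scope, as are baseline integration of raw thermograms.
* The coverage generator plants smooth Gaussian enrichment on an i.i.d.
  background; real tracks carry mappability structure, GC bias and
  fragment-length effects the caller never sees in testing.
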