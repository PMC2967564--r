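---
title: "Model-based peak-list extraction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based peak-list extraction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model behind `extract_peaks()`, the meaning and
defaults of its parameters, what the synthetic-spectrum generator does and
does not emulate, and the numerical and design decisions that are not
obvious from the function documentation.

## The model

### Isotopic distributions by iterative convolution

The isotopic distribution (ID) of a molecule is represented as a vector of
relative abundances indexed by *isotope position*: the nominal mass shift
(number of extra neutrons) relative to the monoisotopic isotopologue.
Isotopologues of equal nominal shift are grouped into one position; the
average mass spacing between adjacent positions is taken to be constant at
1.00235 Da, the value dominated by the ¹³C–¹²C difference in
peptide-like compositions.

`formula_distribution()` builds the ID one atom at a time. If `a` is the
abundance vector of the molecule so far and `b` that of the next atom, the
joint outcome is the outer product `a b^T`, and summing its anti-diagonals
(all configurations with the same total shift) gives the new vector:
`(a ⊗ b)[k] = Σ_{i+j=k} a[i] b[j]` (`convolve_abundances()`). For `n`
identical atoms the package uses binary exponentiation of the single-atom
vector rather than `n` repeated convolutions. Vectors are truncated to 30
positions throughout; truncation is exact for the retained positions,
because discarded positions can only ever contribute to positions beyond
the cut. The unit tests verify the convolution engine against an
independent exhaustive isotopologue enumeration (closed-form multinomial
probabilities per element) for every CHNOS molecule with up to 10 atoms.

### Reference residues and TID tables

The elemental composition of a detected peak is unknown, so its theoretical
ID (TID) is approximated by that of an artificial sequence of identical
average residues with the same monoisotopic mass. Three residue models are
built in: Senko's Averagine (111.054 Da), leucine (113.084 Da, the most
common real residue, sharing its formula with isoleucine), and an updated
average residue recomputed from a recent SwissProt release. For the updated
residue only its elemental composition is treated as authoritative; its
monoisotopic mass is derived from the composition (≈111.118 Da).

Every artificial sequence of `n` residues receives one water terminus
(peptide convention). Fractional residue counts are resolved to an integer
formula by rounding each element and adjusting the hydrogen count so the
integer formula's monoisotopic mass matches the fractional one within half
a hydrogen mass; the *reported* monoisotopic mass stays that of the
fractional formula. TIDs for `n = 1 … N` are precomputed into a table up to
`mass_limit` (20000 Da by default; the pipeline extends lazily to
170000 Da when a spectrum requires it) and interpolated position-wise,
linearly in mass, at query time. Interpolation error against a directly
computed formula is small because adjacent rows differ by one residue
(~111 Da) and abundances vary smoothly with mass.

### The double model

Isotope peaks of a charge-`Z` species are `1/Z` apart in m/z; a peak of
width `FWHM = m/z / RP` resolves them iff `m/z / RP < 1/Z` (strict). Two
regimes follow:

* **Resolved** — the reference peak of the fit is the monoisotopic one.
  Since the monoisotopic peak need not be the *detected* local maximum, the
  fit tries anchoring the detected peak at every isotope position from 0 up
  to the most-likely position `k*`.
* **Unresolved** — only the envelope apex is measurable. The reference is
  the most likely peak (positions `k* ± 1` are tried), and the monoisotopic
  mass is recovered by inverting the mapping `M0 ↦ M0 + k*(M0) · delta`,
  stored as a piecewise-linear interpolation over the TID table rows
  (`fit_most_likely_model()`).

### Detection, threshold, extraction

Candidates are local maxima of the *maximal curve*: the moving-window
maximum of the spectrum with window width `m/z / RP` (computed in O(1) per
point with a sparse range-maximum table). The intensity threshold assumes
the detected local maxima in a window are dominated by noise whose maxima
spread in a Gaussian way: a Gaussian is fitted robustly — median for `mu`,
MAD for `sigma` — and the threshold is `mu + 2*sigma`, linearly
interpolated between window centres. Window widths scale inversely with a
proteome mass-density model (wider windows where real peaks are rare), and
windows are merged until each holds at least 30 local maxima.

The extraction loop repeatedly takes the lowest-m/z surviving candidate
above the threshold and fits TIDs over all charges, residues, coarse
(whole-isotope-position) and fine (grid-resolution) shifts. A TID is
rendered as a Gaussian comb with `sigma = ref_mz / (2.35482 · RP)`, scaled
so the curve equals the observed intensity at the anchor, on top of the
fitted region's minimum intensity (treated as residual local baseline).
The score is the weighted mean absolute difference between curve and
spectrum at the evaluation points, normalised by the reference intensity —
dimensionless, so one acceptance threshold transfers across spectra.
Accepted fits are subtracted and the candidates they explain (fitted curve
above 80% of the observed intensity near a TID position) are dropped.

### Replicate functionality

Peaks of one species co-vary across replicate measurements; peaks of
different species do not. With ≥3 replicates, `use_replicates = TRUE`
weights each evaluation point by the (clamped) Pearson correlation between
its intensities and the reference peak's intensities across replicates, so
an overlapping foreign species barely contributes to the score; candidates
correlating ≥0.8 with an accepted reference are removed with it. With ≥2
replicates, `align = TRUE` corrects per-region integer-grid misalignment
by maximising each replicate's correlation with the representative over the
most informative half of the region's points, accepting a shift only if
the full-region correlation does not decrease. Shift recovery is exact
up to the replicate consensus: if no replicate is unshifted, a common
offset remains.

## Parameters and defaults

* `rp_in`, `rp_grid` (15 log-spaced multipliers in [1/2, 2]) — the nominal
  instrument RP rarely matches the data, so the effective RP is chosen from
  `rp_in * rp_grid` by minimising the mean fitting score of the
  maximum-intensity peak of each of `n_intervals = 4` equal-point
  intervals. RP estimation always uses charge-1 trial fits, even when
  `z_max > 1`: allowing charge switching between trial RPs lets a fit at
  half the RP and twice the charge mimic the true envelope, flattening the
  score profile, while a fixed wrong charge penalises all trial RPs
  equally. A single-value `rp_grid` pins the RP.
* `score_threshold = 0.35` — acceptance bound on the normalised score; the
  value trades recall against false fits and transfers across spectra
  because the score is dimensionless.
* `tid_prune_ratio = 1e-3` — TID positions below 1/1000 of the TID maximum
  are ignored when rendering.
* `removal_fit_ratio = 0.8` — a candidate explained to more than 80% by an
  accepted fit is removed with it.
* `baseline_passes = 2`, `baseline_window = 0.05` — the baseline is the
  running mean of the moving-window minimum, subtracted with clamping at
  zero; two passes remove the residual envelope the first pass leaves under
  wide humps. **The window (a fraction of the grid length) must exceed the
  isotopic-envelope width**: at very low resolution (e.g. 20 kDa at RP 500
  the envelope FWHM is 40 Da) the default window clips the envelope itself
  and must be widened (the low-resolution examples use 0.3).
* `esi_mode = FALSE`, `charge_prior_lambda = 0.05` — under electrospray
  ionisation low charges are less probable; the optional prior multiplies
  the score by `1 + lambda (z_max - Z)/z_max`.
* `qc_min_corr = 0.4` — replicates correlating below 0.4 with the
  representative are dropped before fitting. No intensity normalisation is
  ever applied: each replicate contributes in proportion to its total ion
  current.

## The synthetic generator

`simulate_spectrum()` / `simulate_replicates()` render each species' TID as
a Gaussian comb at the stated RP (abundance = height of the most likely
peak), add an exponentially decaying baseline and i.i.d. Gaussian noise,
and, per replicate, multiply each species' abundance by an independent
log-normal factor of given CV (unit mean; independence across species is
what makes cross-replicate weighting informative) and shift the whole
trace by a rounded Gaussian number of grid steps.

The generator deliberately does **not** emulate: centroided data,
mass-dependent peak-shape asymmetry (real TOF peaks are not Gaussian),
heteroscedastic or multiplicative detector noise, chemical noise (matrix
adducts), detector saturation, calibration drift within one spectrum, or
non-integer replicate misalignment. Conclusions from simulated recovery
rates therefore transfer to real data only as upper bounds.

## Numerical choices

* Threshold Gaussian fit by median/MAD rather than trimmed moments: trimmed
  moments are biased low by construction on pure noise, while median/MAD is
  unbiased there and equally robust to a minority of signal peaks.
* Evaluation points: each kept TID peak contributes its apex grid point and
  both neighbours. With `z_max > 1` the midpoints between adjacent TID
  peaks are evaluated as well — a fit at half the true charge matches every
  other peak of a higher-charge envelope and is only betrayed by the
  interleaved peaks it cannot explain. With `z_max = 1` the points are the
  reference stencil plus three points half a FWHM apart to the *left* of
  the monoisotopic position, where no isotopic signal of the same species
  can interfere.
* Moving-window maxima via a sparse range-maximum table (O(n log n) setup,
  O(1) per query), so detection stays linear-ish in spectrum length.
* TID tables are cached in-session per residue and mass limit, and
  optionally on disk (`cache_dir`) as plain text.

## Open decisions and limitations

* The score is an L1 mismatch at a handful of points; a likelihood-based
  score with an explicit noise model would allow principled acceptance
  levels instead of the fixed 0.35.
* The method favours recall: on noisy spectra a fraction of noise maxima
  above the threshold is accepted as weak fits (low intensity, score close
  to the threshold). Downstream filtering by intensity and score, or
  replicate-based weighting, is expected (see the README example).
* The updated-average-residue composition is used as given; small
  inconsistencies in its published mass are resolved in favour of the
  composition.
* Charges beyond `z_max` are never considered, and species whose envelopes
  extend beyond the acquisition grid are not fitted.
* Alignment shifts are integers on the acquisition grid; sub-grid
  misalignment is not modelled.
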