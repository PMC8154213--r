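---
title: "Methods: models, parameters and design choices in desiscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in desiscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desiscreen)
```

`desiscreen` analyzes raster-scanned DESI mass-spectrometry images of
reaction spots arrayed on a membrane grid, the readout format used for
plate-based biocatalyst screening. This vignette documents the underlying
models, the tunable parameters and their defaults, the numerical choices, and
the limits of what a passing synthetic test establishes.

## 1. Isotopologue envelopes and isotope interference

The envelope of a formula is the convolution across elements of each
element's multinomial isotopologue distribution, computed on centroided
(mass, abundance) lists with IUPAC 2021 representative isotope masses and
abundances embedded as data. Only the elements C, H, N, O, P, S, F, Cl, Br
and singly protonated/deprotonated ions are supported; ion masses use the
proton mass (H minus an electron), so envelope base peaks coincide with
`monoisotopic_mz()`.

**Peak aggregation.** Peaks are merged per *nominal isotopologue unit* — the
integer offset M+k from the lightest peak — at their abundance-weighted mean
mass. An earlier design used a fixed 0.01 Da chain-merge tolerance; that rule
is order-dependent exactly at its boundary (the 81Br or 37Cl substitution
sits 0.009–0.011 Da from the 13C2 substitution), so convolving elements in
different orders could split probability mass differently. Unit grouping is
associative under convolution — the element-wise convolution then agrees with
one-shot isotopologue enumeration to < 1e-12 — and is the natural convention
for the 0.2 Da extraction windows used downstream. The cost is that fine
isotope structure within one unit is never resolved, which this instrument
class cannot resolve anyway. Envelopes are truncated at 1e-6 total abundance
(below any plotted dynamic range) and renormalized.

The practical consequence of the M+2 unit is the screen's false-positive
mechanism: an imine → amine reduction raises the mass by only 2.016 Da, so
the substrate's M+2 isotopologue falls inside the product channel.

```{r}
env <- isotope_envelope("C12H15NO2", "M+H")  # dehydrosalsolidine ion
interference_fraction(env, monoisotopic_mz("C12H17NO2", "M+H"), 0.2)
```

About 1.3% of the substrate's base-peak intensity appears at the product m/z
— a low-intensity positive "beneath" every substrate-containing well.

One deliberate non-agreement: the deoxyfluorinated sugar phosphate
C6H12FO8P computes to an `[M−H]−` of 261.018 Da, while screening literature
sometimes quotes a nominal 261.1 for this ion class. The computed value is
reported unchanged.

## 2. Plate geometry and channel assignment

Coordinates are millimetres, origin at the membrane top-left, x right /
y down; pixels are 0-based and row-major, and a pixel belongs to the cell
containing its center (half-open intervals). Cells default to 5 mm — a
25 mm² area per sample. The ROI of a well is the central square left after
trimming a margin (default 10% per side); the trimmed-off border frame of
the *same* cell supplies the background estimate, which makes the correction
robust to slow row/column intensity drift, unlike a single global blank.

Channels are formed greedily in ascending m/z: species whose m/z fall within
one window (default 0.2 Da, the standard processing window) of the first
member share a channel. Isomeric substrates and products therefore multiplex:
88 isomeric kinase reactions are viewable on a single product channel.
Assignment is invariant to the row order of the species table.

## 3. The synthetic-data generator: the stated world

The generator emulates the statistical structure the analysis assumes — not
DESI plume physics, membrane chromatography, or vendor rebinning.

| Parameter | Default | Why |
|---|---|---|
| cell size | 5 mm | grid scored at 5 mm × 5 mm per sample |
| pixel size | 500 µm | the routine acquisition pixel |
| stage speed | 2000 µm/s | with 500 µm pixels: 25 s/sample at zero overhead |
| spot FWHM | 2 mm | a dried 0.5 µL spot is compact inside its 5 mm cell; the exact diameter is unreported, so it is a parameter |
| response factor | 2e4 counts/mM | arbitrary instrument gain; per-compound, because ionization efficiencies are unknowable a priori |
| saturation level K | 1 mM | response I = rf·c/(1+c/K) saturates above ~1 mM |
| total conc. per well | 0.1 mM | top of the demonstrated 5–100 µM linear range |
| baseline | 1 count/centroid | small additive offset so background subtraction has work to do |
| noise | SD = noise_scale·√I, default 0.05 | signal-dependent Gaussian as a Poisson surrogate; no noise model is reported |
| m/z jitter | 0.005 Da SD | emulates ~20k resolution/rebinning wobble |
| drift times | substrate 5 ms, product 8 ms, SD 0.5 ms | placeholders (real drift times are not printed); 6 SD apart, comfortably above the ≥3 SD regime the gating tests assume |

Spot profiles are isotropic Gaussians truncated at the (possibly translated)
cell footprint. With a drift dimension, each species' intensity is spread
over bins with Gaussian weights at its drift center, normalized to preserve
the total. All randomness flows from one integer seed; the manifest records
it, and an identical seed reproduces the dataset bit-identically. Intensities
are quantized to 32-bit float precision at generation time, because imzML
stores 32-bit intensities — this makes the write→read round trip exactly
lossless rather than "equal within float32".

What a green synthetic test does *not* establish: correct behaviour under
spray-direction bias, raster lag, per-well spot-shape variation, membrane
affinity differences, or real ionization-efficiency spreads. The conversion
formula P/(P + r·S) needs the product/substrate response ratio r; it defaults
to 1, and cross-compound conclusions drawn under that default are
semiquantitative at best.

## 4. imzML dialect

Files are imzML 1.1 pairs: processed mode, 64-bit m/z, 32-bit intensity,
little-endian, no compression. imzML has no standard ion-mobility axis, so a
drift dataset is written as one spectrum per (pixel, drift bin), each scan
tagged with userParams `drift_bin` (1-based index) and `drift_time_ms`, and
the full bin-center vector repeated in scanSettings as
`drift_bin_centers_ms`; standard viewers simply see several spectra per
coordinate. The integrity hash stored in fileContent is MD5 (CV accession
IMS:1000090) rather than SHA-1 — base R ships an MD5, and the imzML CV
accepts either. The 16-byte ibd UUID is derived from the MD5 of the binary
payload, keeping whole files byte-reproducible. Continuous-mode files are
treated as profile data and centroided on read by local-maximum picking
(plateaus keep the left-most point). Missing coordinates are padded with
empty spectra under a single counting warning.

## 5. Quantification, calibration, registration

**ROI sums.** Per well and channel: raw sum over the trimmed ROI; background
= median of the cell's border frame; corrected = max(raw − background·n_ROI,
0). A well is flagged `empty` when corrected ≤ 3·MAD(border)·n_ROI (the
boundary is `≤`, so a perfectly blank noise-free well — corrected 0, MAD 0 —
is flagged).

**Calibration.** OLS of summed intensity against concentration. Saturated
points are those falling >20% below an initial line anchored on the three
lowest concentrations; anchoring low is deliberate — an all-point initial
fit is dominated by the leverage of a saturated top standard and would flag
the *low* points instead. R² is the squared Pearson correlation of retained
points; LOD is the ICH-style 3.3·σ/slope with σ the residual SD. On
noise-free linear data this returns R² = 1 to machine precision and recovers
the generator's response factor exactly through the ROI geometry.

**Registration.** Spots are 4-connected components above an automatic
threshold (median + 25% of the dynamic range); their intensity-weighted
centroids are matched to well centers. The translation is found by a coarse
half-pixel grid search under a truncated quadratic loss plus a penalty of
cap/2 per on-membrane well left unmatched — the penalty separates a
translation from its whole-cell alias, which otherwise explains every
interior spot equally well; an unexplained bright spot costs more (cap) than
an unmatched well, which may legitimately be blank, and exact ties resolve
to the smaller shift. Spot components touching the image border are clipped
at the membrane edge and carry biased centroids: they participate in the
coarse search (they are precisely the evidence that breaks aliases) but are
excluded from the least-squares refinement. Recovery is within half a pixel
for translations up to a full cell.

## 6. Mobility gating and interference subtraction

A drift gate is `expected_center ± 2·SD`, with the SD estimated by a moment
fit over the contiguous flank region of the profile mode nearest the
expected center. Two SD captures ≈95% of a Gaussian drift peak while
excluding a second species ≥3 SD away almost completely; the width is
configurable. If another mode's center would fall inside the gate, the
boundary is tightened to the midpoint (with a warning). A gate covering all
bins reproduces the ungated image bit-exactly because gated and ungated
extraction share one code path.

Without a mobility dimension, the predicted interference fraction times the
corrected substrate sum is subtracted from the corrected product sum,
floored at zero; wells whose entire product signal is explained within 3×
the ROI noise estimate are flagged `isotope_false_positive`. The operation
marks its output and is idempotent. When both mobility data and envelopes
exist, gate first, then subtract the residual leakage.

## 7. Hits, rendering, throughput

Threshold-mode hit calling compares corrected sums against mean + 3·SD of
*declared* blank wells — blanks are declared in the species table, not
inferred, because screening plates contain known controls. Ranking ties
break by row-major well label, making the order total and deterministic.
Heat maps are rendered by a dependency-free PNG encoder (deterministic
byte-for-byte, which a plotting device would not guarantee); per-channel
normalization shows each channel's own dynamic range, global normalization
keeps intensities comparable. Throughput is
`ceil(cell/pixel) × (cell/speed + overhead)` seconds per sample: 25 s at the
default geometry with zero overhead, and the commonly quoted ≈44 s/sample
corresponds to ≈1.9 s of per-line overhead — the overhead is an explicit
parameter, never defaulted silently, because its composition (turnaround vs
inter-sample moves) is not published.

## 8. Library-design statistics

`expand_codon()` expands IUPAC degenerate codons through the standard
genetic code (via Biostrings); `library_size()` multiplies *residue-level*
set sizes, collapsing codon redundancy and excluding stops — screened
variants are proteins, so NNN × NNN is reported as 400 (= 20²) with the
codon-level 4096 as an attribute. Clones for coverage F of V equiprobable
variants use the per-variant confidence formula n = ln(1−F)/ln(1−1/V),
rounded to nearest (`ceiling` available). For F = 0.95, V = 36 this gives
106 — reproduced by Monte-Carlo in the test suite. A full coupon-collector
"every variant at least once" criterion would demand more clones; the
per-variant formula is the default because it is the convention the printed
screening numbers follow. Codon-usage weighting is deliberately out of
scope.

```{r}
design_table(list(double_RBT = c("RBT", "RBT")))
```

## 9. Known limitations

* Singly charged ±H adducts only; no fine isotope structure; no CCS
  calibration — the drift axis is arbitrary bins.
* Translation-only registration (no rotation/scale); one membrane per file.
* Absolute cross-compound quantification is out of scope by design.
* The acceptance-grade stochastic checks (conversion RMSE, false-positive
  removal, calibration R²) run at deliberately reduced plate counts and
  sizes to stay inside test-time budgets; they are scaled-down analogues of
  the instrument-level figures, not reproductions of them.
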