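---
title: "Methods: duplex stable-isotope glycan quantitation from MALDI-MS peak lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplex stable-isotope glycan quantitation from MALDI-MS peak lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyquant)
library(tibble)
```

# The problem

In duplex stable-isotope labeling glycomics, two glycan samples are
derivatized with a light and a heavy variant of the same reducing-end tag
(for example a d0/d2 oxime pair spaced by about 2 Da, or a combined
^18^O + deuterium reduction label spaced by about 3 Da), mixed, and
measured together in one MALDI-TOF spectrum. Every glycan then appears as
two interleaved isotope envelopes, and the relative abundance of the two
samples is the intensity ratio of the two channels.

Two properties of glycan isotope distributions make the naive ratio
wrong:

1. With a small label spacing $\Delta$ (2–3 Da), the light channel's
   $+\mathrm{round}(\Delta)$ isotopologue falls exactly on the heavy
   channel's quantitation peak, inflating the heavy intensity.
2. As glycan mass grows, the most abundant (apex) isotopologue moves off
   the monoisotopic peak, so quantifying at the apex rather than the mono
   peak improves sensitivity — but the apex must be predicted from the
   elemental composition.

`glyquant` implements the full chain from an ASCII peak list to
overlap-calibrated ratios: composition databases, theoretical isotope
patterns, centroiding, deisotoping, exhaustive matching, channel pairing
and ratio calibration.

# Composition databases

A glycan composition is a count vector over the five monosaccharide
classes Hex, HexNAc, dHex, NeuAc, NeuGc, with residue (dehydro) formulas
Hex = C~6~H~10~O~5~, HexNAc = C~8~H~13~NO~5~, dHex = C~6~H~10~O~4~,
NeuAc = C~11~H~17~NO~8~, NeuGc = C~11~H~17~NO~9~. The default database is
combinatorial: every composition with Hex ≤ 12, HexNAc ≤ 7, dHex ≤ 5,
NeuAc + NeuGc ≤ 4 and free mass ≤ 4,500 Da, the common count envelope of
mammalian N-glycans. The `"human"` variant excludes NeuGc and is exactly
the NeuGc-free subset of the `"mammalian"` variant. Curated biosynthetic
filtering beyond these bounds is deliberately out of scope — the
enumeration is transparent and users with a vetted list can load it with
`read_glycan_db()`. A combinatorial database necessarily contains more
entries than a curated one; the matching stage reports *all* candidates
within tolerance precisely so that such over-coverage is visible rather
than silently resolved.

All masses derive from one constants table (CIAAW/NIST monoisotopic
masses and isotope abundances; electron mass 0.000549 Da). Adduct m/z
accounts for the electron:
$m/z = (M + m_{\text{adduct}} - z\,m_e)/|z|$.

Derivatization presets: "free end" (light = H~2~O), "reduced end"
(alditol, light = H~2~O + H~2~), "2-AB" (light = H~2~O + C~7~H~8~N~2~),
"PFBHA" (light adds C~7~H~4~F~5~NO; heavy is the d2 form, Δ = 2.0126 Da)
and "GREDIL" (alditol with one ^18^O and one ^2^H, Δ = 3.0105 Da).
Design notes on two open points:

* The PFBHA light element map C~7~H~4~F~5~NO reproduces published
  reference m/z values for the sodiated derivatives within 1.1 mDa; the
  small residual is consistent with a lower-precision fluorine mass in
  the original calculations and is well inside the 50 ppm matching
  window.
* Whether a "reducing end" preset should denote the native reducing
  sugar or the borohydride-reduced alditol is ambiguous in common usage;
  we expose both ("free end" and "reduced end").

# Theoretical isotope patterns

`isotope_pattern()` computes the unit-mass-binned isotopologue
distribution by per-element binomial/multinomial expansion convolved
across elements (exponentiation-by-squaring on truncated abundance
vectors). Because all terms are non-negative and convolution entry $k$
depends only on entries $\le k$, tail truncation leaves every kept
offset exact; the test suite verifies agreement with exhaustive
isotopologue enumeration to 10^-9^ per offset.

Choices that matter:

* **Unit-mass binning.** MALDI-TOF cannot resolve isotopic fine
  structure, so offsets are aggregated at nominal mass and spaced
  1.0033548 Da (^13^C–^12^C) per charge on the m/z axis.
* **Label atoms are isotopically pure.** D and ^18^O in tags are modeled
  as fixed-mass pseudo-elements with no natural spread. To first order
  this is what label chemistry delivers, and it makes the light-channel
  pattern the correct reference for both channels in the calibration.
* **Truncation.** Trailing offsets below 10^-6^ of the maximum are
  dropped and at most 15 offsets are kept; every default-database glycan
  fits in that window.
* **Charge-carrier atoms are part of the ion pattern.** K carries 6.7%
  ^41^K two bins up; ignoring it would bias calibrated ratios of K+
  adducts by several percent.
* Apex ties break toward the lower offset. Along a hexose homopolymer
  series the apex moves from the first to the second isotopologue near
  2.4 kDa (the tests assert the 2.0–2.6 kDa window), and up to 3 kDa the
  8th isotopologue stays below 1% of the apex — which is why a label
  spacing above 8 Da needs no correction at all, and smaller spacings
  are corrected as below.

# Spectral preprocessing

`read_peaklist()` reads the two-column ASCII exports of vendor software
(tab/space/comma separated), skipping and counting non-numeric lines.
Noise is the median (default) or mean of nonzero intensities times a
coefficient (default 2); both are exposed because instruments differ.
For noise-free synthetic data, pass `noise_level = 0` — estimating
"noise" from a clean stick list would measure signal instead.

Profile data are centroided by Gaussian fitting: each local maximum
above the noise floor claims a window extending while intensity falls,
and a log-parabola least squares on the upper part of the peak (exact
for a noise-free Gaussian) yields the centre and height; windows with
fewer than `min_points` (default 4) points fall back to an
intensity-weighted centroid. Adjacent maxima whose separating valley
stays above 80% of the lower apex are treated as noise ripple on one
physical peak and merged — without this, noise occasionally splits one
peak into two centroids that would then be double-counted. Peak height
(not area) is the intensity measure throughout, matching what centroided
MALDI exports provide.

Deisotoping is greedy and left-to-right after *signal filtration*:
peaks below `snr_min` (default 10) are removed first, since sub-noise
bumps otherwise bridge spurious chains at fractional spacings and
misassign charge. Each surviving unconsumed peak seeds chains at
spacings $1.0033548/z$ for $z = 1..3$; the peak closest to the expected
grid position (within `spacing_tol`, default 0.05 Th) continues a chain;
the longest chain wins, ties toward lower charge; chains with fewer than
`min_isotopes` (default 3) peaks are discarded. The phrase "more than
three isotopes" in common tool descriptions is read as a minimum of 3
isotopic peaks, the usual deisotoping convention; the stricter reading
is available as `min_isotopes = 4`.

Envelope intensities are addressable by offset and are the *sum of all
surviving peaks* within `spacing_tol` of the envelope grid position.
This is the load-bearing choice for quantitation: species closer than
the tolerance are indistinguishable at MALDI-TOF resolution, so when a
heavy monoisotopic peak sits 6 mTh from a light isotopologue the
envelope reads their sum — exactly the quantity the calibration formula
expects.

# Matching, pairing and calibration

Matching is exhaustive and molecular-weight-based: every (composition,
adduct, channel, charge) candidate whose theoretical monoisotopic m/z
lies within the ppm tolerance (default 50) of an envelope's mono m/z is
reported, ranked per envelope by absolute ppm error. No exclusive
assignment is attempted; ambiguous near-isobars (e.g. a sodiated
Hex5HexNAc4 against a potassiated Hex4HexNAc4dHex1) are both reported
for downstream inspection. A constant instrumental offset can be removed
before matching with `calibration_offset`.

Quantitation reads the envelope intensity at the apex offset of the
full-ion theoretical pattern (falling back to the mono offset when the
apex lies beyond the detected envelope). With label spacing $\Delta$ and
$d = \mathrm{round}(\Delta)$ (half away from zero: 2.0126 → 2, 3.0105 →
3), the calibrated ratio is

$$\mathrm{Ratio}_{LH} = \frac{I_{light}}{I_{heavy} - I_{light} \cdot c},
\qquad
c = \frac{A[q + d]}{A[q]},$$

where $A$ is the light channel's theoretical pattern and $q$ the
quantitation offset. On noise-free data the correction is exact: the
measured heavy intensity is $r_H A[q] + r_L A[q+d]$ and the subtracted
term cancels the overlap contribution identically, which the tests
assert to 10^-6^ across mixing ratios 0.1–10 and both label spacings.
If the corrected heavy intensity is not positive the pair is flagged
`overlap_dominated` and no ratio is reported. Both directions
(`ratio_LH` and `ratio_HL`) are emitted, since mixing conventions vary
between experimental designs; the uncalibrated `ratio_raw` is kept so
the size of the correction is visible.

Pairing joins matches with identical (composition, adduct, charge) and
opposite tags whose observed mono separation equals $\Delta/z$ within
tolerance. In profile data the overlapped heavy mono usually merges with
the light isotopologue into one centroid consumed by the light
envelope, so no standalone heavy envelope exists; the heavy partner is
then recovered from the light envelope's own intensity ladder at offset
$q + d$, *gated on the measured intensity exceeding the light channel's
predicted contribution by more than 2%*. The gate keeps a genuinely
light-only sample unpaired (its ladder intensity equals the prediction)
while recovering duplex partners down to a few percent heavy fraction.
Exactness below 2,250 Da holds because the apex equals the mono peak
there; above the apex crossover the light channel's apex intensity also
carries a heavy contribution that the published correction does not
model, a known limitation of the method itself.

# The synthetic-data generator

`render_sticks()` places each member's full-ion pattern at its exact
theoretical positions, with heavy sticks at the light m/z plus the
*exact* label delta over charge (2.012553 Da for a d2 pair, 3.010523 Da
for ^18^O+D) — not the rounded value — reproducing the true mass
relationship of the labels; only the calibration uses the rounded
offset. Sticks within 0.1 mTh are summed. `render_profile()` turns each
stick into a Gaussian of the same height with FWHM 0.1 Th at m/z 1,000
(a typical reflectron MALDI-TOF resolution of 10,000) scaling linearly
with m/z, sampled at 0.01 Th, plus an optional constant baseline and
seeded additive Gaussian noise clipped at zero. A fixed seed makes
rendering bit-identical.

The default study conditions mirror the published duplex designs: d0/d2
oxime-style pairs (Δ = 2.0126 Da) on glycans such as Hex3HexNAc3,
Hex3HexNAc6, Hex3HexNAc7, Hex5HexNAc2 at heavy:light 10:1, 5:1, 1:1,
1:5, 1:10, and a 3.0105 Da reduction label for serum-type panels. What
the generator does *not* emulate — detector saturation, matrix cluster
chemical noise, baseline drift, mass-dependent resolution deviations —
bounds what passing tests show: they validate the algorithms under
ideal-instrument assumptions, not robustness to every artifact of real
acquisitions.

Problem sizes used by the test and acceptance suites are chosen to keep
a full run in a few minutes: the database-wide isotope-interference scan
covers all ~5,200 sub-3,000 Da compositions, envelope-recovery rendering
covers the whole ~9,100-entry database, the match-stage round-trip and
noisy-profile replicates run on seeded samples (150 compositions; 20
replicates per mixing ratio, asserting the mean recovered ratio within
5%).

# Worked example

```{r example}
db <- glycan_db("mammalian")
d2 <- derivatization("d0/d2", light = "H2O", heavy = "OD2")
mix <- mixture_spec(
  tibble(composition = "Hex3HexNAc2", adduct = "Na+", ratio_hl = 5),
  deriv = d2)
cfg <- search_config(db = db, deriv = d2, noise_level = 0)
run <- run_pipeline(render_sticks(mix), cfg)
tidy(run)[, c("composition", "adduct", "calibr_ratio", "ratio_raw",
              "ratio_HL", "flag")]
glance(run)
```

The raw heavy/light ratio is inflated by the overlap; the calibrated
column returns the planted 5:1 exactly.

# Known limitations

* Quantitation above the apex crossover (~2.4 kDa here) corrects only
  the light-into-heavy overlap, not the reverse direction.
* No decoy/FDR scoring of matches; a combinatorial database plus 50 ppm
  at high mass yields deliberate ambiguity for manual review.
* No baseline subtraction, smoothing or internal-standard recalibration;
  only a constant mass offset is supported.
* Monoisotopic peaks are taken as the first envelope member — no
  averagine-style inference, which is adequate for glycans below
  4.5 kDa where the mono peak is visible.
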