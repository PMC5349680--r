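---
title: "Identifying cone-outer-segment-specific membrane proteins from fraction proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying cone-outer-segment-specific membrane proteins from fraction proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosfrac)
```

## The problem

Rod and cone photoreceptors differ in light response, morphology and
metabolism, and those differences must ultimately trace back to differences in
the proteins each cell type expresses — above all in the outer segment (OS),
the compartment that runs phototransduction. Purified rod and cone
preparations can be sheared and separated on a sucrose gradient into an
OS-membrane-rich upper fraction and an inner-segment (IS)-rich lower fraction,
for both rods and cones, giving four membrane fractions: ROS-, RIS-, COS- and
CIS-rich. Shotgun LC-MS/MS of the washed membranes of each fraction then
yields four protein lists. The inference problem this package addresses is:
given those four lists and the known cross-contamination between fractions,
which proteins are present in the cone outer segment *specifically or
dominantly*?

The gradient does not separate compartments cleanly — the COS-rich fraction
carries several percent of the inner segment's membranes, and because a cone's
IS has roughly six times the volume of its OS, "a few percent of the IS" can
rival the OS content in protein mass. The method therefore never treats
presence in the COS-rich fraction as evidence by itself; everything rests on
*comparisons* between fractions.

## Abundance index: emPAI

Protein amounts are compared through the exponentially modified protein
abundance index. For a protein with $N_{\mathrm{obsd}}$ distinct identified
peptides out of $N_{\mathrm{obsbl}}$ observable in-silico tryptic peptides,

$$\mathrm{emPAI} = 10^{N_{\mathrm{obsd}} / N_{\mathrm{obsbl}}} - 1,$$

which is approximately proportional to the protein amount in the analyzed
sample. "Observable" means a tryptic peptide (cleavage after K or R, not
before P) whose monoisotopic mass falls in the instrument-detectable window,
by default 800–4500 Da with 0 missed cleavages. Both window and missed
cleavages are configurable (`digestion_rule()`); the defaults are the
conventional choices for this index and changing them changes
$N_{\mathrm{obsbl}}$ for every protein consistently.

Two conventions deserve emphasis because the index is nonlinear:

* **Distinct-peptide counting.** $N_{\mathrm{obsd}}$ counts distinct peptide
  sequences, not spectra, and replicate experiments are pooled by the union
  of distinct peptides before computing the index.
* **Linear cell normalization.** emPAI values measured on membranes from
  different cell numbers are rescaled linearly to a common reference count
  (default $5 \times 10^4$ cells, configurable via `cells_reference`; the
  source experiments report values per $5 \times 10^4$ cells in the main
  candidate table). Linearity is the index's own working assumption —
  "emPAI is proportional to amount" — and we adopt it as a convention rather
  than claim it is exact.

## The specificity statistic and the exclusion rules

For each protein the share

$$s = \frac{\mathrm{emPAI}_{\mathrm{COS}}}
           {\mathrm{emPAI}_{\mathrm{COS}} + \mathrm{emPAI}_{\mathrm{CIS}}}$$

measures the portion detected in the COS-rich fraction out of its total
across the cone fractions. `build_candidate_list()` applies, in order:

1. **Scoring.** Proteins absent from both cone fractions have no defined
   share and are set aside (with a logged count).
2. **Share pre-filter.** $s < 0.5$ means the protein sits mostly in the
   CIS-rich fraction; dropped.
3. **ROS-presence rule.** A protein whose equal-volume ROS-rich emPAI is
   *more than* 1/10 of its COS-rich emPAI is dropped: it is not
   cone-specific, or it entered the cone preparation with contaminating rod
   membranes. The comparison is strict, so exactly 1/10 is kept. The ROS
   value is first multiplied by `ros_cos_volume_ratio` so the two outer
   segments are compared at equal volume; the true rod:cone OS volume ratio
   is preparation-specific geometry this package cannot know, so the default
   is 1 and the parameter is prominent in `filter_config()`.
4. **Abundance floor.** Proteins with COS emPAI *lower than* 1/100 of the
   most abundant surviving candidate are dropped — at that depth,
   single-peptide shot noise dominates the index. The reference maximum is
   computed over the survivors of steps 2–3 by default (`floor_reference =
   "survivors"`), or over all scored proteins (`"all"`).
5. **Report threshold.** The reported list keeps $s \ge 0.8$. The boundary
   is *inclusive* and applied to shares rounded to 3 decimals: published
   lists of this kind print shares at 2–3 decimals and contain boundary rows
   that print exactly 0.8, so a strict comparison on rounded values would
   contradict the very lists the rule generates.

Records are ordered by share descending, ties broken by COS emPAI descending,
then protein id — the ordering used in published candidate tables, where the
block of share-1 proteins descends by abundance.

Because published reference lists print *rounded* emPAI columns while their
share column was computed from unrounded values, recomputing shares from a
printed table does not reproduce every row at 3 decimals. For re-evaluating
such a table, `build_candidate_list(..., share = )` accepts the printed
shares as authoritative; without the override the function recomputes shares
from the emPAI columns it is given.

## Marker accounting and cross-contamination

Fraction purity is quantified with marker proteins of known residence: visual
pigment for OS membranes, F1 ATPase β subunit (mitochondrial inner membrane),
TOM20 (mitochondrial outer membrane), Na⁺/K⁺ ATPase α subunit (IS plasma
membrane) and calnexin (ER). Band signals are converted to amounts through an
ordinary least-squares calibration line (`fit_calibration()`; intercept
unconstrained by default because densitometry baselines are rarely zero, with
a `force_origin` option), with 4× loading-volume lanes divided back down
(`quantify_band()`), and below-intercept signals clamped to zero with a
warning — a faint band is "not detected", not negative. Recoveries are
percent-of-initial-membranes from the same cell number.

The cross-contamination estimator converts recoveries into protein-mass
ratios under the explicit assumption of equal membrane and protein density
per volume across compartments, weighting IS terms by the IS:OS volume ratio
(default 6):

$$\frac{\text{contaminant}}{\text{target}}
  = \frac{r_{\mathrm{cont}} \times V_{\mathrm{IS}}/V_{\mathrm{OS}}}
         {r_{\mathrm{target}}}$$

for an OS-rich fraction, and with the volume weight moved to the denominator
for an IS-rich fraction. With the packaged reference recoveries
(`reference_marker_recoveries()`), IS contamination of the cone OS-rich
fraction evaluates to 0.39–0.76 of the OS protein mass — far from negligible,
which is exactly why the candidate rules exclude via the CIS-rich list rather
than trusting the COS-rich list alone — while OS contamination of the
CIS-rich fraction evaluates to about 0.01, validating the CIS-rich fraction
as the cleaner reference.

## Pigment quantification by sequential bleaching

Visual pigments are the OS marker, measured spectrophotometrically. Cone
pigments overlap spectrally, so contents are read from *difference spectra*
under sequential selective bleaching: long-pass light bleaches the
red-sensitive pigment (λmax 622 nm) first, then green (535 nm), then blue
(460 nm); rods carry rhodopsin (522 nm) bleached in one step. Subtracting the
post-bleach from the pre-bleach spectrum isolates the bleached pigment's
contribution by linearity, and its amplitude at the pigment's λmax is the
relative content (`quantify_sequential_bleach()`, `mode = "peak"`).

The peak readout is template-agnostic, which is why it is the default. The
package still provides peak-normalized template families — a Gaussian in
wavenumber (default σ `1.7e-4` nm⁻¹, roughly a 4000 cm⁻¹ full width at half
maximum, typical of pigment α-bands) and the standard A1/A2 visual-pigment
α-band templates — used to compose synthetic spectra and for the optional
`mode = "fit"` readout, a non-negative least-squares amplitude that is more
robust when noise sits exactly at the peak. On noiseless single-component
differences the two modes agree exactly. Two biases are documented rather
than corrected: an incomplete bleach under-reports content proportionally,
and photoproduct absorbance is ignored (difference spectra are assumed to
reflect pigment loss only).

## What the synthetic generator emulates

The wet-lab inputs are not publicly deposited, so `simulate_proteome()` /
`simulate_fraction_tables()` generate every input the pipeline consumes with
the statistical structure the analysis assumes:

* **Proteome.** Random sequences of 80–600 residues with ~12% combined K/R,
  so digests are peptide-rich (≥ 5 observable peptides for ≥ 90% of
  proteins). Abundances are log-normal (meanlog 0, sdlog 1) — a modest
  dynamic range typical of the washed-membrane proteome remaining after
  soluble and peripheral proteins are stripped.
* **Localization classes.** Default mix: 7% COS-specific, 40% CIS residents,
  25% shared between rod and cone OS, 20% RIS residents, 5% present in both
  the cone OS and a cone IS organelle, 3% red-blood-cell contaminants.
  IS residents are assigned to organellar membranes — mitochondrial inner
  (0.5), outer (0.3), ER (0.2), the ellipsoid being dominated by
  mitochondria. No resident class is placed in the IS *plasma* membrane: the
  plasma membrane is continuous between inner and outer segment, so a
  protein confined to it is not a coherent ground-truth class, and the
  reference recoveries themselves show IS plasma membrane migrating mostly
  with the upper fraction. Blood-cell membranes contaminate *both* purified
  preparations, so their proteins surface in the ROS-rich table and are
  removed by the ROS rule.
* **Mixing.** Each protein's amount in each fraction is
  `abundance × recovery × volume weight`, with recoveries transcribed from
  the reference marker experiment (`default_mixing_matrix()`) and IS
  compartments weighted by the 6× volume ratio.
* **Detection.** Each observable peptide is detected independently with
  probability $p(a) = 1 - e^{-a/\kappa}$ — the simplest saturating model
  under which expected emPAI grows roughly proportionally with amount. The
  scale κ = 1.5 puts the median observed/observable ratio near 0.3 for a
  unit-median-abundance proteome passed through the cone-OS recovery
  (0.545): $0.545 / (-\ln 0.7) \approx 1.5$. Two independent replicates are
  simulated and pooled by peptide union, matching the two-experiment design
  the pipeline emulates.

What passing tests on this generator do show: the share statistic plus the
three exclusion rules recover compartment-confined ground truth with high
sensitivity and low false-discovery proportion *when the mixing matrix is
correct and detection is abundance-driven*. What they do not show: robustness
to the things the generator leaves out — peptide-level detectability
differences (hydrophobicity, charge), shared peptides between homologous
proteins, chimeric or mis-assigned spectra, and membrane classes that
genuinely straddle compartments. Real candidate lists of this kind retain
known-elsewhere proteins (a third of the published reference list), and the
generator reproduces the mechanism for some of that (density-based
co-migration) but not all of it.

## Numerical choices and degenerate inputs

* Share comparisons use unrounded values except the final report boundary,
  which is inclusive on 3-decimal-rounded shares (see above). The two
  "strictly more/less than" exclusion rules are strict, as stated.
* `cos_share(0, 0)` is an error, not NaN: a protein absent from both cone
  fractions must be set aside by the caller, and `build_candidate_list()`
  does so with a logged count.
* `compute_empai()` refuses `n_observed > n_observable` — that combination
  signals an inconsistent digestion window rather than a quantity to clamp.
  Identified peptides absent from a protein's digest are excluded with a
  logged count; peptides in the digest but outside the mass window are not
  counted, preserving the invariant.
* Peptides containing non-standard residues are dropped from observable sets
  with a warning.
* Below-detection calibration signals clamp to 0 with a warning, mirroring
  "not detected" entries in recovery tables.
* All generators are pure functions of their seed and restore the caller's
  RNG state.

## Problem sizes

The packaged evaluation (`evaluate_candidate_recovery()`) runs 20 seeded
simulations of 300 proteins each — large enough that class counts are stable
(≈ 21 COS-specific proteins per simulation) and small enough that the full
suite runs in well under a minute; sensitivity and false-discovery medians
are reported over the 20 seeds. Property checks of the digestion engine use
50 random sequences of length ≤ 60 against an independent boundary-scan
oracle, and spectral-noise behavior uses 200 seeded bleach series.

## Known limitations

* The ROS:COS equal-volume correction defaults to 1 because the true
  geometry is preparation-specific; users with measured OS volumes should
  set `ros_cos_volume_ratio` explicitly.
* emPAI is treated as linear in amount for normalization, as the method
  itself does; no saturation correction is applied at high abundance, where
  the index compresses toward 9.
* The filter provides no significance statement — it is a deterministic
  rule set, and the package deliberately does not attach p-values the
  original procedure never defined.
* Protein inference from shared peptides, FDR control of identifications
  and intensity-based quantification are out of scope; identification
  tables are taken as accepted identifications.
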