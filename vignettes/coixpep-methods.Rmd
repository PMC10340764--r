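---
title: "Methods: in silico proteolysis, quality indices and amide I deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico proteolysis, quality indices and amide I deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coixpep)
```

coixpep implements the computational workflow used to evaluate a cereal
storage protein (coix seed prolamin) as a precursor of DPP-IV-inhibitory
peptides: simulated gastrointestinal proteolysis, peptide physicochemistry
and screening, amino-acid-based quality indices, wet-assay arithmetic, and
secondary-structure estimation from vibrational spectra. This vignette
documents the models, the tunable parameters, the numerical choices, and
what the synthetic-data tests do and do not establish.

## Proteolysis model

An enzyme is a pair of residue sets: cleave the bond C-terminal to any P1
residue unless the P1′ residue blocks it. The shipped defaults are

* trypsin (EC 3.4.21.4): P1 = {K, R}, blocked by P1′ = {P};
* pepsin at pH > 2 (EC 3.4.23.1): P1 = {F, L, W, Y}, blocked by P1′ = {P}.

Published specificity tables for these enzymes differ between tools
(PeptideCutter, BIOPEP-style engines and MS search engines disagree on
pepsin in particular), so the rule tables are data, not code: any
`cleavage_rule()` can be passed to `digest()`. The defaults above are the
most widely used simple dialect and are what the bundled generators assume.

Two application modes are provided. *Concurrent* mode cuts at the union of
all rules' sites in one pass, modelling a one-pot multi-enzyme digest;
*sequential* mode applies each enzyme to the fragments left by the previous
one, mirroring gastric-then-intestinal protocols. Because the P1/P1′
predicate depends only on the local residue pair, the two modes provably
yield the same peptide set for such rules; the equality is asserted in the
test suite rather than assumed. Concurrent is the default.

Coordinates are 0-based half-open, which makes the conservation invariant —
concatenating the peptides of a `digest_result` reproduces the parent
sequence exactly — trivial to assert. The degree of hydrolysis is
DH = 100·d/D with d cleaved bonds and D = length − 1 total bonds; across
proteins `census()` reports the bond-weighted aggregate
100·Σd/ΣD rather than a mean of per-protein percentages, so long proteins
carry their proper weight.

Real prolamin accessions are deliberately not bundled: sequence-level tests
run on synthetic prolamin-like sequences (see below) or user FASTA. Kinetic
or probabilistic (missed-cleavage) digestion is out of scope.

## Peptide masses, motifs and screening

Masses are residue-mass sums plus one water: monoisotopic 18.010565 Da,
average 18.01528 Da. The residue table carries both mass scales; the
monoisotopic sum of the 20 residues (2376.11434 Da) is frozen in the test
suite as a checksum against accidental edits. Non-canonical residue codes
(B, J, O, U, X, Z) are rejected with positions named, not silently dropped,
because mass and motif arithmetic is undefined for them.

Motif flags record the features the DPP-IV structure–activity literature
emphasises: hydrophobic residue fraction (set {A, V, I, L, F, M, P}), a
hydrophobic N-terminal residue, and proline at the N-terminus, penultimate
position, or C-terminus. They are reported as independent booleans, not
collapsed into a verdict, because the structure–activity evidence is
qualitative.

External predictor outputs (bioactivity, DPP-IV inhibition probability,
allergenicity marks, Caco-2 log-permeability, MDCK permeability in cm/s,
HIA/PPB/BBB/Fu) are *ingested* from CSV and never recomputed — the
underlying tools are trained models that cannot be meaningfully
reimplemented here. The parser accepts both ASCII (`8.90E-6`) and typeset
(`8.90 × 10^−6`) scientific notation and treats `NA` and `-` as explicitly
missing, never as zero. Screening retains rows with bioactivity strictly
above the 0.5 default and ranks by DPP-IV probability descending, missing
last, ties broken by bioactivity then sequence so that the order is total
and reruns are byte-identical. No default DPP-IV probability cut is applied:
no defensible threshold is published, so the probability is reported and the
cut left to `screen_config(dppiv_min = ...)`. MDCK banding uses
low < 2×10⁻⁶ ≤ medium ≤ 20×10⁻⁶ < high (cm/s), boundaries belonging to the
medium band.

## Nutritional and flavour indices

All indices start from a profile of residue contents in g/100 g sample.

* **AAS** = 100·content/reference. By default the profile is first
  normalised to mg of amino acid per g of total amino acids so its units
  match the WHO/FAO adult pattern (mg/g protein, with Met+Cys and Phe+Tyr
  paired); a raw-ratio mode is available since the formula itself is
  unit-agnostic. Residues with zero measured content (Trp is routinely
  destroyed by acid hydrolysis) score `NA` and are excluded from the
  limiting-residue ranking — otherwise a not-detected residue would always
  rank first with a score of 0, which conflates analytical absence with
  deficiency.
* **PER** regressions (quality threshold 2):
  PER₁ = −0.684 + 0.456·Leu − 0.047·Pro;
  PER₂ = −0.468 + 0.454·Leu − 0.105·Tyr;
  PER₃ = −1.816 + 0.435·Met + 0.78·Leu + 0.211·His − 0.944·Tyr.
  These are affine, so they deliberately fail the linear-scaling property
  that the sums and TAVs satisfy; the test suite checks both behaviours.
* **Class sums**: essential amino acids follow the cereal-analysis grouping
  {Thr, Val, Met, Ile, Leu, Phe, Lys, Trp} (His counted non-essential, as is
  conventional for adult cereal-protein totals even though the adult scoring
  pattern includes His); hydrophobic {A, V, I, L, F, M, P}; umami ("fresh")
  {Glu, Asp}; bitter {Val, Met, Ile, Leu, Phe, His, Arg}; sweet
  {Thr, Ser, Gly, Ala}; medicinal {Met, Leu, Phe, Lys, Asp, Tyr, Glu, Ala,
  Arg}.
* **TAV** = 1000·content/threshold, thresholds in mg/100 g for the fourteen
  flavour-presenting residues; TAV > 1 (strict) flags a flavour-relevant
  residue. The umami and bitter totals sum their full classes. The sweet
  total defaults to {Thr, Ser, Gly} only: although Ala belongs to the sweet
  *content* class, reference sweet-TAV totals in the source data are
  reproducible only without Ala (whose low 60 mg/100 g threshold would
  otherwise dominate the total several-fold). The sweet-TAV set is therefore
  configurable and the discrepancy surfaced here rather than hidden.

One further inconsistency is worth recording: in the reference composition
table the printed umami class sum equals Asp alone, while the class
definition and the umami TAV total both use Glu + Asp. The package follows
the class definition (F = Glu + Asp); the test suite accordingly checks
every derived row of that table *except* the printed F and F/T rows, at
0.5% relative tolerance (the per-residue inputs are printed rounded to two
decimals).

## Assay calculators

Inhibition, 100·(1 − (As − Asb)/(Ac − Acb)), is invariant to adding a
constant to all four absorbances and to rescaling them; both invariances are
tested. Negative values (apparent activation) are returned with a warning,
never clamped — clamping is a presentation choice that destroys information.
Replicate wells are averaged per role *before* the ratio (the aggregation
order is otherwise undefined; averaging absorbances is the default choice
and is documented as such). The biuret calculator inverts the calibration
y = 0.0721·x + 0.069 exactly; readings below the blank return a negative
concentration with a warning. Surface hydrophobicity H₀ is the OLS slope of
fluorescence on concentration over the whole dilution series, with
`k_lowest` available to restrict to the lowest concentrations since
"initial slope" is not otherwise defined.

## Amide I deconvolution

`fit_amide1()` estimates secondary-structure fractions from the amide I
band (default assignment windows, cm⁻¹: β-sheet 1615–1637 and 1682–1700,
random coil 1637–1645, α-helix 1646–1664, β-turn 1664–1681):

1. The analysis window is the assignment span padded by 20 cm⁻¹ per side
   (clipped to the data). The padding matters: a β-sheet component centered
   near 1618 still has most of its area below 1615, and fitting on the bare
   span truncates it and biases every fraction.
2. A straight baseline through the window endpoint intensities is
   subtracted.
3. Component count and centers are seeded from local minima of the
   Savitzky–Golay second derivative (window 15 points, order 3) of the
   pre-smoothed signal. Minima shallower than 3% of the deepest curvature
   are treated as noise. Every assignment window showing negative curvature
   is guaranteed at least one seed: in the four-band model each window is
   expected to hold a component, and a shoulder merged into a stronger
   neighbour does not always produce a separate derivative minimum.
4. A sum of Gaussians is fitted by bounded Levenberg–Marquardt least
   squares (minpack.lm), amplitudes non-negative, each center confined to
   ±4 cm⁻¹ of its seed, sigma in [1.5, 12] cm⁻¹. A non-converged fit is
   retried once from a seeded jitter of the start; failure after that is an
   error carrying the residual, not a silent result.
5. While the smoothed residual still contains a peak above 4× the noise
   floor (estimated as mad(diff(y))/√2), a component is added at the
   residual maximum and the fit repeated, up to 8 components.
6. Components below 0.5% of total area are dropped; each remaining band is
   assigned to the structure whose window contains its center (a center in
   the small gaps between windows goes to the nearest window; a center
   outside the whole region is flagged unassigned). Fractions are
   percentages of total assigned area and always sum to 100.

Gaussian lineshapes only: that is the lineshape the reference workflow
used, and mixing lineshapes would change area ratios silently. Fourier
self-deconvolution as a separate preprocessing stage is out of scope.
Fractions are invariant to intensity rescaling (tested); fits of real
instrument spectra depend additionally on water-vapour correction and
baseline chemistry that this package does not model, so published fractions
for real samples are not reproduction targets.

The Raman tyrosine doublet ratio I850/I830 is computed from
baseline-corrected local maxima nearest 850 and 830 cm⁻¹; tyrosine is
classified exposed when the ratio is ≥ 1 (boundary inclusive, following the
printed rule) and buried below 1. Disulfide rotamers are banded as g-g-g
[500, 516), g-g-t [516, 531), t-g-t [531, 545]: the g-g-g band is widened
from its single characteristic wavenumber (510) so the classification is
total on 500–545, and 531 goes to t-g-t per the stated range.

## Synthetic data: what it emulates, and what passing proves

Each generator draws from its own named RNG stream derived from the user
seed, so adding a generator never shifts another's draws, and every output
is a pure function of the seed. Ground truths are computed by separate
naive code paths (a literal loop for cleavage sites, straight-line
arithmetic for indices, window lookup for band structures) so they are
valid oracles for the modules under test.

* `gen_proteins()`: i.i.d. residue sampling with a prolamin-like bias
  (elevated Q, P, L, A, F; together 55% of the mass). Real prolamins have
  repeat structure and homology that i.i.d. sampling does not emulate, so
  digestion tests establish rule-engine correctness, not biological peptide
  yields. Default 10 proteins of 50–300 residues.
* `gen_profile()`: uniform contents in [0, 20] g/100 g with analytic index
  truths.
* `gen_spectrum()`: four Gaussian bands, one per structure window, centers
  3 cm⁻¹ inside their windows, sigma uniform in 3–5.5 cm⁻¹ (FWHM
  7–13 cm⁻¹), areas uniform in 10–50, on a 0.5 cm⁻¹ grid over
  1580–1720 cm⁻¹, plus Gaussian noise at 40 dB peak-signal-to-noise. The
  width range is a deliberate design condition: it keeps the four
  components spectroscopically resolvable, which is what makes the
  fraction-recovery benchmark well-posed — at widths much above this,
  adjacent bands in the narrow coil window merge into a mathematically
  non-identifiable sum and *no* fitter could recover the generating areas.
  Passing the recovery suite (mean absolute fraction error < 2 points over
  100 spectra) therefore demonstrates correct deconvolution of resolvable
  band systems at realistic noise, not that any overlapping system is
  recoverable.
* `gen_plate()`: absorbances constructed to invert to a chosen true
  inhibition (default blank 0.1, control window 0.8), with optional reading
  noise; at σ = 0.01 and 1000 replicates the calculator's mean recovers a
  50% truth within 3 standard errors (the small ratio-of-noisy-quantities
  bias, ≈0.02 points at these settings, is far inside that band).

## Problem sizes and determinism

The default test suite runs the digestion oracle on 1000 random sequences
of 2–60 residues, the spectra recovery suite on 100 four-band spectra, and
the plate recovery on 1000 replicates; everything is seeded and completes
in about a minute on one core. These sizes were chosen so the property
suites have real statistical teeth (the composition check at ~30,000
sampled residues resolves 2 percentage points; 100 spectra average over
band-geometry draws) while remaining fast enough to run on every change.
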