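---
title: "Carbon-position-resolved 13C enrichment analysis of aspartate: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbon-position-resolved 13C enrichment analysis of aspartate: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posE13C)
```

## The measurement problem

Photoautotrophs fix inorganic carbon through two carboxylases with
distinct positional signatures on the C4 backbone of aspartate: RUBISCO
fixes CO2 into what becomes position 1-C, the CBB cycle redistributes
fixed carbon into 2-C and 3-C, and PEPC fixes bicarbonate directly into
4-C of oxaloacetate and hence of aspartate. An ordinary mass spectrometer
counts how many 13C atoms a molecule carries, not where they sit. But GC
in-source fragmentation of silylated aspartic acid produces fragment ions
that retain different *subsets* of the backbone carbons, and the fractional
enrichment of a fragment is the arithmetic mean of the enrichments of the
positions it covers. Measuring several fragments with nested coverage
therefore determines the enrichment at every single position by linear
algebra, without MS/MS.

`posE13C` implements that chain: MID extraction from chromatograms,
natural-isotope-abundance correction, positional algebra, molar
quantification, and sigmoidal rate estimation — plus a synthetic-data
generator that stands in for instrument data in all tests.

## Fragment registry

The shipped registry (`default_registry()`) covers aspartic acid 3TMS and
2TMS ions. The validated, literature-anchored entries are the molecular
ions m/z 349 ([M]+) and 350 ([M+H]+, coverage {1,2,3,4}) and the m/z 232
fragment (loss of a carboxyl-TMS group, coverage {2,3,4}). The m/z 350
adduct is excluded from the default positional set because its MID is
overlapped by the [M]+ isotopologues one mass unit below; correcting that
overlap (a CorMID-style deconvolution) is deliberately out of scope and
the entry is only flagged. Entries for the {2,3}, {3,4} and {1,2}
coverages, and the positional assignments of the 2TMS fragments m/z 245
and 160, are **synthetic placeholders**: chemically plausible silyl
fragment formulas that make the full pipeline runnable on simulated data.
They are marked `synthetic-placeholder` in the registry `notes` column and
must be replaced by certified assignments (via a user registry CSV and
`read_registry()`) before analyzing real chromatograms. The registry is
data, not code, precisely so that these values can be dropped in without a
package release.

## MID extraction

For high-resolution APCI data, isotopologue windows are centered at
`exact_mz + i * 1.00336` Da (the 13C-12C mass difference) with a half
width of 0.005 Da. The 29Si isotopologue sits 3.8 mDa below the 13C
window center and is intentionally collected rather than resolved: silicon
contributions are removed arithmetically by the formula-based correction.
The apex is located on the **sum** of the isotopologue traces — at high
enrichment M0 can vanish entirely — and each trace is integrated by the
trapezoidal rule over apex ±10 scans. Measured vectors default to
`n_tracer + 4` mass offsets so the Si envelope is captured. Nominal-mass
EI data enter as pre-integrated apex-height peak tables; peak detection
for EI chromatograms is out of scope because such data arrive
deconvoluted from vendor software.

## Natural-isotope-abundance correction

Every fragment ion formula contains atoms whose natural heavy isotopes
(13C, 2H, 15N, 17/18O, 29/30Si) inflate the measured MID. For a fragment
with $n$ covered backbone carbons, the correction matrix column for
tracer count $j$ is

$$ M_{\cdot j} \;=\; p_{\mathrm{rest}} \otimes \delta_j \otimes
   \mathrm{Binom}(n - j,\, a_{13}) $$

where $p_{\mathrm{rest}}$ is the natural isotopologue pattern of the
formula minus the $n$ backbone carbons (computed by per-element
multinomial expansion and discrete convolution, nominal-mass binned),
$\delta_j$ shifts by $j$ mass units, and the binomial term carries the
natural 13C abundance $a_{13} = 0.0107$ of the unlabeled backbone
carbons. The tracer-isotopologue fractions solve

$$ \hat x = \arg\min_{x \ge 0} \lVert M x - m \rVert_2, \qquad
   E^{13}C = \tfrac{1}{n} \sum_j j\, \hat x_j $$

with $m$ the measured MID normalized to unit sum. Non-negative least
squares (Lawson–Hanson) is used instead of plain matrix inversion because
inversion returns negative fractions at low abundance; the inversion
route is retained in the test suite as an independent cross-check and the
two agree to numerical precision on noise-free carbon-only systems.
Isotope masses and abundances are pinned to one published IUPAC table
(`ISOTOPES`) for reproducibility.

Numerical choices: patterns are pruned at $10^{-9}$ and renormalized;
correction matrices are deterministic for a fixed isotope table; when a
measured vector is shorter than the matrix, trailing matrix rows are
dropped and columns renormalized (with a warning); a relative residual
above 0.05 sets a `poor_fit` flag; an all-zero vector is an error, not a
zero result.

## Tracer-purity convention

Certified standards are not 100% labeled (the certificates are 99.0% for
the fully labeled and 99.6/99.7/99.6/99.3% for the position 1–4
standards). Measurements are **not** purity-corrected; instead the purity
enters the *expected* value of a validation mixture:
$e_i^{\mathrm{exp}} = \sum_c f_c\, \pi_c\, [i \in L_c]$ over components
with mole fraction $f_c$, purity $\pi_c$ and labeled positions $L_c$.
This is the conservative reading of manually adjusting corrected results
to certificate purity, and it keeps measured values untouched. The
complementary convention (dividing measurements by purity) can be applied
by the user downstream; both cannot be defaults at once.

Consistently, the synthetic generator treats positional enrichments as
**tracer** enrichments: a covered position is tracer-13C with probability
$e_i$ and otherwise carries natural abundance. Under this convention
correction followed by simulation is an exact identity
(`correct_mid(simulate_mid(e))` recovers the subset-enumeration
distribution of `e` and `E13C = mean(e)`), which is the invariant the
test suite enforces.

## Positional algebra

With fragment enrichments $E_{1234}, E_{234}, E_{23}, E_{34}$ (each the
mean over its covered positions), the per-position enrichments are

$$ e_1 = 4E_{1234} - 3E_{234}, \qquad e_2 = 3E_{234} - 2E_{34}, $$
$$ e_3 = 2E_{23} + 2E_{34} - 3E_{234}, \qquad e_4 = 3E_{234} - 2E_{23}. $$

The weights are the fragment carbon numbers; positions 1, 2 and 4 need
two fragments, position 3 needs three because in-source fragmentation
offers no simpler combination. The published rendering of the third
equation is typeset ambiguously; the form above is the unique
carbon-number-weighted identity consistent with the derivation, and the
package treats it as such. Two linear identities follow exactly and are
tested at $10^{-12}$: feeding exact coverage means through the equations
returns the truth vector, and $\mathrm{mean}(e_1..e_4) = E_{1234}$.

Uncertainties propagate under an independence assumption,
e.g. $\sigma(e_1) = \sqrt{16\sigma^2(E_{1234}) + 9\sigma^2(E_{234})}$,
with weights (9,4) for $e_2$ and $e_4$ and (4,4,9) for $e_3$. The four
fragments share one ion source, so their errors may be correlated; the
propagated SDs are therefore approximate — a documented limitation, and
the reason precision is always also measured empirically across
replicates. Negative positional values caused by noise are reported
as-is with a flag, never clipped, so accuracy statistics stay unbiased.
When the {2,3} or {3,4} fragment is unavailable (the EI situation), the
affected positions are reported as undetermined rather than imputed.
Fragment-level enrichments outside $[0,1]$ by more than 0.02 are clipped
to that tolerance and flagged. `cross_check()` compares alternative
fragment combinations pairwise per position (default tolerance 0.02) as
an interference screen.

## Quantification

The quantifier is the sum over *all* isotopologue abundances, so the
labeling state cannot bias the concentration. The response is normalized
to the constant 13C6-sorbitol internal standard (25 ng per injection in
all simulated fixtures), inverted through an ordinary least-squares
calibration line fitted on at least three amounts of the non-labeled
reference, multiplied by the GC split ratio, converted to pmol via the
molecular weight, and normalized to OD750 x volume. Responses outside
the calibrated range are flagged `extrapolated`; negative inverted
amounts clamp to zero. A single configurable `aliquot_factor` (default 1)
absorbs extraction-aliquot arithmetic, which is workflow-specific.
Molar positional 13C is then simply $m_i = e_i \cdot c$.

## Sigmoidal rate estimation

Molar positional 13C time courses sampled at 0, 5, 10, 15, 30, 60 and
90 min are fitted with the three-parameter logistic
$y(t) = y_{\max} / (1 + e^{-k(t - t_{\mathrm{mid}})})$, baseline pinned
to zero. A double-sigmoidal (rise-then-decay) branch is deliberately not
implemented: no decay occurs within the 90 min window this design
targets. Optimization is multi-start Levenberg–Marquardt over a fixed
grid ($k \in \{0.01, 0.05, 0.2, 1\}$, $t_{\mathrm{mid}}$ at the observed
time quartiles, $y_{\max}^{(0)} = \max y$), evaluated in fixed order so
fits are deterministic. A fit is classified `sigmoidal` only if

* the fitted relative intensity at $t_0$ does not exceed the allowed
  maximum of 0 by more than a numerical tolerance of 0.05 (a pure
  fit-quality guard — observed $y(0)$ is forced to 0 by the design),
* the last observed value reaches 0.75 of the fitted plateau (the
  threshold-intensity-ratio rule, interpreted as "the plateau must
  actually be observed"), and
* the AIC improvement over a flat constant model is below −10.

Otherwise it is `ambiguous`; an all-zero series is `no_signal` with zero
rate. The maximal assimilation rate is the analytic maximum slope
$k\,y_{\max}/4$, attained at the half-max time $t_{\mathrm{mid}}$; both
identities hold exactly for every returned fit. Replicates are fitted
individually and summarized by medians (pooling replicates into one fit
is possible but hides between-culture variation; the published protocol
does not specify which was done, so the more informative option is the
default). A position/condition with no sigmoidal replicate fit is
reported ND.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which every acceptance statement is evaluated.

* **Mixture panel.** 36 designs reconstructed from the stated design
  rules — five labeled standards each at labeled fractions 100/95/90/50/
  10/5%, the equal 1:1:1:1 positional mix at dilutions 100/50/20/10/4%,
  and pure natural — times 4 technical replicates at 25 ng. The original
  composition table is not redistributed; the reconstruction is flagged
  as such. Abundances scale linearly with injected amount over split
  ratio; m/z 232 and 350 default to split ratio 5, mirroring the
  split-mode acquisition used for saturation-prone fragments.
* **Noise.** Per-isotopologue multiplicative noise with CV 0.01 at the
  25 ng scale (the calibration at which the panel reproduces the
  validated accuracy < 1 and precision < 2.5 percentage-point envelope),
  an additive baseline floor of SD 100 counts (~1e-5 of full scale, a
  realistic detector floor that degrades accuracy below ~12.5 ng), and
  smooth saturation $y/(1+(y/T)^s)^{1/s}$ with $T = 10^7$ counts and
  $s = 4$, which leaves the MID untouched below ~0.5 T and distorts it
  progressively above — reproducing the qualitative
  deviation-versus-abundance shape without modeling detector physics.
* **Time courses.** Logistic trajectories per position. Light defaults:
  plateaus (100, 70, 70, 95) pmol/OD750/mL, rates (0.2, 0.15, 0.15,
  0.2) min$^{-1}$, midpoints (22, 28, 28, 22) min on a 300 pmol/OD750/mL
  pool — 1-C and 4-C rates deliberately similar, signal detectable from
  ~10 min. Dark defaults: positions 1–3 identically zero, 4-C plateau 60,
  rate 0.1, midpoint 45 min — a lower, later PEPC-only signal first
  detectable after ~15 min. These values are the package's realistic
  emulation of the day/night physiology; no public numeric time-course
  data exist to pin them to, so recovery is asserted against the
  generator's own parameters. Replicate variability enters through a 5%
  CV on the pool (concentration measurement dominates replicate scatter,
  not E13C), and a matching noise-free-slope calibration series is
  emitted alongside.
* **mzML fixtures.** Gaussian chromatographic peaks (SD 1.5 s, 0.5 s
  scan interval) rendered per isotopologue at the registry m/z values and
  written as centroided mzML, so the extraction path is exercised against
  files with known ground truth.

What the generator does **not** emulate — and what passing tests
therefore do not demonstrate about real data: isobaric interferences from
co-eluting matrix compounds, the [M]+/[M+H]+ cross-contamination of
m/z 349/350, retention-time drift, baseline structure, correlated
isotopomer patterns (labeling is independent per position), and real
detector saturation physics. On real chromatograms the interference
screens (natural-sample E13C ≈ 0, `cross_check()`, the detection scan)
are the guards that must be run first.

## Problem sizes and runtime

The default test and validation sizes are the study layout itself: the
36 x 4 panel at 25 ng (144 positional calculations, seconds of runtime),
100 random round-trip vectors per registry fragment, 60-replicate
sigmoid recovery ensembles, and 4-replicate light/dark time courses on
the 7-point grid. All are chosen to be statistically meaningful at
interactive runtimes on a single core.

## Known limitations

* Only 13C tracers on the aspartate backbone are supported; H/N/O
  tracers and charge states above 1 are out of scope.
* The [M+H]+ overlap by [M]+ is flagged, not corrected.
* Propagated positional SDs assume independent fragment errors.
* The registry's partial-coverage entries are synthetic placeholders
  until certified assignments are supplied.
* Calibration is linear; matrix effects and recovery are not modeled.
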