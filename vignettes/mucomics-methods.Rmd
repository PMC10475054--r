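---
title: "Methods: models, parameters and design choices in mucomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in mucomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucomics)
```

`mucomics` implements the quantitative core of a comparative "mucomics"
workflow for mucus hydrogels: AFM nanoindentation mechanics, differential
permethylation glycomics, EDX elemental profiling, and spectral-count
proteomic profiling.  Every stage has a generative twin in the synthetic-data
functions, so the package's accuracy claims are all statements about
parameter recovery on data with known ground truth.  This vignette documents
the models, the tunable parameters and their defaults, the numerical choices,
and the places where the design was genuinely open.

## JKR contact mechanics

An AFM cantilever of spring constant $k$ (default 0.139 N/m) and deflection
sensitivity $s$ (default 40.7 nm/V) indents the gel with a spherical tip of
radius $R$ (default 20 nm).  The recorded observables are piezo position and
deflection; the calibrated force is $F = k\,s\,d_V$ and the tip--sample
separation is the piezo travel corrected for cantilever bending,
$z = z_{piezo} - F/k$.  The adhesive contact is described by the
Johnson--Kendall--Roberts model in the parameterization used throughout this
package:

$$E_{JKR} = \frac{9\pi R^2 \Delta r}{2 a_0^3}, \qquad
  P_{adh} = -\tfrac{3}{2}\pi \Delta r R,$$

$$h_t - h_0 = \frac{a_0^2}{R} m^{4/3} - \frac{2}{3}\frac{a_0^2}{R} m^{1/3},
  \qquad m = \frac{1 + \sqrt{1 - P/P_{adh}}}{2},$$

with $a_0$ the zero-load contact radius, $P_{adh}\le 0$ the pull-off force,
$h_t$ the indentation depth and $h_0$ the contact point.  Two consequences
used as analytic anchors in the tests: $h_t(P{=}0) - h_0 = a_0^2/(3R)$ and
$h_t(P_{adh}) - h_0 = -0.13228\,a_0^2/R$.

The exponent pair $(4/3, 1/3)$ of the depth--load relation differs from some
classical JKR depth formulations; it is implemented exactly as written above,
and since the synthetic data are generated from the same law, generator and
analyzer are consistent by construction.  Real-instrument users should
confirm the parameterization matches their analysis software.

**Two-stage fitting.**  `fit_jkr()` first detects the pull-off force as the
minimum retract force, fixes $\Delta r$ through the pull-off relation, and
then estimates $(a_0, h_0)$.  With $P_{adh}$ fixed, the depth--load relation
is *linear* in $(h_0, a_0^2/R)$, so the least-squares problem is solved
exactly by a linear solve -- the same minimizer a nonlinear optimizer would
find, without iteration or convergence failures; `converged` reports whether
the solution maps back to a physical $a_0 > 0$.  A co-estimation mode
(`co_estimate = TRUE`) wraps a one-dimensional search over $P_{adh}$ around
the same solve; its objective clips loads below the trial pull-off rather
than dropping them, keeping the RSS continuous.  Fits with fewer than five
usable points are refused.

**Numerical choices.**  Baseline: the mean force over the 10% of approach
points at largest separation, subtracted from both segments (the retract of
an indentation has no non-contact region of its own).  Pull-off under noise:
the global minimum, optionally after Savitzky--Golay smoothing
(`smooth = TRUE`, off by default); note the minimum of $n$ noisy samples is
biased low by roughly $\sigma\sqrt{2\ln n}$, which is the error envelope the
tests assert.  Hysteresis integration: trapezoids on the union depth grid
with linear interpolation of both segments -- deterministic and checkable
against quadrature.

## The synthetic force-curve generator

`simulate_jkr_curve()` inverts the modulus relation for $a_0$, evaluates the
pull-off force, samples loads uniformly on $[P_{adh}, P_{max}]$ with
$P_{max} = 5\,|P_{adh}|$ by default, evaluates depths from the depth--load
law, and converts to instrument units so the analysis stage must perform the
full calibration.  The approach segment follows the same single-valued JKR
branch restricted to $P \ge 0$, preceded by a flat non-contact baseline;
this choice (the instrument literature does not prescribe an approach model
for ideal curves) yields an enclosed hysteresis loop with a closed form.
Noise, when requested, is additive Gaussian on force after ideal-curve
generation.  With $\Delta r = 0$ the JKR expressions degenerate
($a_0 = 0$), and the generator switches to the Hertzian law
$P = \tfrac{4}{3}E\sqrt{R}\,h^{3/2}$, giving a reversible curve with zero
pull-off.

The default study conditions are the reference values shipped with the
package (`mucus_mechanics_reference()`): moduli of 41.6, 132 and 162 MPa and
works of adhesion of 3.37, 2.39 and 17.2 N/m for adhesive, lubricating and
protective mucus, with $n$ = 36, 51 and 59 indentations.  The per-aggregate
replication scheme behind those $n$ is not specified by the source study, so
$n$ is a free parameter of the generator.  In the pipeline, per-curve true
parameters are drawn from normal distributions whose spread matches the
reference standard errors times $\sqrt{n}$, emulating material
heterogeneity; the tests and the acceptance analysis use homogeneous
noiseless curves so that recovery is exact.

**Two routes to the work of adhesion -- and why they disagree.**
The pull-off route inverts $P_{adh} = -\tfrac{3}{2}\pi\Delta r R$ and
recovers the generator's $\Delta r$ exactly.  The hysteresis route
(`work_of_adhesion()`) integrates the area enclosed between approach and
retract and normalizes by the contact area $\pi R h_{t,max}$.  For the
reversible JKR loop generated here, approach and retract coincide for
$P \ge 0$, so the enclosed area is exactly the adhesion well
$A = \tfrac{3}{4}\pi\Delta r a_0^2 I$ with
$I = \int_0^1 (1-u^2)\left[\tfrac{4}{3}m^{1/3} - \tfrac{2}{9}m^{-2/3}\right]du
= 0.58835$, and the maximum depth under the default load range is
$1.26890\,a_0^2/R$.  The ratio of the two routes is therefore the constant

$$\frac{W_{hyst}}{\Delta r} = \frac{3I}{4 \times 1.26890} = 0.34775,$$

independent of $E$, $\Delta r$ and $R$.  No choice of approach model can
remove this gap: the loop area saturates while the normalizer grows with the
maximum load.  On real, dissipative materials the enclosed loop also
contains viscoelastic hysteresis at positive loads, which the reversible
generator deliberately omits; the two routes should not be expected to agree
there either, for the opposite reason.  The package reports both
(`W_fit` and `W_hyst` in the pipeline output), and the tests pin the ratio
against an independent quadrature oracle.  This is the main feature of real
force curves that the synthetic data do *not* emulate, and recovery of the
hysteresis-normalized $W$ at the planted value is accordingly not a claim
this package makes.

Sample statistics follow the standard-error definition
$SE = SD/\sqrt{n}$ with the $n-1$ sample standard deviation
(`sample_summary()`).

## Permethylated-glycan annotation

Compositions are multisets over the mass-degenerate residue families Hex,
HexNAc, dHex, Pent, Neu5Ac and Neu5Gc (`residue_table()`); Gal vs Man or
GalNAc vs GlcNAc cannot be distinguished by MALDI mass and are reported
generically.  O-glycans released by reductive beta-elimination are handled
as open-ring alditols (+H$_2$ and one extra derivatizable hydroxyl);
N-glycans as free reducing-end species.  Permethylation replaces every
hydroxyl, amide and carboxyl hydrogen with a methyl: the site count of a
composition is the sum of free-monosaccharide sites minus two per glycosidic
bond, plus one for the alditol terminus.  The light run uses CH$_3$I; the
heavy run uses CD$_3$I, so each *added* methyl weighs
$3(m_{^2H} - m_{^1H}) = 3.01883$ Da more, while *native* methyls -- present
on the glycan in vivo -- stay CH$_3$ in both runs.  Ions are matched as
[M+Na]$^+$ only (standard positive-mode MALDI of permethylated glycans; the
electron mass is neglected, as in the field's mass tables).

`decompose_mass()` enumerates all compositions within per-residue bounds
(defaults: Hex $\le$ 10, HexNAc $\le$ 6, dHex $\le$ 4, Pent $\le$ 3,
Neu5Ac $\le$ 3, Neu5Gc $\le$ 2) and returns candidates within a tolerance
(default 0.2 Da, appropriate for MALDI-TOF), sorted by mass error with ties
broken by parsimony: fewer residues, then fewer native methyls.  Error
comparison is performed at micro-Dalton granularity because exact
degeneracies exist -- a permethylated pentose plus one extra methylation
site weighs exactly as much as a hexose -- and floating-point noise must not
decide between them.  Native-methyl counts are mass-degenerate in the light
run, so they are not enumerated by default (`enumerate_native = TRUE`
restores the literal expansion); the heavy run is the information-bearing
measurement, and `infer_native_methylation()` recovers
$n_{native} = sites - round(\Delta m / 3.01883)$, flagging rounding
residuals beyond tolerance.

`annotate_glycans()` performs the full stage.  Methylation variants of one
residue composition share a single light peak; the annotator therefore
matches heavy peaks *globally* -- each heavy peak is granted to the one
(light peak, native-methyl count) slot that predicts it best -- and splits
a shared light peak across its variants in proportion to their heavy-run
intensities.  Relative abundances are normalized over assigned peaks using
the light run's total, and the major/trace split uses the strict 5% rule.
Whether reported profiles should derive from the light run, the heavy run or
an average is not specified by the source study; the light run is the
default authority here, with the heavy run used only where the light run is
uninformative (the variant split).

The reference profiles (`oglycan_reference_profiles()`) carry the reported
anchor values -- core-1 at 52% (adhesive) and 69% (lubricating), the
dimethylated trisaccharide at 48% (protective), two sialylated O-glycans
totalling 7% of the adhesive profile, extended glycans near 8% of the
lubricating profile -- and fill the remaining fractions with fixed package
choices so each profile sums to one while respecting every reported ordering
constraint.  These fillers were chosen once, before any recovery test was
run, and are not tuned.

## EDX elemental profiles

`normalize_wt_pct()` implements two conventions.  The *as-printed* rule
divides each raw abundance by the element's standard atomic weight and
normalizes to 100 -- the literal formula stated by the table legend this
stage mirrors.  The *conventional* rule multiplies by the atomic weight, the
usual atom-fraction-to-weight-percent conversion.  The legend's wording is
chemically self-contradictory (dividing a weight by a molar mass yields
moles, yet the column is labelled wt%), and the reference table's columns
already sum to about 100; both conventions are therefore exposed, the
convention used is recorded in the output, and the default is the as-printed
rule.  Missing elements are treated as zero, not missing-at-random.
Normalization is scale invariant, idempotent on an already-normalized
profile, and sums to 100 within $10^{-9}$.

One deliberate diagnostic: summing C+O+N of the reference adhesive column
gives 82.98%, while the accompanying text reports 84.7%.
`organic_content()` returns the computed sum; the discrepancy is surfaced,
never silently corrected.

## Proteomic filtering and profiling

`filter_identifications()` applies the acceptance rules as worded: at least
two peptides (inclusive), local FDR strictly below 1%, peptide probability
at least 95% (inclusive).  The published protein-probability threshold of
"5.0%" is ambiguous next to the 95% peptide threshold; both readings are
implemented (`protein_rule = "as_printed"`: probability $\ge$ 0.05;
`"complement"`: probability $\ge$ 0.95) with the literal reading as default
and no intent guessed.  The synthetic table generator plants records that
pass under *both* readings (and marginal records that fail both), so filter
recovery is rule-independent.  `filter_glycopeptides()` uses inclusive
thresholds $|\log prob| \ge 3$ and Delta Mod Score $\ge 50$.  Local FDR is
consumed as a precomputed per-record value; a simple decoy-fraction
estimator is provided for synthetic tables only.  `category_profile()`
computes percent composition from MS/MS spectral counts of accepted records
(all accepted records in the denominator, including Unknown/Novel
categories), per sample, summing to 100 by construction.

## Pipeline, determinism and problem sizes

`run_pipeline()` drives all stages from one configuration
(`default_run_config()` / YAML via `load_run_config()`), writes every
intermediate as TSV, and is byte-identical under a fixed seed; the log
records the package version, a 32-bit FNV-1a fingerprint of the scientific
configuration and the seed.  Any stage failure aborts naming the stage and
offending path.

Problem sizes used by the test suite and the reproduction script are chosen
for exactness rather than scale: recovery of a noiseless curve is exact at
any sampling density, so the suite uses 150--300 points per segment and
3--10 curves per condition, a 5x5x2 grid over
$(E, \Delta r, R) \in [1, 500]\,\mathrm{MPa} \times [0.5, 30]\,\mathrm{N/m}
\times \{2, 20\}\,\mathrm{nm}$, 100--200 random compositions for the
glycan round trip, and 1000-record tables for the filter oracle.  The full
suite runs in well under a minute.

## Known limitations

* The reversible generator omits viscoelastic dissipation, jump-to-contact,
  and long-range surface forces; passing recovery tests demonstrate the
  correctness of the analysis chain, not instrument realism.
* Glycan annotation is composition-level only: linkage, branching and the
  position of native methyls are out of scope, and isomeric residues are
  reported by family.
* EDX handling is a normalization layer; detector physics (ZAF
  corrections) and spatial mapping are out of scope.
* The proteomic stage consumes search-engine outputs; database searching,
  homology assignment and dendrogram construction are out of scope.
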