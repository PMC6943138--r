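---
title: "Methods: quantifying i-motif stability and its epigenetic modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying i-motif stability and its epigenetic modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimotif)
```

# Scope

i-Motifs are four-stranded DNA structures formed by C-rich sequences: two
intercalated hairpins held together by hemi-protonated C:C+ base pairs,
favored at mildly acidic pH. Because the structure is literally built from
cytosines, the epigenetic marks 5mC, 5hmC, 5fC and 5caC can tune both its
thermal stability (melting temperature, folding enthalpy/entropy) and its pH
stability (transitional pH). This package implements the complete analysis
chain for such measurements — UV melting thermodynamics, CD pH titrations,
thermal difference spectra — together with a genomics screen that asks where
methylation actually falls within i-motif forming sequences in two cell
lines. A synthetic-data module generates every input with known ground
truth, so the estimators are validated end to end without any external data.

# The two-state melting model

The melt of an intramolecular i-motif monitored by absorbance at 295 nm is
modelled as a two-state equilibrium between folded and unfolded forms. With
$\theta$ the fraction folded, the association constant is
$K_a = \theta/(1-\theta)$ and

$$\ln K_a = -\frac{\Delta H}{RT} + \frac{\Delta S}{R},$$

with $\Delta H$, $\Delta S$ referring to the *folding* reaction (so
$\Delta H < 0$) and $R = 8.314\,\mathrm{J\,mol^{-1}K^{-1}}$. At the midpoint
$K_a = 1$, which makes $T_m = \Delta H / \Delta S$ an identity rather than an
extra assumption. The observed absorbance is a $\theta$-weighted mixture of
two linear baselines, folded above unfolded (the i-motif absorbs more at
295 nm, which is also why its thermal difference spectrum has a negative
295 nm trough).

The analysis chain is:

1. **`first_derivative_tm()`** — the classical first-derivative estimate of
   $T_m$. Two choices matter here. The derivative is taken after a local
   least-squares quadratic smoother (7 points by default, i.e. ±3 °C on the
   standard 1 °C grid), which estimates d$A$/d$T$ robustly without moving a
   symmetric extremum. And the extremum is located on the derivative with
   respect to *reciprocal* temperature of the baseline-corrected fraction
   folded: against $1/T$ a van't Hoff transition is exactly symmetric, so
   its derivative extremum sits at the midpoint, whereas against $T$ itself
   the $1/T^2$ factor and sloped baselines shift the extremum a few tenths
   of a degree low. The grid extremum is refined by a parabolic vertex fit
   over ±10 points, about the transition half-width for a
   $-160\ \mathrm{kJ\,mol^{-1}}$ melt. A transition is only called when the
   derivative minimum stands out from the flank scatter by more than five
   robust SDs; strictly linear or flat ramps raise a `no_transition` error
   instead of returning a meaningless extremum.
2. **`fit_baselines()`** — ordinary least squares over the coolest and
   hottest 15% of the temperature range. The 4–95 °C protocol leaves wide
   flanks around a mid-range transition, so 15% is conservative; windows
   that reach into the transition (provisional $\theta$ within 0.35 of the
   midpoint, judged against reference baselines from narrow 10% flanks that
   a wide window cannot contaminate) trigger a warning.
3. **`fraction_folded()`** — $\theta(T)$ from the baseline geometry, clamped
   to $[0,1]$ with the clamp count reported. Amplitudes below five times the
   baseline residual SD are refused as indistinguishable from noise.
4. **`vant_hoff_fit()`** — linear regression of $\ln K_a$ on $1/T$(K),
   restricted to $\theta \in [0.15, 0.85]$ where $K_a$ is well conditioned
   (outside that window a small absorbance error produces a large $\ln K_a$
   error). $\Delta H = -R \times$ slope, $\Delta S = R \times$ intercept,
   reported in kJ by default with a kcal option since the field uses both.

Replicates (triplicate melts in the standard protocol) are summarized by
`analyze_replicates()` as mean ± sample SD, and modified-vs-control
comparisons use two-sided Welch t-tests (`compare_to_control()`): with
n = 3 per group and no reason to assume equal variances, the
unequal-variance form is the defensible default. `hysteresis_check()`
compares heating- and cooling-direction midpoints against a 1 °C tolerance;
the generator itself is equilibrium-only, so hysteresis scenarios are built
by offsetting the planted midpoints.

# CD titrations and the transitional pH

Folding is driven by protonation, so ellipticity at 288 nm (the i-motif
positive band) against pH follows a cooperative sigmoid. The package fits

$$E(\mathrm{pH}) = E_u + \frac{E_f - E_u}{1 + 10^{\,h(\mathrm{pH} - \mathrm{pH_T})}}$$

by Levenberg–Marquardt least squares. The measurement protocol only
prescribes "the inflection point of fitted ellipticity at 288 nm"; this
Hill-type parameterization is chosen because the inflection *is* the
$\mathrm{pH_T}$ parameter, and a fit is more noise-robust than a numerical
derivative of a 13-point series. The Hill coefficient is fitted rather than
fixed because hemi-protonated C:C+ formation is cooperative with
sequence-dependent steepness. The fit runs on raw millidegrees — pH_T is
invariant to affine rescaling of the ellipticity axis, so normalization
would change nothing. Degenerate inputs are handled explicitly: a dynamic
range below three times the residual SD is "no transition", and a fitted
pH_T within one pH step of the sampled boundary is flagged unreliable.

CD spectra are classified against the canonical signatures: i-motif = large
positive peak near 288 nm plus a negative band near 255 nm; random coil =
smaller positive peak near 276 nm without the trough. Peaks are located
after 5-point local-quadratic smoothing and must clear both three times the
310–320 nm noise SD and 40% of the spectrum's largest absolute signal. The
relative floor is what keeps a half-folded mixture honest: its residual
255 nm trough falls below 40% of its main peak, so the classifier returns
"indeterminate" rather than guessing a state.

Thermal difference spectra (`compute_tds()`) subtract the folded (4 °C)
absorbance spectrum from the unfolded (95 °C) one over 220–320 nm and
normalize the maximum change to exactly +1; no other processing is applied,
and an inverted or null difference is an error rather than a silently
negative "spectrum". The i-motif signature test (`classify_tds()`) requires
a positive 235–245 nm peak of at least 0.5 and a 290–300 nm trough of at
least 0.2 on the normalized scale.

# The methylation screen

`find_c_tracts()` decomposes a C-rich strand into maximal runs of C of a
configurable minimum length (default 3, the hTeloC tract length; genomic
sequences such as MSMO1/PLCB2 use 5), the inter-tract loops, and flanks —
the three segment classes always concatenate back to the input. Cytosines
are then numbered 5'→3' over *all* cytosines (the convention used to label
modified positions) and given roles; tract-terminal cytosines record which
loop they touch. Biophysically, the positions flanking loops 1 and 3 are
the most modification-sensitive, so the screen's "loop-adjacent" flag
defaults to loops 1 and 3 of the four-tract core (configurable).

Methylation calls (bedGraph-style intervals with beta values, 0-based
half-open) are mapped onto cytosine genomic positions with
GenomicRanges overlaps; minus-strand records mirror their coordinates. A
sequence is "methylated" in a cell line when any cytosine reaches beta ≥
0.5 with coverage ≥ 1 — a deliberately permissive coverage default since
the emulated tracks are pre-filtered; both are configurable, and percent
-scale inputs are rescaled with a message. Differential methylation between
the two lines means either discordant sequence-level flags or a per-cytosine
beta change of at least 0.2. CpG context is *not* required for a call to
map, since modified positions in i-motif studies are not restricted to CpG;
restriction can be imposed upstream by filtering the call table.

Stability classes come from the transitional pH: "neutral" i-motif formers
are defined by a pH_T threshold of 6.8 — the common definition
"transitional pH > 7.0 ± 0.2" is ambiguous about the edge, and the
inclusive lower edge (7.0 − 0.2) is used so that borderline sequences count
as neutral; the threshold is a parameter. The cohort summary reports counts
and integer-rounded percentages (exact fractions kept in the object) for
methylated, differential, loop-adjacent and the neutral/acidic split among
methylated sequences, plus a pooled two-proportion z-test comparing
methylation rates between neutral and acidic classes. Screen summaries
quoted in the literature sometimes carry inconsistent denominators (for
example a 10-vs-3 neutral/acidic split alongside 12 methylated sequences),
so every breakdown here is reported with its own explicit denominator and
no attempt is made to reconcile them; for the same reason
`proportion_test()` takes explicit counts rather than hard-wiring any
particular denominators.

# The synthetic-data generators

The generators are first-class, tested code, and their defaults *are* the
study conditions: melting curves on a 4–95 °C grid recorded every 1 °C with
the control scenario $T_m = 39.7$ °C and $\Delta H = -160$ kJ/mol;
titrations sampled in 0.25 pH-unit steps from 5.0 to 8.0. Measurement noise
is additive Gaussian — 0.002 AU on absorbance (typical for a 0.14 AU
transition amplitude, i.e. ~1.5%) and 2% of the titration amplitude on
ellipticity. Values the protocols do not pin down were chosen once as
field-realistic: baseline intercepts/slopes (0.70/−5·10⁻⁴ and 0.54/−2·10⁻⁴
AU, AU/°C), titration plateaus (10 and 2 mdeg at 288 nm) and Hill
coefficient 2, and the Gaussian band bases behind the CD and absorbance
spectra. All stochastic outputs are pure functions of (parameters, seed).

What the generators deliberately do **not** emulate: kinetic (non-two-state)
melting, instrument drift or correlated noise, multi-transition melts,
bisulfite-sequencing sampling noise in beta values, and real methylome
spatial structure (the screen fixture plants calls directly on cytosines).
Passing the recovery tests therefore demonstrates correctness of the
estimators under the stated model, not robustness to every pathology of
real instrument data.

The screen fixture (`make_screen_fixture()`) plants sequence-level truth —
which sequences are methylated, differential, loop-adjacent, neutral — and
emits FASTA/BED/bedGraph/CSV files deterministically. Its defaults mirror
a reference cohort structure (44 sequences, 12 methylated, 10
differential, 8 loop-adjacent, 13 neutral) so the summary's printed
percentages (27%, 83%, 67%) arise from a genuine round trip through
interval overlap, not from bookkeeping.

# Numerical choices and problem sizes

Monte-Carlo validation in the tests and the acceptance script uses 100
replicate curves/titrations per scenario, which stabilizes the mean and
median error statistics well below their pass margins while keeping the
whole suite in tens of seconds. Observed performance under the default
conditions: mean |Tm error| ≈ 0.3 °C with |bias| < 0.1 °C; median relative
ΔH error ≈ 4%; mean |pH_T error| ≈ 0.015. Noiseless inputs recover their
generating parameters to numerical precision (the van't Hoff regression is
exact because the generating model is exactly linear in ln K_a vs 1/T).

Tie-breaks and degeneracies: equal derivative extrema resolve to the lowest
temperature with a `multiple_extrema` flag; zero-variance replicate groups
with equal means give p = 1 (flagged) rather than NaN; a screen with zero
methylated sequences reports undefined downstream percentages rather than
0/0.

# Known limitations

* The two-state assumption is structural: multi-state melts will fit, but
  the reported ΔH is then an apparent value (the r² of the van't Hoff
  regression is the diagnostic to watch).
* The first-derivative Tm inherits the grid resolution; below ~1 °C spacing
  the parabolic refinement dominates and the estimate is effectively
  continuous.
* The screen maps calls by position only; it cannot detect assembly
  mismatches between the sequence intervals and the methylation track —
  that responsibility is documented as the caller's.
* `classify_cd_spectrum()` is a signature test on two reference states, not
  a secondary-structure deconvolution.
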