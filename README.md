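# epimotif

Stability analysis of epigenetically modified i-motif DNA.

i-Motifs are four-stranded DNA structures assembled from C-rich sequences:
two intercalated hairpins held together by hemi-protonated C:C⁺ base pairs,
typically favored at acidic pH. Because the structure is built from
cytosines, the epigenetic marks **5mC, 5hmC, 5fC and 5caC** can tune its
stability, and the sensitivity depends strongly on *which* cytosine is
modified — the positions flanking the first and third loops are the most
responsive. `epimotif` is for biophysicists and genome biologists who
measure that tuning: it turns raw UV melting ramps, CD pH titrations and
absorbance spectra into thermodynamic and pH-stability parameters, and
screens i-motif forming sequences against methylomes from two cell lines.

## What it computes

**UV melting thermodynamics** (absorbance at 295 nm vs temperature). For an
intramolecular two-state melt with fraction folded θ, the association
constant is K_a = θ/(1−θ) and

    ln K_a = −ΔH/(RT) + ΔS/R,    T_m = ΔH/ΔS  (K_a = 1 at the midpoint)

The pipeline gives the first-derivative T_m, linear folded/unfolded
baselines, θ(T), and ΔH, ΔS from the van't Hoff regression of ln K_a on
1/T restricted to θ ∈ [0.15, 0.85], with replicate mean ± SD and two-sided
Welch t-tests against a control.

**Transitional pH** from CD. Ellipticity at 288 nm vs pH is fitted with a
Hill-type sigmoid `E = E_u + (E_f − E_u)/(1 + 10^(h(pH − pH_T)))`; the
inflection pH_T is the pH-stability readout ("neutral" i-motif formers have
pH_T ≥ 6.8). CD spectra are classified i-motif / unstructured /
indeterminate from the 288 nm peak and 255 nm trough; thermal difference
spectra (unfolded 95 °C minus folded 4 °C, maximum normalized to exactly
+1) are tested for the i-motif signature (+240 nm peak, −295 nm trough).

**Methylation screen.** C-rich sequences are decomposed into C-tracts,
loops and flanks; every cytosine gets an ordinal and role (tract-terminal
cytosines know which loop they touch). Per-cytosine beta values from two
cell lines are overlaid by genomic interval overlap, and the cohort is
summarized: % methylated, % differentially methylated, % methylated next
to loops 1/3, the neutral/acidic split, and a pooled two-proportion z-test.

**Synthetic data.** Generators for melting curves, titrations, CD/TDS
spectra, the 48-variant single-modification ledger of the human telomeric
i-motif (hTeloC, `TCCCTAACCCTAACCCTAACCCAA`), and a two-cell-line screen
fixture with planted ground truth (FASTA + BED + bedGraph output).

## Worked example

Triplicate synthetic melts of the unmodified control scenario
(T_m = 39.7 °C, ΔH = −160 kJ/mol, 0.002 AU noise), analyzed end to end:

```r
library(epimotif)
curves <- lapply(1:3, function(r)
  simulate_melt_curve(two_state_params(noise_sd = 0.002, seed = r),
                      replicate_id = r))
analyze_replicates(curves)$summary
#>   parameter      mean       sd
#> 1  Tm_deriv   39.6808  0.60499
#> 2     Tm_vH   40.2714  0.77920
#> 3        dH -157.7232 11.25353
#> 4        dS   -0.5033  0.03707
```

The derivative T_m lands on the planted 39.7 °C, the van't Hoff route
agrees within its own scatter, and ΔH/ΔS recover the generating
−160 kJ/mol and −0.511 kJ/(mol·K) within noise.

```r
fit_titration(simulate_titration(
  titration_params(pHT_true = 6.0, hill = 2, noise_sd = 0.16, seed = 1)))
#> <titration_fit> pHT = 6.010, hill = 2.17, plateaus 9.88/2.08 mdeg, r2 = 0.9988
```

A 2%-noise titration returns pH_T within 0.01 of the planted value. The
screen fixture round trip recovers its planted cohort exactly:

```r
fx <- make_screen_fixture(seed = 1)   # 44 sequences, 12 methylated planted
summarize_screen(screen_sequences(fx$sequences, fx$calls_A, fx$calls_B))
#> <screen_summary>
#>   methylated:             12/44 (27%)
#>   differential:           10/12 (83%)
#>   loop-adjacent:          8/12 (67%)
#>   neutral among meth.:    10/12 (83%)
#>   acidic among meth.:     2/12 (17%)
#>   neutral vs acidic methylation: z = 4.789, p = 1.678e-06
```

A command-line interface wraps the same functions
(`inst/scripts/epimotif`): subcommands `ledger`, `simulate`, `melt`,
`titrate`, `tds`, `screen`.

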