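# translocatr

Quantitative subcellular fractionation turns "where is this protein?" into a
measurable profile: cells are split into sequential chemical extracts
(FR1–FR6, enriching cytosol, membrane-bound organelles and the
nucleus/nucleolus), and each protein or phospho-site is quantified per
fraction, condition and replicate by mass spectrometry. `translocatr` is an
R package for analysing such data end to end, aimed at proteomics groups
studying spatio-temporal signalling (growth-factor stimulation, stress
responses) who need a statistically controlled answer to *which proteins
moved, from where to where, and when*.

## What it computes

**Movement score.** Per feature and time point, intensities are scaled to
fraction proportions, `s_f = I_f / Σ_f I_f`, averaged over replicates. With
`Δ_f = s_f(t) − s_f(control)`, the acceptor is `argmax Δ`, the donor
`argmin Δ`, and the score

```
M = (Δ[acceptor] + |Δ[donor]|) / 2
```

is the proportion of the protein's distribution that shifted between its
top gaining and top losing fraction (equal to the moved mass for a clean
two-fraction move). Moves are categorised by the neighbourhoods they
connect — cytosol (FR1–2), membrane organelles (FR3–4), nuclear (FR5–6).

**Significance.** A genuine translocation must change in *both* fractions,
so the per-fraction empirical-Bayes moderated t-tests (variances shrunk
toward a moment-matched prior, `s²_post = (d₀s₀² + d_g s²_g)/(d₀ + d_g)`)
supply p-values for the donor and acceptor fractions, combined by Fisher's
method, `X² = −2(ln p_donor + ln p_acceptor) ~ χ²₄`, and BH-corrected across
features within each time point. Candidates require `M ≥ 0.1` and
`q < 0.05`.

Around this core the package provides per-fraction preprocessing (minimum
3 valid values per group, cyclic-loess normalization, neighbour-average
imputation for partially observed values and 2.5th-percentile imputation
for whole-condition missingness), marker-based compartment assignment
(k-means + marker voting with precision/recall/F-scores), marker–centroid
profile correlations, group distribution percentages with paired t-tests,
and a synthetic-data generator with known ground truth.

## Worked example

```r
library(translocatr)

sim   <- simulate_fractionation(n_features = 500, seed = 42)  # known truth
clean <- preprocess(sim$data)                                 # filter/normalize/impute
res   <- translocation_analysis(clean, reference = "ctrl")
res
#> <translocation_result> reference 'ctrl', score >= 0.1, q < 0.05
#> # A tibble: 2 × 3
#>   condition n_tested n_called
#>   <chr>        <int>    <int>
#> 1 stim1          431       22
#> 2 stim2          426       21

head(dplyr::filter(tidy(res), called), 5)
#>   feature condition score donor acceptor category           q_value
#> 1 P0132   stim1     0.316     3        1 cytosol-membrane 1.75e-151
#> 2 P0449   stim1     0.253     5        1 cytosol-nuclear  4.27e-141
#> 3 P0261   stim1     0.321     2        1 within           1.02e-126
#> 4 P0033   stim1     0.308     3        1 cytosol-membrane 2.34e-111
#> 5 P0065   stim1     0.379     4        2 cytosol-membrane 3.81e- 47
```

Each called row says: this feature moved `score` of its distribution from
fraction `donor` to fraction `acceptor` at that time point, with BH-adjusted
combined significance `q_value`. Of the 25 translocators injected by the
simulation above, 22 are recovered at the default thresholds.
`autoplot(res)` draws the score-versus-significance plot with the cutoff
lines; `assign_compartments()` + `score_compartments()` give per-compartment
precision/recall/F for a marker list; `group_fraction_percentages()` +
`paired_fraction_test()` handle complex-level redistribution (e.g.
ribosomal subunits).

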