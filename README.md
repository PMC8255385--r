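# groupitizr

Tools for studying **groupitizing in audition** — the improvement in
numerosity estimation that appears when a set of items is clustered into
small, subitizable groups. The package closes the loop for the auditory
version of the paradigm:

1. **Stimulus scheduling and rendering.** 1.4-s sequences of 50-ms pure
   tones (numerosities 5–12), either *unstructured* (regular timing plus 10%
   ISI jitter), *grouped by tone frequency* (clusters share a pitch from
   400/700/1000 Hz, adjacent clusters differ), or *grouped by ISI* (clusters
   of consecutive slots on a 12-slot grid, separated by silence). Sequences
   render to 16-bit WAV with 20-ms raised-cosine ramps at 8192 Hz.
2. **Synthetic Weber-law observers.** Trial-level estimates follow scalar
   variability — `response ~ max(1, round(Normal(b·N, w·N)))` — with
   condition-specific generative coefficients of variation (defaults 0.12 /
   0.10 / 0.09 for unstructured / frequency-grouped / ISI-grouped) and
   lognormal inter-individual variability shared across conditions.
3. **The precision analysis.** 3-SD outlier exclusion per cell; CV = σ/N;
   grouping advantage (CVu − CVg)/CVu × 100; condition × numerosity fully
   within-subject repeated-measures ANOVA with partial η² =
   F·df₁/(F·df₁ + df₂); Bonferroni-corrected paired t-tests with Cohen's
   d = t/√n; default (JZS, Cauchy scale √2/2) Bayes factors reported as
   log₁₀ BF₁₀; and a low/high numerosity range split (5–7 vs 9–11).

Because the observer's parameters are known, the whole pipeline is
validated by parameter recovery: analysing a simulated cohort must return
the precision values that generated it.

## Worked example

```r
library(groupitizr)

# one ISI-grouped stimulus: 9 tones in clusters 2+3+4 on the 12-slot grid
isi_grouped_sequence(9)
#> stimulus_sequence: isi_grouped, numerosity 9, pattern 2+3+4
#>   onset_ms duration_ms frequency_hz group_index
#>     0.0000          50          700           0
#>   122.7273          50          700           0
#>   490.9091          50          700           1
#>   ...
#>  1350.0000          50          700           2

# simulate the default cohort (14 participants x 3 conditions x N 5-12 x 25
# trials) and run the full analysis
tab <- simulate_cohort(seed = 1)
run_pipeline(tab)
#> Auditory groupitizing analysis
#>   322 cells, 178 trials excluded by the 3-SD filter
#>   grand-mean CV: freq_grouped = 0.110, isi_grouped = 0.095, unstructured = 0.127
#> Repeated-measures ANOVA (dv: cv)
#>   condition              F(2, 26) = 47.6, p = 2.04e-09, partial eta^2 = 0.79
#>   numerosity             F(6, 78) = 1.01, p = 0.426, partial eta^2 = 0.07
#>   condition:numerosity   F(12, 156) = 0.876, p = 0.572, partial eta^2 = 0.06
#> Post-hoc paired t-tests on condition-mean CVs:
#>   freq_grouped vs isi_grouped      t(13) = 4.84, p_bonf = 0.000977, d = 1.29, log10 BF = 2.01
#>   freq_grouped vs unstructured     t(13) = -7.09, p_bonf = 2.45e-05, d = -1.89, log10 BF = 3.42
#>   isi_grouped vs unstructured      t(13) = -7.76, p_bonf = 9.33e-06, d = -2.07, log10 BF = 3.79
#> Grouping advantage: freq_grouped = 12.0%, isi_grouped = 23.3%
#>   range low          mean =  17.7%  t(83) = 6.17, p = 2.4e-08, d = 0.67, log10 BF = 5.70
#>   range high         mean =  16.9%  t(83) = 8.04, p = 5.53e-12, d = 0.88, log10 BF = 9.19
#>   range high_vs_low  mean =  -0.8%  t(83) = -0.23, p = 0.817, d = -0.03, log10 BF = -0.91
```

Reading the output: the 3-SD filter removed 178 of 8400 trials (~2%).
Grand-mean CVs sit near their generative values (0.12 / 0.10 / 0.09) — the
small upward shift is the expected effect of integer rounding on the
response SD. The condition effect on CV is strongly significant, both
grouped conditions beat the unstructured baseline (negative t: smaller CV),
grouping by ISI improves precision by ~23% and by frequency ~12%, and the
advantage is statistically indistinguishable between the low (5–7) and high
(9–11) numerosity ranges.

Stimuli can be written to disk (`write_stimulus()` produces a WAV plus a
CSV event table), whole runs reproduced from a YAML config
(`end_to_end()`), and everything driven from a shell via the thin CLI in
`inst/cli/groupitizr` (`generate`, `simulate`, `analyze`, `run`
subcommands).

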