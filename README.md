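# rhythmnest

Hierarchical rhythm analysis of annotated vocal sequences: detecting
isochrony, and isochrony *nested inside* isochrony, in two-stratum pulse
trains such as great-ape long calls.

## Who this is for

Bioacousticians with event-level annotations (Raven selection tables or
plain CSV/TSV: begin/end times, element type, call and individual IDs)
who want to ask whether a vocal display is rhythmically regular at one or
more temporal strata, how the strata relate, and whether the lower-stratum
element types are acoustically distinct once individual identity is
controlled for. The package consumes annotation tables only — it never
reads audio.

## The statistics at its core

For same-type elements of one call, inter-onset intervals are
`t_k = onset_{k+1} − onset_k`, and the rhythm ratio of adjacent intervals
is

    r_k = t_k / (t_k + t_{k+1})

`r_k = 0.5` is perfect isochrony (1:1 rhythm); a 1:2 alternation puts
ratios at 1/3 and 2/3. Around that primitive the package builds:

* **Ratio densities and peaks** — Gaussian KDE on [0, 1], with the peak
  restricted to (0.400, 0.600) as the isochrony-reporting value.
* **Isochrony band counts** — on-band (0.440, 0.555) vs off-bands
  (0.400, 0.440) ∪ (0.555, 0.600), strict inequalities.
* **Band-preference model** — negative-binomial GLMM of per-cell counts
  on `element_type * band` with `log(band width)` offset and a random
  intercept per individual, full-vs-null likelihood-ratio test, and
  Bonferroni-adjusted per-type on-vs-off contrasts
  (`fit_band_count_model()`), plus an exact-binomial cross-check.
* **Nested tempo ratios** — each sub-pulse `t_k` divided by its enclosing
  full pulse's `t_k`; the density peak of that quantity is the
  cross-stratum tempo relation (e.g. 0.046 ≈ 1:22), and a paired
  quartile-extent Wilcoxon test quantifies its peakedness
  (`pair_nested_iois()`, `nested_density_peak()`,
  `quartile_extent_test()`).
* **Crossed permuted DFA** — LDA over seven acoustic measures with
  permutations of the test factor confined to individual blocks,
  balanced selection, cross-classification, and a permutation p-value
  (`pdfa_crossed()`).
* **A synthetic two-stratum generator** (`generate_dataset()`) that draws
  event tables and acoustic features with the full nested structure, so
  every stage is testable without field recordings.

## Worked example

```r
library(rhythmnest)

ds <- generate_dataset(synthetic_spec(), seed = 1)   # ~12,000 events
report <- analyze_long_calls(ds$events, model_method = "glm")
print(report)
```

```
Long-call rhythm report
  intervals per type (raw -> filtered):
    full_pulse              1639 ->  1639
    grumble_sub_pulse       3552 ->  3552
    sub_pulse_transitory    1388 ->  1388
    pulse_body                 0 ->     0
    bubble_sub_pulse        4754 ->  4754
  restricted ratio-density peaks:
    full_pulse             0.511
    grumble_sub_pulse      0.505
    sub_pulse_transitory   0.501
    bubble_sub_pulse       0.499
  skipped (too few ratios): pulse_body
  nested sub/full tempo-ratio peak (pooled): 0.070 (~1:14)
  band model LRT: Chisq = 87.45, df = 7, p = 4.13e-16
```

Reading it: all four strata with ratio data peak near 0.5 — each is
isochronous (peak-location noise is about ±0.01 at these sample sizes).
Pulse bodies occur as isolated single elements, so they yield no
same-parent interval pairs and are skipped, as in real tables. The
pooled nested peak says sub-pulse intervals run at about 1/14 of their
enclosing pulse's interval for this draw (the generator's per-type tempo
ratios are 0.070, 0.141 and 0.110; the pooled peak sits on the most
concentrated type). The likelihood-ratio test rejects the
width-proportional null: on-isochrony ratios are over-represented.

```r
res <- pdfa_crossed(ds$acoustics, acoustic_variables(), seed = 1)
print(res)
```

```
Crossed permuted discriminant function analysis
  test factor sub_pulse_type within control factor individual_id (11232 cases, 7 variables)
  correctly classified, selected cases: 65.9% (expected 35.2%)
  correctly cross-classified:           71.5%
  p = 0.000999 (1000 permutations within individual_id blocks)
```

The three sub-pulse types are acoustically separable (65.9% correct
against a permutation chance of 35.2%; p at the attainable minimum for
1000 permutations).

File-level entry points (`simulate_run()`, `analyze_run()`,
`pdfa_run()`) write JSON/TSV reports with a reproducibility manifest; a
thin command-line wrapper lives at `inst/cli/rhythmnest-cli.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package: the rhythm ratio of
a perfectly periodic event train, and the restricted ratio-density peak
of the full-pulse stratum of the default synthetic dataset generated at
the given seed. Results are written as JSON to `--out`.
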