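---
title: "Detecting nested isochrony in two-stratum vocal sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nested isochrony in two-stratum vocal sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Some animal vocal displays are built on two temporal strata: a train of
*full pulses* recurring near one tempo, with each pulse itself composed of
faster *sub-pulses* of one of several acoustically distinct types. When
both strata are rhythmically regular, the signal exhibits *nested
isochrony* — a self-embedded temporal pattern, with the same organizing
principle (constant-tempo repetition) recurring at two scales. rhythmnest
implements the statistical machinery for detecting and quantifying that
structure from annotated event tables: no audio is touched, only begin/end
times plus categorical annotations and, for the discriminant analysis,
per-element acoustic measures.

The core statistic is the rhythm ratio of two temporally adjacent
inter-onset intervals,

$$ r_k = \frac{t_k}{t_k + t_{k+1}}, \qquad
   t_k = \text{onset}_{k+1} - \text{onset}_k , $$

computed within runs of same-type elements of one long call (and, for
sub-pulse types, within one enclosing pulse by default). Perfect
isochrony gives $r_k = 0.5$; a 1:2 alternation gives $r_k \in \{1/3,
2/3\}$. The ratio is invariant to any global rescaling of time, which
makes it comparable across individuals with different absolute tempi.
Whether a stratum is isochronous is asked three ways, mirroring the
protocol lineage this package follows:

1. **Density peaks.** A Gaussian kernel density of the $r_k$ sample; the
   peak restricted to the reporting window $(0.400, 0.600)$ is the
   headline location, with the global peak also reported.
2. **Band counting.** Counts of $r_k$ inside the on-isochrony band
   $(0.440, 0.555)$ versus the flanking off-isochrony bands
   $(0.400, 0.440) \cup (0.555, 0.600)$, compared by a count model.
3. **Cross-stratum nesting.** Each sub-pulse $t_k$ divided by the
   interval of its enclosing full pulse (onset-to-next-onset, consistent
   with intervals defined from begin times only). The peak of that
   nested-ratio distribution is the tempo relation between strata — e.g.
   a peak near 0.046 is a 1:22 nesting, far from any small-integer
   harmonic relation.

## Tunable parameters that matter

| Parameter | Default | Units | Why this value |
|---|---|---|---|
| IOI filter | $0.025 < t_k < 5$ | s | excludes sub-resolution annotation
  artifacts and gaps that are pauses, not rhythm; strict bounds |
| on-isochrony band | $(0.440, 0.555)$ | ratio | brackets 0.5; width 0.115 |
| off-isochrony bands | $(0.400, 0.440), (0.555, 0.600)$ | ratio | width 0.085 total |
| KDE bandwidth | Silverman (`nrd0`) | ratio | the conventional default;
  exposed for sensitivity analysis |
| KDE grid | 512 points on $[0,1]$ | — | resolution ≈ 0.002 ratio units |
| `within_parent` | `TRUE` for sub-pulse types | — | cross-pulse gaps
  reflect the pulse-level tempo, not the sub-pulse tempo |

Band membership uses strict inequalities exactly as the band definitions
are written; a ratio equal to a boundary belongs to no band. For
continuous data these are measure-zero events, so nothing of consequence
hangs on the convention, but it keeps counting reproducible.

## The band-preference count model

Because the on band (width 0.115) is wider than the off bands (0.085
combined), raw counts cannot be compared directly. The model is a
negative-binomial GLMM of the per-cell count (cell = element type ×
individual × band) on `element_type * band` with `log(band_width)` as an
exposure offset and a random intercept per individual; the null model
keeps only offset and intercepts. A likelihood-ratio test compares the
two, and per-type on-vs-off Wald contrasts are Bonferroni-adjusted
(positive estimates = more on-isochrony density than the widths predict).

Two numerical choices deserve notice:

* **Dispersion is estimated under the null model** and carried into both
  fits, so the LRT compares one family. Estimating it under the full
  model is upward-biased in these small tables (the extra parameters
  absorb dispersion), which we measured to make the LRT markedly
  anticonservative (≈14% type-I error at nominal 5%); the null-model
  estimate brings it back into the 4–8% calibration band that the test
  suite checks over 500 null simulations. The price is some conservatism
  when effects are large — immaterial at the effect sizes this analysis
  is used for.
* **Fallback chain.** Ten individuals is few for variance-component
  estimation, so if the random-intercept fit fails the model refits as a
  fixed-effect negative-binomial GLM with individual as a covariate and
  flags the fallback in the result. The calibration simulations in the
  test suite use this fixed-effect route directly (`method = "glm"`):
  500 random-intercept fits would exceed a sensible test budget, and the
  LRT being calibrated — full vs null with the individual term present
  in both — is structurally identical in the two routes.

A model-free cross-check, `binomial_band_check()`, runs a one-sided exact
binomial test per type with null proportion $0.115/0.200 = 0.575$.

## The quartile-extent test

The peakedness of the nested-ratio distribution is tested per unit
(default: long call): sort the unit's ratios, split them into four
equal-count blocks, and compare the *central extent* with the
*peripheral extent* by a paired one-sided Wilcoxon signed-rank test
across units (exact null for ≤ 25 units, normal approximation with
continuity correction otherwise).

"Extent" needed an operational definition, and the obvious one — the
range of the two central blocks pooled versus the two peripheral blocks
pooled — is degenerate: the pooled peripheral blocks span the whole
sample, so their range is *always* at least the central range and the
test could never calibrate. We therefore define the extent of a pair of
blocks as the **sum of the two per-block ranges**. For a uniform sample
all four blocks span equal ranges in expectation, so central and
peripheral extents are equal in expectation and the p-value is
approximately uniform (checked by simulation in the test suite); for a
peaked sample the central blocks are compressed and the test gains
power. The unit of pairing is exposed (`unit =`) because published uses
of this test do not pin it down; with a different unit the statistic
changes, so the default is a documented choice, not a reconstruction of
any particular published value.

## The crossed permuted discriminant analysis

Whether sub-pulse types are acoustically distinct — and not merely
individually distinct — is tested with a crossed permuted discriminant
function analysis over seven spectro-temporal measures (duration, peak
frequency, peak time, mean and maximum peak-frequency-contour slope,
mean entropy, signal-to-noise ratio). The crossed design controls for
individual identity by permuting type labels **only within individuals**;
a label never crosses an individual block (the test suite asserts this on
traced permutations).

Design choices, stated because the procedure's original implementation
is not published line-for-line:

* Balanced selection: within each individual, the per-type selection
  size is that individual's smallest cell (optionally capped), so every
  individual contributes evenly; held-out cases form the
  cross-classification set.
* The classifier is a Fisher LDA with pooled within-class covariance and
  proportional priors; an optional ridge (fraction of the mean diagonal)
  handles collinear feature sets. LDA is affine-invariant, so features
  enter untransformed by default; a standardization flag exists purely
  for numerical conditioning.
* Chance level is the mean of the permutation null, not $1/k$:
  resubstitution on finite selections inflates accuracy above $1/k$
  even for random labels, and the permutation null inherits exactly
  that inflation, which is why published expected values exceed $1/k$.
* The p-value uses the add-one convention,
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{perm}} + 1)$,
  so its minimum with 1000 permutations is about 0.001.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` draws the world the analysis assumes: ~10
individuals, ~66 long calls, ~25 pulses per call at a mean interval of
1.696 s (marginal cv 0.3), each pulse carrying one sub-pulse type whose
mean interval is type-specific (grumble 0.118 s, transitory 0.239 s,
bubble 0.186 s; marginal cv 0.3), positional layout (grumbles early,
transitory mid, bubbles late), a few single-element pulse-body pulses
(so that type yields no same-parent interval pairs — the degenerate edge
real tables also show), and 7-dimensional acoustic vectors with
type-specific means separated by ~1.5 pooled SDs, a regime where
discriminant accuracy is meaningfully between chance and 100%.

Timing jitter is multiplicative lognormal (mean-one), so intervals stay
positive and cv is scale-free. Critically, the log-variance is split
into a **slow per-call tempo factor shared by both strata**
(`tempo_coupling = 0.85` of the variance) and fast independent
per-interval jitter. This is a structural commitment, not a dial: tempo
is a slow variable (a call runs near one tempo; tempo differs between
calls and individuals), and sub-pulse tempo is locked to the call's
pulse tempo — which is precisely what "nested isochrony" asserts. The
shared factor cancels both from adjacent-interval ratios (so each
stratum's $r_k$ concentrates at 0.5) and from the sub/full nested ratio
(so its peak recovers `sub_tempo_mean / full_tempo_mean`). With fully
independent jitter (`tempo_coupling = 0`) neither holds: the nested
ratio is then a ratio of independent lognormals whose mode sits below
the tempo ratio by $e^{-2\sigma^2}$ — a 16% shift at cv 0.3 — and the
pulse-level ratio distribution becomes flat-topped enough that its
density argmax wanders outside (0.48, 0.52). Both worlds are available;
only the coupled one is the package default.

Not emulated: long-call climax structure, amplitude and frequency
contours (beyond the seven summary features), inter-call behavioural
context, annotation error, and recording dropouts. A green test on this
generator therefore establishes that the *pipeline* recovers the
structure it is pointed at — not that field recordings contain that
structure, which only the field tables can show.

Other generator choices: per-individual tempo factors and acoustic
offsets (sd 0.1) create modest individual signatures; sub-pulse trains
are truncated at 95% of the enclosing pulse interval so nesting is
containment in time, not just in labels; `anisochrony_ratio` switches
the pulse stratum to an alternating short/long tempo for negative
controls (ratios at 1/3 and 2/3, empty on-band).

## Degenerate inputs and numerical conventions

* Fewer than 10 ratio values → classed insufficient-data error rather
  than a meaningless density.
* Filtering out an interior interval splits its sequence; ratios are
  never computed across the gap.
* A sub-pulse inside the final pulse of a call has no enclosing interval
  and contributes no nested ratio; unresolvable parents are skipped with
  a message, never fatally.
* All quartile-extent differences zero → p = 1, no evidence (rather than
  an error from the signed-rank routine).
* KDE peak locations are grid points (resolution ≈ 0.002); with
  Silverman bandwidths around 0.008 on ~1500 ratios, the argmax of a
  flat-topped symmetric distribution is itself noisy by roughly ±0.01 —
  peak values should be read at that precision, and the 3-decimal
  peaks reported in field studies are bandwidth-sensitive.

## Known limitations

* The band-count model's dispersion-under-null choice trades power for
  calibration; with very strong band preference the LRT statistic is
  conservative (the conclusions at realistic effect sizes are
  unaffected — all contrasts remain far beyond any threshold).
* `glmer.nb` on 10 individuals can fail to converge; the fallback is
  principled but changes the individual term from random to fixed.
* The quartile-extent statistic depends on the pairing unit, which the
  protocol lineage leaves unspecified; comparisons across studies should
  fix the unit explicitly.
* The pDFA's selection-size rule (per-individual minimum cell) is a
  documented stand-in for an unpublished original; results are stable
  under the cap (`n_to_sel`) but not guaranteed to match other
  implementations case-for-case.
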