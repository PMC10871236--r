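---
title: "How an AUPRC is actually computed: anchors, connectors, and the choices in between"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How an AUPRC is actually computed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prcaudit)
```

## The estimation problem

A binary classifier assigns each entity a score; thresholding at each
distinct observed score $t$ (positive $\iff$ score $\ge t$) produces
cumulative counts $(tp, fp)$ and hence one anchor point
$(R, P^{\mathrm{rec}}) = (tp/P,\; tp/(tp+fp))$ per threshold. The PR curve
is only *observed* at these anchors; the area under it is therefore an
estimate that depends on an interpolation model for the gaps. `prcaudit`
treats that model as an explicit, user-visible parameter rather than an
implementation detail.

Between adjacent anchors $A=(tp_A, fp_A)$ and $B=(tp_B, fp_B)$, with
$\Delta tp = tp_B - tp_A$ and $\Delta fp = fp_B - fp_A$, four connectors
are implemented:

* **line** — the straight chord; the segment area is the trapezoid
  $(\Delta tp/P)\,(p_A + p_B)/2$.
* **discrete expectation** — interior points on the expectation curve
  (below) at $s = 0.5, 1.5, \dots$ between untied anchors and
  $s = 1, 2, \dots$ across a tie block, joined by chords.
* **continuous expectation** — the expectation curve itself, integrated in
  closed form.
* **step** — the Average Precision rectangle $(\Delta tp/P)\, p_B$.

### The expectation curve

A tie block of $b$ positives and $c$ negatives at one score contributes a
single anchor. To draw a curve *through* the block one must posit how true
and false positives accrue inside it. The expectation interpolation
assumes false positives grow proportionally with true positives, giving
the precision after $s \in [0, \Delta tp]$ additional true positives:

$$p(s) = \frac{tp_A + s}{tp_A + s + fp_A + s\,\Delta fp / \Delta tp}.$$

This "linear-fp" form is the one consistent with a constant classifier
recovering the prevalence $P/(P+N)$ exactly, and with the behaviour of the
evaluation tools that advertise expectation interpolation. It is *not* the
combinatorial expectation under uniformly random orderings of the tied
entities, which is $E[fp \mid tp = s] = fp_A + s\,c/(b+1)$: the oracle
`permutationAverage()` computes the latter by exhaustive enumeration, and
the test suite verifies the closed form $s\,c/(b+1)$ and that the
linear-fp surrogate lies strictly above it in the interior. We implement
the linear-fp form as the package's expectation connector and keep the
combinatorial one as a measurable alternative rather than a user option,
because the two agree at block boundaries and the surrogate is what
deployed tools compute.

Integrating $p(s)$ over recall gives the closed form used by
`continuousSegmentArea()`: with $\beta = 1 + \Delta fp/\Delta tp$ and
$C = tp_A + fp_A$,

$$\mathrm{area} = \frac{1}{P}\left[\frac{\Delta tp}{\beta} +
\left(tp_A - \frac{C}{\beta}\right)\frac{1}{\beta}
\ln\frac{C + \beta\,\Delta tp}{C}\right],$$

with the logarithmic term dropped when its coefficient vanishes or
$C = 0$, and zero area for vertical segments ($\Delta tp = 0$). The test
suite checks this against composite quadrature (`quadratureSegmentArea()`,
Simpson combination of midpoint and trapezoid panels) to $10^{-9}$ over a
thousand random integer segments.

### Why the connector matters: a provable ordering

On a segment where precision falls from $A$ to $B$ the expectation curve
is convex, so rectangle, curve and chord areas order as
$\text{step} \le \text{continuous} \le \text{linear}$, strictly when
$b, c \ge 1$; the ordering reverses where precision rises. Falling
mixed tie blocks are exactly the situation produced by a discrete-score
classifier on an imbalanced task, which is why linear tie interpolation
is systematically optimistic there. The suite verifies the strict ordering
exhaustively for all block compositions $b, c \in [1, 6]$ appended to
clean (tie-free) prefixes.

## The full recipe: MethodSpec

`methodSpec(noTies, ties, startPolicy, endPolicy, tiePolicy)` fixes:

* `noTies` / `ties` — the connector used for one-entity segments and for
  multi-entity tie-block segments respectively. Mixed dispatch is per
  segment: this is how real tools combine their two documented methods.
* `startPolicy` — the curve's zero-recall vertex. `segment_limit`
  (default) uses the first segment's precision limit as $tp \to 0$, which
  for every connector equals the first anchor's precision; `fixed_0_1`
  forces $(0, 1)$; `first_anchor` omits the zero-recall region entirely.
* `endPolicy` — `full_recall` (default) or `truncate_at_last_distinct`.
* `tiePolicy` — `group` (default; ties form one anchor) or `input_order`
  (one anchor per entity, ties broken by row order).

The default
`(line, continuous_expectation, segment_limit, full_recall, group)` is the
combination in which none of the catalogued issues can arise.

Design decisions where the behaviour was genuinely open:

* **Truncation semantics.** "Not covering the full recall range" is
  realised as dropping the final anchor (the threshold equal to the
  minimum score), so the curve ends at the last anchor induced by a
  strictly interior threshold. Other partial-coverage behaviours exist in
  the wild; this one was chosen because it is the minimal, deterministic
  form of the defect and composes cleanly with every connector.
* **Forced (0, 1) start and non-chord connectors.** A forced start vertex
  enters the *area* only through connectors that integrate chords (line,
  and the first chord of the discrete expectation); rectangles and the
  closed-form integral have no term a start vertex could alter — which is
  precisely the conceptual inconsistency of forcing $(0,1)$ onto
  expectation or AP methods. For those connectors `fixed_0_1` therefore
  moves only the plotted vertex.
* **Degenerate inputs.** Zero positives is an error (classed,
  `prcaudit_no_positives_error`): no PR curve exists. Zero negatives is
  allowed — precision is identically 1, AUPRC is 1 — with a warning
  attached to the result. Precision at $tp + fp = 0$ is never evaluated;
  the virtual origin is handled through connector limits.
* **Exact tie grouping.** Scores form a tie group only under exact
  floating-point equality. No epsilon is applied, so behaviour is
  reproducible and callers who want coarser grouping can round scores
  explicitly.

## Tool profiles

`toolProfile()` exposes 13 presets named after widely used tools (two
variants each for scikit-learn, yardstick and PRROC), each a `MethodSpec`
plus integer issue flags 1–5 (linear ties; forced $(0,1)$ start;
incomplete recall range; input-order ties; omitted anchors). The presets
emulate the tools' *documented method combinations only*: tool-specific
programming bugs are deliberately out of scope, and flag 5 concerns which
vertices appear on a plotted curve, not the area. `compareMethods()`
reports distinct-value counts at a configurable rounding (default 3
decimal places, the scale at which published AUPRC values are read) and
`rankClassifiers()` produces rank matrices (rank 1 = largest, average
ranks on ties) and Pearson correlations between profiles' value vectors.

## The audit

`auditScores()` condenses a data set's exposure into four numbers: the
tie fraction (share of entities in multi-entity groups); the inflation
$\Delta_1$ = AUPRC(linear ties, forced start) − AUPRC(default); the
start-point effect $\Delta_2$ of forcing $(0,1)$ alone; and the
order sensitivity $\Delta_3$ = spread of AUPRC over seeded random row
shuffles (default 100) under `input_order`. For a constant classifier
with $P=3, N=2$, $\Delta_1 = 0.8 - 0.6 = 0.2$ exactly.

## Synthetic data

`simulateScores()` draws class-conditional Gaussian scores (unit
variance, positive class shifted by `separation`) and optionally
quantizes the pooled scores into `n_levels` equal-width bins — the
mechanism by which discrete-score classifiers generate tie blocks. Only
the rank structure of scores reaches any estimator, so the distributional
family is immaterial; Gaussians were chosen as the conventional
location-shift model. `tieBlockFixture()` constructs a data set whose tie
groups equal a requested $(b, c)$ sequence exactly, for reproducing
specific anchor configurations.

What the generator does *not* emulate: correlated scores, calibrated
probabilities, per-class score distributions with unequal variance or
heavy tails, and the particular single-cell or challenge data sets that
motivate the method catalogue. Passing tests on synthetic data therefore
demonstrate correctness of the estimators and the orderings among them,
not field performance of any classifier.

## Scales, tolerances and limitations

The property suites run at deliberately modest sizes chosen to make
brute-force verification exact: AUROC-vs-pairwise equality on 1,000
random data sets of up to 12 entities (integer-rational equality, no
tolerance); quadrature agreement at $10^{-9}$ with 2,000 Simpson panels;
exhaustive tie-block sweeps with $b, c \le 6$; permutation oracles capped
at $10^5$ enumerated orderings with a seeded sampling fallback. Audits
default to 100 shuffles. Floating-point "exact" limit assertions
(prevalence, perfect separation) use a $10^{-12}$ tolerance, i.e.
accumulation rounding only.

Known limitations: no multi-class or multi-label support; no partial-area
or confidence-interval machinery; no interpolation in ROC space (ROC
segments are straight by construction); curve rendering is limited to the
vertex export, by design. One caution worth stating explicitly: Average
Precision is *not* monotone in a single entity's score once tie groups are
involved — promoting a positive out of a large all-positive block can
lower AP, because the recall it covered at the block's high precision is
re-covered at a lone anchor's lower precision. The suite pins this with a
concrete counterexample (cross-checked against an independent
implementation); monotonicity holds, and is tested, on tie-free data.
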