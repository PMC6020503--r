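---
title: "Methods: symbolic gait sequence clustering and classification"
author: "gaitstrings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symbolic gait sequence clustering and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitstrings)
```

## The problem

Neurodegenerative diseases — Parkinson's disease (PD), Huntington
disease (HD) and amyotrophic lateral sclerosis (ALS) — disturb the
stride-to-stride rhythm of walking. The raw observable is a per-subject
time series of left-foot stride intervals (seconds per stride,
typically a few hundred strides from a timed walk). The question this
package answers is: can a subject be assigned to {ALS, HD, PD, healthy
control (CO)} from that series alone, while keeping the learned class
representation human-readable?

The approach is syntactic rather than numeric: each series becomes a
string over a small ordered alphabet, each class is summarised by a
few *prototype strings*, and classification is nearest-prototype
matching under edit distance. The prototypes can be plotted back
against the series that generated them, which is the main practical
attraction over black-box numeric classifiers.

## Pipeline and parameters

### Preprocessing

`preprocessStrides()` drops the first 20 strides (gait initiation is
not steady-state walking) and applies a single-pass 3-SD median
filter: the median and sample SD of the remaining series are computed
once, and strides farther than 3 SDs from the median are removed.
Defaults (`dropFirst = 20`, `sdMultiple = 3`) are the protocol's
values. A single pass was chosen over iterating-to-fixpoint: the
filter's purpose is to delete sensor artefacts (missed or doubled
heel-strikes), which are gross outliers caught on the first pass;
iterating would progressively eat genuine pathological variability.
The output is always an order-preserving subsequence of the post-drop
series.

### SAX symbolisation

`saxTransform()` z-normalises the series (population-SD convention,
with a `sdType` switch), applies piecewise aggregate approximation
(PAA) and maps each segment mean to a symbol using the A−1
standard-normal quantiles at probabilities i/A as cell boundaries.
Defaults: alphabet size A = 8 (`a..h`), segment count `w = n`, i.e.
one symbol per stride — the protocol's setting, which makes PAA the
identity and keeps the full stride-by-stride rhythm in the string.

Numerical conventions, chosen for determinism:

* cells are lower-inclusive: a value equal to a breakpoint maps to the
  higher cell, so exactly-zero values map to the fifth symbol `e` at
  A = 8;
* when `n` is not divisible by `w`, blocks have size `⌊n/w⌋` and the
  tail remainder is dropped (never triggered at `w = n`);
* a zero-variance series is an error, not a constant string —
  silently emitting `eeee…` would fabricate rhythm information.

On standard-normal input the eight cells are equiprobable; the test
suite checks each symbol's frequency to 12.5% ± 0.5% on 100,000
draws.

### Edit distance and median strings

All comparisons use unit-cost Levenshtein distance (insertions,
deletions, substitutions), computed by the C-level dynamic program in
`utils::adist()` and verified in the tests against an exhaustive
recursion over the whole 3-symbol language up to length 5. There is
no length normalisation: the protocol compares full-length strings of
similar size, and raw edit counts are what the clustering objective
weighs.

Three medians are provided:

* `setMedianString()` — the dataset member minimising total distance
  to all members;
* `weightedMedianString()` — the member minimising the weighted sum;
* `modifiedFuzzyMedian()` — a greedy search over *all* strings: from
  a start string, evaluate every single-symbol substitution, deletion
  and insertion, apply the edit with the largest cost decrease, and
  repeat until no edit improves or `maxPasses` (default 10) edits
  were accepted.

Ties are broken deterministically everywhere: lowest dataset index
for medians; substitution before deletion before insertion, then
position, then alphabet order for edits. `maxPasses = 10` bounds the
per-update work; since the search starts at the weighted set median
(already near-optimal) the greedy loop almost always stops earlier by
failing to improve, and on tiny instances (binary alphabet, length
≤ 4) it reaches the enumerated global optimum in the tests.

### The clustering model

`sgupfcmed()` minimises, over prototypes V, memberships U and
typicalities T,

$$J = \sum_{i=1}^{C}\sum_{k=1}^{N} (a\,u_{ik}^m + b\,t_{ik}^\eta)\,
      \mathrm{Lev}(s_k, sc_i)
    + \frac{\beta}{\eta^2 C}\sum_{i=1}^{C}\sum_{k=1}^{N}
      (t_{ik}^\eta \ln t_{ik}^\eta - t_{ik}^\eta),$$

with columns of U summing to 1. The fuzzy memberships give the
partition; the possibilistic typicalities are absolute (unnormalised)
degrees of belonging that decay exponentially with distance, making
the prototype update robust to outlier strings: an outlier has small
typicality in every cluster and therefore little pull on any median.
The scale β — the mean edit distance from the set median to all
strings — calibrates that exponential to the dataset's spread and is
computed once, on the set being clustered (per class in the
pipeline), before iterating.

The alternation is: membership update (closed form), typicality
update (closed form), prototype update (weighted modified fuzzy
median per cluster, weights $a\,u_{ik}^m + b\,t_{ik}^\eta$). Both
closed-form updates are exact minimisers given the other blocks, and
the prototype search only ever accepts cost improvements — the
previous prototype is kept as a candidate, which matters because
accepted prototypes can leave the dataset — so the recorded objective
is non-increasing across iterations (asserted to 1e−9 in the tests).

Defaults `m = η = 2`, `a = 1`, `b = 6`, `tol = 0.01` on
$\max|\Delta U|$, `maxIter = 100` are the gait protocol's settings.
`b = 6` weighs typicality six times the membership in the prototype
weights; in practice, with β of order the within-class spread, the
typicality factor is near 1 only for strings close to a prototype, so
it acts as a soft trimming of the median.

Numerical and degenerate-input choices:

* **Initialisation** (unspecified by the protocol): farthest-first
  traversal over the distinct strings — uniform first pick under the
  seed, then repeatedly the string with the largest minimum distance
  to the picks so far. A uniform sample of C strings was tried first
  and rejected: with two balanced clusters it starts both prototypes
  inside one cluster about half the time, and the alternation then
  settles in a local optimum that splits one cloud instead of
  separating the two. Farthest-first starts are deterministic under
  the seed and guarantee spread.
* **Convergence quantity**: $\max_{ik}|u_{ik}^{(t)}-u_{ik}^{(t-1)}|$,
  the bounded, scale-free choice for "change below 0.01".
* **Coincident prototypes**: if two clusters land on the same string,
  the duplicate is reseeded with the dataset string carrying the
  largest weighted-distance contribution to the objective. This is an
  anti-collapse restart, not a descent step; the model records reseed
  events (`@reseeds`), and on data with genuine cluster structure it
  does not fire.
* **Underflow**: typicalities that underflow the double exponential
  are clamped to the smallest positive double, keeping T in (0, 1];
  the entropy term uses the continuous extension
  $t^\eta\ln t^\eta - t^\eta \to 0$ at $t \to 0^+$.
* A dataset whose strings are all identical has β = 0 and is rejected
  (degenerate); C must be smaller than the number of distinct
  strings.

### Classification and protocol

`trainPrototypes()` clusters each class separately into p prototypes
and pools them with crisp one-hot class memberships.
`fknnClassify()` implements the fuzzy k-NN rule: the K nearest
prototypes by edit distance vote with weights
$(1/d)^{1/(m-1)}$; a zero-distance query takes its prototype's class
with membership 1 immediately. Neighbour ties are broken by distance
then class index, which makes predictions invariant to the order in
which prototypes were pooled; membership ties on the argmax go to the
class owning the nearest neighbour, then the lowest class index.

`runCV()` runs stratified n-fold cross-validation over subjects (one
SAX string per subject; held-out subjects never contribute to
clustering). Cells with $K > p \times$ (number of classes) are
reported as unavailable rather than an error, mirroring the dashes in
the protocol's result tables. For the best cell (highest mean
accuracy; ties to smaller p, then smaller K — the parsimony rule)
sensitivity is recall on the pooled diseased classes and specificity
recall on CO, computed per fold and summarised as mean ± SD; for the
4-class task predictions are collapsed to diseased-vs-CO after
classification.

## The synthetic generators

Real stride-interval recordings cannot be bundled, so the package
generates its own test populations; both generators are pure
functions of their seed.

`generateStringClusters()` plants known structure directly in string
space: each sample is a center string with independent per-symbol
substitutions. Substitution-only mutation (the default) keeps the
expected Hamming distance at `length × rate` in closed form for the
tests; an indel mode exists but is off by default.

`generateGaitRecords()` emulates stride series: a stationary AR(1)
process with template mean, SD and lag-1 autocorrelation, plus
occasional prolonged outlier strides, plus an optional deterministic
rhythmic stride-time modulation (a sinusoid with class-specific depth
and period). The modulation field deserves a note, because it is what
makes the four default class templates separable. The upstream
pipeline is deliberately invariant: z-normalisation removes mean and
scale, the equiprobable breakpoints flatten any marginal
distribution, and the 3-SD filter removes gross outliers — so
differences in stride mean, variability, autocorrelation or outlier
kurtosis leave almost no trace in the strings of *independent* AR
subjects (empirically, intra- and inter-class edit distances both sit
near 0.6–0.75 of the string length). A shared deterministic waveform
is the feature that survives: subjects of a class oscillate with the
same period, so their strings share a symbol pattern, while a
sinusoid's peak is only √2 of its SD contribution and therefore
always inside the 3-SD filter band at any amplitude. Rhythmic
stride-timing oscillation is also a recognised pathological gait
phenomenon (festination-like short cycles, slower oscillations in
chorea and weakness), which is why the default templates encode the
classes as periods 6 (PD), 10 (HD), 15 (ALS) and 24 (CO) strides at
depth 5 SD, on top of class-plausible means (1.10–1.35 s), SDs
(0.025–0.10 s) and increasing persistence.

What the fixtures do **not** emulate: long-range (fractal)
correlations of real gait, inter-subject heterogeneity of rhythm
within a class, non-stationarity over the walk, or any physiological
coupling between the template fields. Passing the synthetic
end-to-end check therefore demonstrates that the machinery —
preprocessing, symbolisation, clustering, pooling, fuzzy k-NN,
fold hygiene — is correct and recovers planted class structure; it
does not certify accuracy on clinical recordings, where the class
signal is weaker and of a different nature.

## Problem sizes

The test-suite and acceptance-script runs use sizes chosen to probe
each property at meaningful scale: exhaustive edit-distance
verification over all 364² pairs of the 3-symbol language up to
length 5; 10,000 random triples for the metric axioms; 50 seeded
two-cluster datasets (strings of length 10–16, 12–20 strings) for
objective monotonicity; planted-recovery fixtures with length-30
strings, 5% mutation, 20 strings per cluster over ten seeds; and a
synthetic cohort of 32 subjects (8 per class, 100 strides each)
for the cross-validated protocol. A full fit on one class of that
cohort takes a few seconds on one core; the complete acceptance
script runs in well under a minute.

## Known limitations

* The prototype update is a greedy local search; it inherits the
  usual local-optimum caveat of alternating minimisation, mitigated
  but not removed by farthest-first starts and the maximum-objective
  reseeding rule.
* Levenshtein distance with unit costs treats all symbol confusions
  equally, although adjacent SAX symbols are closer in value than
  distant ones; a graded substitution cost is a natural extension the
  protocol does not use.
* β is estimated once from the initial set; it is not re-estimated as
  clusters form, so very unbalanced within-class spreads share one
  typicality scale.
* One string per subject means the cross-validation unit is the
  subject; the package does not implement windowed/multi-string
  variants per subject.
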