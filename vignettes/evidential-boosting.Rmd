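---
title: "Evidential classification with boosted stumps: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidential classification with boosted stumps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsboost)
```

## The problem and the model

Multiclass classifiers usually emit a single label or a probability vector
over classes. In Dempster–Shafer evidence theory, belief is instead
distributed over *subsets* of the frame of discernment
$\Theta = \{\gamma_1, \dots, \gamma_{N_c}\}$ by a basic probability
assignment (BPA, or mass function) $m : 2^\Theta \to [0,1]$ with
$m(\emptyset) = 0$ and $\sum_{A \subseteq \Theta} m(A) = 1$. Mass on a
composite proposition such as $\{\gamma_2, \gamma_3\}$ expresses *ambiguity*
— the sample looks like either class — which a probability vector cannot
say. The hard part in practice is constructing a BPA from data; `dsboost`
implements a fully data-driven construction with no distributional
assumptions:

1. **Singleton mass from boosted voting.** For every unordered attribute
   pair $(i, j)$ and every unordered class pair, a binary AdaBoost ensemble
   of decision stumps is trained on the two-column view of the training
   table. A stump is $h(x) = \operatorname{sign}^*(\beta x^{(d)} - \beta\theta)$
   (attribute $d \in \{1,2\}$, threshold $\theta$, direction
   $\beta \in \{\pm 1\}$); round $t$ selects the stump minimizing the
   weighted 0–1 error $\varepsilon_t$, weights it by
   $\alpha_t = \tfrac12 \ln \frac{1-\varepsilon_t}{\varepsilon_t}$, and
   reweights samples by $w \propto w\,e^{-\alpha_t y h_t(x)}$. At prediction
   time the classifier for classes $(A, B)$ assigns
   $m_t(\{A\}) = \sum_{k : h_k(x) = +1} \alpha_k \big/ \sum_k \alpha_k$
   (the *vote fraction*) and $m_t(\{B\}) = 1 - m_t(\{A\})$.
2. **Composite mass from area ratios.** Each class's training points on the
   pair plane get an axis-aligned bounding box; all box intersections form
   a lattice with areas $\mathrm{area}(X^{(l)})$. If the sample lies in the
   intersection of the two classes' boxes, a share
   $S(X^{(l)}, X^{(l-1)}) = \mathrm{area}(X^{(l)}) / \mathrm{area}(X^{(l-1)})$
   of each singleton mass migrates to the two-class composite, and the
   recursion continues to larger composites whose intersection regions
   contain the sample:
   $m_{AR}(X^{(l)}) = S\, m_{AR}(X^{(l-1)})$,
   $m_{AR}(X^{(l-1)}) \leftarrow (1 - S)\, m_{AR}(X^{(l-1)})$.
   Total mass is conserved exactly.
3. **Fusion.** The $\binom{N_c}{2}$ reallocated masses of one attribute
   pair are averaged; the $\binom{n}{2}$ per-pair BPAs are fused with
   Dempster's rule
   $m(A) \propto \sum_{A_i \cap B_j = A} m_1(A_i) m_2(B_j)$, normalized by
   $1 - k$ where the conflict $k$ is the product mass on empty
   intersections. The decision is the singleton with maximal combined mass.

## Order of reallocation and averaging

The published pseudo-code of the source method reallocates *after* averaging
the one-vs-one votes, but its worked example (and the only printed
seven-focal-element BPA, which can only arise from averaging already
reallocated two-class masses) reallocates each one-vs-one mass *before* the
average. This package follows the worked example:
`evidential_fit(..., realloc = "per_classifier")` is the default. The
post-averaging reading is kept as `realloc = "post_average"` for comparison;
because an averaged mass can feed several composites at once there, outgoing
shares are capped at the available mass by proportional scaling, which keeps
the result a valid mass function in all cases.

For more than three classes the recursion step is ambiguous when several
composites could absorb mass simultaneously. The package absorbs candidate
classes one at a time in ascending frame order, discounting sequentially;
with three classes this reduces exactly to the single published chain
$\{A\},\{B\} \to AB \to ABC$. This is a documented package choice, not a
fact about the source method.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `T` | 20 | Boosting rounds (stumps) per one-vs-one classifier. The source experiments never state their value; 20 is enough for the stump ensemble to shape smooth vote fractions on Iris-sized data while staying fast. Configurable everywhere. |
| `realloc` | `"per_classifier"` | Reallocation order, see above. |
| `fraction` / `per_class` | — | Train/test split: pooled floor(N·fraction) rows (minimum 1), per-class fraction (`stratified = TRUE`), or an exact per-class count. The floor rule is a package choice; the source does not state its rounding. |
| `overlap` (generator) | 0.5 | Scales cluster support half-width `1.5·(1+overlap)` against center spacing 4, see below. |
| missing markers | `"?"` | UCI convention; incomplete rows are dropped per attribute pair at training, and pairs touching a missing attribute are skipped (not imputed) at prediction. |

## Numerical choices

- **Complete conflict**: combination raises an error when
  $1 - k < 10^{-12}$ rather than dividing by a vanishing normalizer.
- **Error clipping**: $\varepsilon_t$ is clipped to
  $[10^{-10}, 1 - 10^{-10}]$ before the log-odds weight, so a perfect stump
  gets a large finite $\alpha$; training stops after a perfect round (the
  weight update would collapse). If the very first stump cannot beat chance
  (symmetric XOR-type data) one stump is recorded with error clipped just
  below $0.5$ so that $\alpha > 0$ and the vote fraction is well defined.
- **Determinism**: threshold candidates are midpoints of consecutive sorted
  distinct values plus outer guards (half the smallest gap; 1 for constant
  columns) — this grid exhausts every labeling a stump can produce, so the
  search is globally optimal; ties break toward the lower attribute index,
  then lower threshold, then direction $+1$. Training has no randomness.
- **Mass validation**: user-supplied masses must total 1 within $10^{-6}$
  (published tables are truncated to 4 decimals — one reference row totals
  0.9999); internally produced masses are renormalized. All emitted masses
  satisfy $\sum m = 1$ within $10^{-9}$ and $m(\emptyset) = 0$.
- **Degenerate regions**: a zero-area region (a constant attribute within a
  class) propagates no mass: $S$ through it is 0 and the chain stops.
  Region membership is closed-interval on both axes, matching the inclusive
  published ranges.
- **Zero margin**: the plain-AdaBoost baseline maps a zero ensemble margin
  to $-1$; this never affects BPA generation, which uses per-stump votes.
- **Dense fast path**: the default prediction pipeline runs on numeric
  vectors indexed by a canonical subset order with a precomputed
  intersection table (bitmask set algebra). The object route
  (`mass_function()`, `reallocate()`, `ds_combine()`) is the reference
  implementation; the test suite asserts the two routes agree to $10^{-9}$
  and checks combination against a third, fully independent brute-force
  enumeration oracle.

## What the synthetic generator emulates — and what it does not

`synth_classes()` draws each class from a truncated Gaussian with support
exactly `center ± halfwidth` per attribute (sd = halfwidth / 2.5), so class
bounding boxes — the geometric object the method reasons about — are
controlled exactly. Defaults place class $c$ at $4(c-1)$ on every attribute
with half-width $1.5(1+\text{overlap})$: `overlap = 0` gives disjoint boxes
with margin 1 (reallocation provably inert), `overlap > 1/3` makes adjacent
boxes intersect. `synth_iris_like()` fixes the structure of the motivating
dataset: one separable class (centered at 0, half-width 1.5) and two
entangled ones (centers 5 and 7, half-widths 1.8 and 2.2, shared support
$[4.8, 6.8]$ on every attribute).

Real tabular data differ in ways the generator deliberately ignores:
attributes are correlated and non-Gaussian, class supports are not
rectangles, outliers inflate bounding boxes, and class priors are
unbalanced. A green test on synthetic data therefore establishes that the
pipeline implements the stated mechanics (conservation, combinatorics,
monotone accuracy in training size, inertness without overlap) — not that
any particular accuracy will be reached on a real dataset.

## Known limitations

- All $\binom{n}{2}$ attribute pairs are trained, so cost grows
  quadratically in the number of attributes; wide tables (e.g. 60-attribute
  sonar-type data) are slow in this implementation.
- Bounding boxes are sensitive to single outliers; robust (percentile)
  boxes are a future hook, not implemented.
- Dempster fusion of many near-certain, disagreeing pair BPAs can approach
  complete conflict; the package surfaces this as an error naming the
  offending pair rather than silently renormalizing.
- The evaluation harness reports means over Monte-Carlo repeats only; it
  does not compute variance bands.
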