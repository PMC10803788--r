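---
title: "Dynamic Fermatean fuzzy multi-attribute decision making with fermadm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic Fermatean fuzzy multi-attribute decision making with fermadm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermadm)
```

## The model

A Fermatean fuzzy number (FFN) encodes an expert judgement as a membership /
non-membership pair $(\mu, \nu) \in [0,1]^2$ constrained by
$\mu^3 + \nu^3 \le 1$. Cubing relaxes the intuitionistic constraint
$\mu + \nu \le 1$ and the Pythagorean $\mu^2 + \nu^2 \le 1$, so an expert may
simultaneously assert strong support and strong reservation — $(0.9, 0.6)$
is admissible — without renormalising their judgement. What the pair leaves
undecided is the indeterminacy $\pi = (1 - \mu^3 - \nu^3)^{1/3}$, so that
$\mu^3 + \nu^3 + \pi^3 = 1$ identically.

FFNs are ordered for ranking by the score $g = \mu^3 - \nu^3 \in [-1, 1]$;
equal scores fall through to the accuracy $H = \mu^3 + \nu^3$, and pairs
equal on both are reported as equivalent. A second, *componentwise* partial
order ($\mu_1 \le \mu_2$ and $\nu_1 \le \nu_2$, `ff_leq()`) exists in the
algebra; the two orders answer different questions and the package keeps
them as separate functions rather than conflating them. Containment-style
equality of two FFNs reduces to componentwise equality of the pairs, which
is how `ff_leq()`'s documentation resolves the otherwise circular
"mutual containment" phrasing of equality.

### Dynamic aggregation

When the same item is assessed at $p$ time periods with time weights
$\epsilon_k \in [0,1]$, $\sum_k \epsilon_k = 1$, the two closed-form
aggregators are

$$\mathrm{FFDyWA} = \Big(\sqrt[3]{\textstyle 1 - \prod_k (1-\mu_k^3)^{\epsilon_k}},\ \prod_k \nu_k^{\epsilon_k}\Big),
\qquad
\mathrm{FFDyWG} = \Big(\prod_k \mu_k^{\epsilon_k},\ \sqrt[3]{\textstyle 1 - \prod_k (1-\nu_k^3)^{\epsilon_k}}\Big).$$

Both arise by folding the dynamic operational laws $\oplus$ / $\otimes$
(`ff_add()`, `ff_mul()`) with the scalar laws (`ff_scale()`, `ff_power()`),
and both are closed on the constraint region, idempotent, bounded by the
componentwise min/max envelope, and monotone. They are De Morgan duals under
the complement $(\mu,\nu)^c = (\nu,\mu)$, and the averaging form dominates
the geometric form componentwise (weighted power-mean inequality). The test
suite asserts every one of these properties on at least a thousand seeded
random instances each, because the package treats the theorems as executable
contracts, not prose.

The per-period attribute aggregators `ffwa()` / `ffwg()` are the identical
closed forms with attribute weights $\omega_j$ substituted for
$\epsilon_k$ — one shared kernel, asserted identical in the tests. A
*different* operator circulates under the FFWA name: the componentwise
weighted arithmetic mean $(\sum_j \omega_j \mu_j, \sum_j \omega_j \nu_j)$.
The two do not agree (0.820 vs 0.841 membership on the same three-pair
example), and only the power form reproduces the case study's printed
overall values, so the pipeline canonically uses the power form while
`ffwa_arithmetic()` remains available as a separately named operation.

### The two-stage pipeline

A decision problem is an $m \times n \times p$ tensor of FFNs (alternatives
$\times$ attributes $\times$ periods) plus the two weight vectors.
`ff_decide()` composes:

1. `aggregate_time()` — each cell's $p$-length series pooled with
   FFDyWA/FFDyWG into the collective $m \times n$ matrix;
2. `aggregate_attributes()` — each row pooled with the power-form
   FFWA/FFWG into one overall FFN per alternative;
3. `rank_alternatives()` — scores, accuracies, and the total order.

Residual ties (score and accuracy both equal within $10^{-12}$) are kept as
explicit tie groups in input order rather than broken arbitrarily, since a
decision problem may legitimately have plural optima.

All attributes are treated as benefit-type: the case-study data include a
cost-flavoured attribute (side effects) yet the source analysis aggregates
all five columns uniformly with no complementing or normalisation, and the
package reproduces that choice rather than silently "fixing" it. Users who
wish to treat a column as a cost can complement its cells with
`ff_complement()` before building the tensor.

### Intuitionistic baselines

The comparative operators IFDWA/IFDWG are the exponent-1 members of the
same family, with linear score $\mu - \nu$. The kernel is parameterised by
the constraint exponent $q$, with $q = 3$ (Fermatean) and $q = 1$
(intuitionistic) surfaced; the tests assert that the generic kernel at
$q = 3$ is bit-identical to the Fermatean operators. Fermatean data
generally violate $\mu + \nu \le 1$, so the baseline runs default to
permissive validation and the report records every violating cell — that
mismatch is the substance of the comparison, not an error to be hidden.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `tol` (validation) | 1e-9 | slack on the power-sum constraint; absorbs decimal-literal rounding without admitting genuinely invalid pairs |
| `tol` (comparison) | 1e-12 | score/accuracy tie threshold; exact floating-point equality is meaningless |
| weight-sum tolerance | 1e-6 | user CSVs carry rounded weights; `normalize = TRUE` rescales exactly |
| `variant` | averaging | FFDyWA/FFWA vs FFDyWG/FFWG; averaging never scores below geometric |
| `family` | fermatean | exponent-3 operators vs the exponent-1 baselines |
| `mode` | strict (fermatean), permissive (intuitionistic) | abort on invalid cells vs flag and proceed |

## Numerical choices

* **Log-space products.** Weighted products are accumulated as exponentials
  of weighted log sums, so series of hundreds of periods do not underflow.
* **`log1p`/`expm1` on the complement path.** The averaging membership
  $\big(1 - \prod(1-\mu_k^3)^{\epsilon_k}\big)^{1/3}$ is computed as
  $(-\mathrm{expm1}(\sum \epsilon_k \log1p(-\mu_k^3)))^{1/3}$. With plain
  `pow`, $1 - \mu^3$ rounds to 1 for small $\mu$ and idempotency degrades to
  worse than $10^{-12}$ below $\mu \approx 2\times10^{-3}$; the `expm1` form
  holds it at $\sim 10^{-15}$ across the whole region.
* **Boundary conventions.** $0^0 := 1$ (a zero weight drops its period) and
  $0^\epsilon := 0$ for $\epsilon > 0$, with exact short-circuits when any
  factor is exactly 0 or 1, so idempotency and boundedness hold at the
  boundary rather than only in the interior.
* **Tiny negative radicands** within tolerance are clamped to zero before
  cube roots; anything larger signals an invalid pair and aborts.
* **Serialization.** Machine formats write doubles as decimal strings with
  17 significant digits, making write/read round trips bit-exact; the JSON
  reader accepts plain numbers too. Human-readable output rounds to three
  decimals, matching the field's reporting convention.

## Validation strategy

The suite validates against three independent anchors:

1. **Published worked values.** The dynamic-aggregation examples, the
   case-study collective matrix, overall values, scores and rankings, and
   the intuitionistic comparison table, all within an absolute tolerance of
   ±0.002 — the published values are rounded (sometimes truncated) to three
   decimals, and downstream score prints were evidently computed from
   3-decimal intermediates, so tighter agreement is not meaningful. Two
   printed values fail verification against their own defining formulas and
   are excluded as reference points: the non-membership 0.881 of one
   three-period geometric example (it violates the closure property its own
   theorem guarantees; the formula gives 0.681) and one collective-matrix
   membership printed as 0.647 where the closed form — and the identical
   series elsewhere in the same table — gives 0.674. The tests pin both
   discrepancies explicitly instead of widening tolerances around them.
2. **A naive direct-product oracle** (literal `prod()` over powers, no log
   space) on a thousand seeded random instances, within $10^{-12}$.
3. **A 50-digit high-precision oracle** (arbitrary-precision arithmetic via
   Python's mpmath) on seeded instances of up to 30 periods, within
   $10^{-12}$.

The synthetic generator `ff_simulate_tensor()` draws $\mu \sim U(0,1)$ and
$\nu \mid \mu \sim U\big(0, (1-\mu^q)^{1/q}\big)$ — the full admissible
interval, so property tests exercise near-boundary pairs. It emulates the
*structure* of an expert-filled decision tensor (valid cells, label sets,
weights), not its sociology: real panels produce correlated columns, round
their judgements to one decimal, and rarely use the extreme corners.
Passing property tests therefore certify the algebra and the pipeline
plumbing on arbitrary valid data, not the behaviour of any particular
expert panel. Problem sizes in the default test run are deliberately
modest (thousands of scalar aggregations, tensors up to $100 \times 10
\times 10$), chosen so the whole suite exercises every property densely
while remaining quick to run routinely.

## Known limitations

* Only exponents $q \in \{1, 3\}$ are surfaced; interval-valued, picture,
  spherical and general q-rung variants are out of scope.
* No ordered-weighted (OWA/OWG), Dombi, Hamacher or power-aggregation
  variants.
* No cost-attribute reversal, sensitivity analysis over the weight vectors,
  or multi-expert group aggregation.
* The score function is a total preorder: alternatives with different
  $(\mu, \nu)$ but equal score and accuracy are reported tied, which is a
  property of the ranking laws, not of the implementation.

## Session info

```{r}
sessionInfo()
```
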