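# fermadm

Dynamic multi-attribute decision making (MADM) with Fermatean fuzzy
evaluations.

Many real decisions — here, choosing among treatment modalities for acute
lymphoblastic leukemia — are scored by experts as *membership /
non-membership* pairs rather than crisp numbers, and the evidence is
collected repeatedly over time. A **Fermatean fuzzy number** (FFN) is a pair
(μ, ν) with μ, ν ∈ [0, 1] constrained by

    μ³ + ν³ ≤ 1,

which admits strongly conflicting judgements (for example (0.9, 0.6)) that
the intuitionistic (μ + ν ≤ 1) and Pythagorean (μ² + ν² ≤ 1) constraints
reject. FFNs are ranked by the score g = μ³ − ν³, with the accuracy
H = μ³ + ν³ breaking ties; the indeterminacy π = (1 − μ³ − ν³)^⅓ is the
residual hesitation.

`fermadm` implements the dynamic weighted aggregation operators over a
time series of FFNs F_k with time weights ε_k (ε_k ∈ [0, 1], Σε_k = 1):

    FFDyWA(F_1 … F_p) = ( (1 − ∏(1 − μ_k³)^ε_k)^⅓ ,  ∏ ν_k^ε_k )
    FFDyWG(F_1 … F_p) = ( ∏ μ_k^ε_k ,  (1 − ∏(1 − ν_k³)^ε_k)^⅓ )

and the two-stage ranking pipeline for an m × n × p decision tensor
(alternatives × attributes × time periods):

1. collapse the time dimension per cell with FFDyWA (averaging) or FFDyWG
   (geometric) under the time weights ε,
2. pool each alternative's row across attributes with the power-form
   FFWA/FFWG under the attribute weights ω,
3. score each overall value, 4. rank (ties reported as explicit groups).

The exponent-1 counterparts (IFDWA/IFDWG, score μ − ν) are included as the
classical intuitionistic baselines for comparison; both families share one
exponent-q kernel, computed in log space with `log1p`/`expm1` so long series
neither underflow nor lose precision near the boundary.

## Worked example

The packaged case study (`all_treatment()`) evaluates four leukemia
treatments — chemotherapy, stem-cell transplantation (HSCT), radiation, and
CAR T-cell therapy — against survival rate, remission, side effects,
efficiency and reliability over three periods, with time weights
ε = (0.2, 0.3, 0.5) and attribute weights ω = (0.3, 0.25, 0.1, 0.2, 0.15).

```r
library(fermadm)

# one cell: three periodic assessments pooled into a single FFN
ffdywa(ffn(c(0.7, 0.8, 0.9), c(0.6, 0.7, 0.5)), c(0.25, 0.3, 0.45))
#> # A tibble: 1 × 2
#>      mu    nu
#>   <dbl> <dbl>
#> 1 0.842 0.579

# the full two-stage pipeline
dec <- ff_decide(all_treatment(), variant = "averaging")
dec
#> <ff_decision> fermatean family, averaging variant (FFDyWA + FFWA)
#>   4 alternatives x 5 attributes x 3 periods
#> # A tibble: 4 × 7
#>   alternative     mu    nu score accuracy tie_group  rank
#>   <chr>        <dbl> <dbl> <dbl>    <dbl>     <int> <int>
#> 1 CAR-T        0.805 0.497 0.4      0.645         1     1
#> 2 Chemotherapy 0.75  0.504 0.294    0.55          2     2
#> 3 HSCT         0.738 0.625 0.157    0.646         3     3
#> 4 Radiation    0.622 0.531 0.091    0.391         4     4
#>   ranking: CAR-T ≻ Chemotherapy ≻ HSCT ≻ Radiation
```

Each row is an alternative's overall pair after both aggregation stages;
`score` = μ³ − ν³ drives the order, so CAR T-cell therapy (score 0.400)
is the optimal choice, and the same order emerges from the geometric
variant and from both intuitionistic baselines
(`ff_decide(..., family = "intuitionistic")`). `tidy()`, `glance()` and
`autoplot()` expose the report as tibbles and a score chart;
`read_ff_tensor()` / `write_ff_report()` handle the JSON/CSV interchange
formats; `ff_simulate_tensor()` draws seeded random tensors.

A command-line front-end ships in `inst/scripts/ffdm`:

```sh
Rscript inst/scripts/ffdm --input inst/extdata/all_treatment.json \
    --variant both --compare all --output report.json --format json
```

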