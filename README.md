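# crsim — similarity testing for parametric competing risks models

`crsim` answers a question that classical two-group comparisons cannot:
*are the event dynamics of two patient populations similar enough to be
treated as one?* The setting is competing risks — every subject can move
from an initial state to exactly one of k event states (e.g. hospital
readmission within 90 days of surgery for cause 1, 2 or 3) — with the
cause-specific transition intensities α₀ⱼ⁽ℓ⁾(t) of each group ℓ ∈ {1, 2}
modelled parametrically (exponential, Gompertz or Weibull per transition,
possibly time-varying and defective).

Similarity is measured by the maximum over transitions of the sup-norm
distance between the paired intensity curves on the observation window
𝒯 = [t\*, τ]:

    d = max_j  sup_{t ∈ 𝒯} | α₀ⱼ⁽¹⁾(t) − α₀ⱼ⁽²⁾(t) |

and the hypotheses are inverted relative to a classical test:

    H₀: d ≥ Δ    versus    H₁: d < Δ

so that *rejecting* H₀ certifies similarity (all transition intensities
within Δ of each other) at a controlled Type I error α. The reference
distribution of the statistic d̂ comes from a **constrained parametric
bootstrap**: when d̂ < Δ, both groups are re-fitted by joint maximum
likelihood under the boundary constraint d = Δ, bootstrap datasets (with
censoring regenerated from the fitted censoring model) are refitted without
constraint, and H₀ is rejected when the p-value B⁻¹ Σ I{d̂\*⁽ᵇ⁾ ≤ d̂} falls
below α. A per-transition variant combined by the intersection-union
principle (`crm_iup_test()`) and a data-adaptive smallest rejecting
threshold (`minimal_delta()`) are included, along with the event-history
simulator and a seeded Monte Carlo driver for level/power studies.

## Worked example

Two groups of 300 subjects with three competing causes, daily rates
(0.001, 0.0011, 0.0004) vs (0.0008, 0.0017, 0.0009) — true distance
d = 0.0006/day — under exponential random censoring:

```r
library(crsim)
sc <- crm_scenario(1, n1 = 300, n2 = 300, censoring = censoring_random(0.002))
d  <- generate_scenario_dataset(sc, seed = 42)
tst <- crm_similarity_test(d, rep("exponential", 3), delta = 0.0015,
                           B = 250, censoring = censoring_random(), seed = 1)
tst
#>     Similarity test for parametric competing risks models
#>
#> families: exponential, exponential, exponential;  n = (300, 300);  window [0, 90] days
#> d_hat = 0.000627726, delta = 0.0015, bootstrap B = 250 (constrained null fit)
#> p-value = 0, alpha = 0.05, q_alpha = 0.00108664
#> => similarity established (null of relevant difference rejected)
```

The observed statistic d̂ ≈ 0.00063 is the largest fitted rate difference
(attained by transition 3 here); every bootstrap replicate generated under
the null boundary d = 0.0015 exceeded it, so the p-value is 0 at the
resolution 1/B and the groups are declared similar at Δ = 0.0015. The
smallest threshold at which similarity can be claimed (sequential
rejection, shared bootstrap seeds across the grid):

```r
minimal_delta(d, rep("exponential", 3), delta_grid = seq(5e-4, 5e-3, 5e-4),
              B = 250, censoring = censoring_random(), seed = 1)
#> observed d_hat = 0.000627726
#> smallest rejecting threshold: delta_hat = 0.001 (alpha = 0.05)
#>   delta p_value reject
#>  0.0005   0.468  FALSE
#>  0.0010   0.004   TRUE
#>  0.0015   0.000   TRUE
#>  ...
```

A command-line wrapper covering `simulate`, `test`, `minimal-delta` and
`study` ships at `inst/cli/crsim` (see `?crm_cli`).

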