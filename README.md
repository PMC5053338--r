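# pathdc — decision analysis of pathway impact hierarchies

Pathway-level analyses of time-course or multi-treatment transcriptome
experiments usually rank pathways one at a time, even though pathways share
genes and regulate one another. `pathdc` scores the members of a three-level
pathway hierarchy (KEGG-style category → subcategory → secondary pathway)
with a **decision coefficient** that folds the dependence structure among
sibling pathways into each pathway's score.

For one parent node with impact values *y* and child impact values
*x₁ … x_q* observed over *n* contrasts, the package fits the standardized
path-analysis model

&nbsp;&nbsp;&nbsp;&nbsp;**R**ₓ **b**\* = **R**ₓᵧ,

where **R**ₓ is the Pearson correlation matrix of the children and **R**ₓᵧ
their correlation vector with the parent. The coefficient of determination
decomposes as

&nbsp;&nbsp;&nbsp;&nbsp;R² = Σⱼ (bⱼ\*)² + Σⱼ<ₜ 2 bⱼ\* r_jt b_t\*,

a direct and an indirect part, and the decision coefficient of child *j* is

&nbsp;&nbsp;&nbsp;&nbsp;DC_j = (bⱼ\*)² + 2 Σ_{t≠j} bⱼ\* r_jt b_t\*,

its own direct determination factor plus the indirect determination
contributed by every correlated sibling. Unlike the total effect r_jy, the
decision coefficient also accounts for the regulation child *j* exerts back
on its siblings (retro-regulation). Its sign estimates the impact direction
(positive = activated, negative = inhibited), its magnitude the
decision-making ability. Significance is tested against the t-based cutoff

&nbsp;&nbsp;&nbsp;&nbsp;DC_cut(j) = 2 t_α(n−q−1) · |r_jy − bⱼ\*| · √(c_jj (1−R²)/(n−q−1)),

with c_jj the j-th diagonal element of **R**ₓ⁻¹, and normalized absolute
coefficients (decision percentages, summing to 100 per parent) annotate the
edges of a decision tree exported as Graphviz DOT or JSON.

The package covers the full workflow: TSV readers/writers for hierarchies,
impact matrices and differential-expression (DEG) tables; the missing-data
rules (rows with ≥ 3 missing contrasts dropped, sparser gaps filled with the
row mean); impact scoring from gene-level results
(proportion of DEG × mean |log2FC| × mean −log₁₀ p, with direction =
impact(up) − impact(down)); method-comparison metrics (direction concordance
and top-*a* overlap); and a synthetic-data generator for validation.

## Worked example

The package ships a reconstruction of the published four-child
demonstration model (printed path coefficients, child–parent correlations,
and the child correlation matrix recovered from the printed cross-products):

```r
library(pathdc)
fx <- table2_fixture()
da <- decision_analysis(fx$model)
da$report[, c("child_id", "b_star", "direct_factor", "indirect_factor",
              "dc", "direction", "decision_percentage")]
#>    child_id b_star direct_factor indirect_factor      dc direction decision_percentage
#> x1       x1  0.383        0.1467        0.000552  0.1472 activated               1.066
#> x2       x2 -1.097        1.2034       -0.530875  0.6725 activated               4.868
#> x3       x3 -2.593        6.7236      -10.420634 -3.6970 inhibited              26.762
#> x4       x4  2.471        6.1058      -15.403541 -9.2977 inhibited              67.304
```

x₃ and x₄ have large *positive* direct determination but end up *inhibited*:
the indirect determination from their strongly correlated siblings is
negative and dominates — exactly the kind of call a one-pathway-at-a-time
ranking cannot make. With the default fixed threshold |DC| ≥ 0.4, the most
impacted pathways are x₂, x₃ and x₄, and x₄ alone carries 67.3% of the
parent's decision percentage.

The determination-coefficient split, on a simulated parent with positively
coupled children:

```r
cfg <- simulation_config(q = 4, b_true = rep(0.344, 4), n = 12, seed = 7)
d <- simulate_dataset(cfg)
m <- fit_path_model(d[1:4, ], d["y", ], parent_id = "metabolism")
coefficient_of_determination(m)
#> R^2 = 0.9722; direct CD = 0.381 (39.2%); indirect CD = 0.591 (60.8%)
```

Here the indirect share exceeds the direct share: most of what the children
explain about the parent flows through their mutual correlations. And
parameter recovery under the generator's own assumptions:

```r
cfg <- simulation_config(q = 4, n = 5000, noise_sd = 0.1, seed = 1)
d <- simulate_dataset(cfg)
m <- fit_path_model(d[1:4, ], d["y", ])
max(abs(m$b_star - standardized_truth(cfg)))
#> [1] 0.0168
```

## Limitations

- The hierarchy is fixed at three single-parent levels; GO-style DAGs are
  out of scope.
- The t-based cutoff is anti-conservative in small samples (see the methods
  vignette); the fixed |DC| ≥ 0.4 threshold is the more robust screen.
- A parent needs at least 3 contrasts, at least 2 children, and
  n − q − 1 ≥ 1 for cutoffs; near-singular child correlation matrices are
  handled by pseudo-inverse with a warning (or an error in strict mode).
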