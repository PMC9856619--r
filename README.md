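# bcrlmap

Unsupervised risk stratification of breast cancer-related lymphedema
(BCRL) from mixed-type clinical variables.

BCRL — chronic arm swelling after breast-cancer treatment — affects
roughly a fifth to a quarter of women who undergo axillary dissection,
and no single clinical variable identifies who is at risk. `bcrlmap` is
for biostatisticians and clinical data scientists who want to stratify
such patients *without* fitting an outcome model: patients are embedded
into a two-dimensional **prognostic map** from their clinical profile
alone, the map is clustered, and BCRL prevalence is compared between
clusters afterwards.

## Method

Given a cohort of patients with 23 clinical variables (9
ordinal/categorical, continuous AGE and BMI binned to ten ordinal
levels, and 12 binary) plus a binary BCRL outcome:

1. **Dual embedding.** The ordinal block (11 variables, Canberra
   distance, 44 neighbours) and the binary block (12 variables,
   correlation distance `1 − r`, 38 neighbours) are each turned into a
   fuzzy k-nearest-neighbour graph with adaptive kernels calibrated so
   every point's memberships sum to log₂k, symmetrised by
   `a + b − ab`.
2. **Fusion by intersection.** The two graphs are combined by the
   fuzzy-set product over the union of edge sets (absent edges floored
   at ε of the partner weight, memberships renormalised per node), and
   the fused graph is laid out in 2-D by stochastic-gradient
   minimisation of the fuzzy cross-entropy against
   `q(r) = 1/(1 + a r^{2b})`.
3. **Gated clustering and grading.** Gaussian mixtures with
   k ∈ {2, 3, 4} (EM from k-means) are scored by silhouette
   `mean((b − a)/max(a, b))`; only clusterings with silhouette ≥ 0.6
   are retained and the best survivor is graded into an ordinal risk
   scale by ascending BCRL prevalence. Low-risk clusters can be merged
   into an "others" group.
4. **Risk statistics.** The graded clustering is characterised by χ²
   and Cramér's V, the Fisher–Freeman–Halton exact test (full
   enumeration), the Cochran–Armitage trend test, joint/conditional
   probability tables, prevalence ratios and excess odds, per-variable
   Mann–Whitney comparisons, modal values, absolute risk differences
   `|risk_B − risk_O|` among the exposed, and per-cluster Fisher/χ²
   association tests.
5. **Label reproduction.** A classifier panel (logistic regression,
   LDA, naive Bayes, random forest, extra trees, AdaBoost, and a
   chance-level dummy) is evaluated by repeated stratified
   cross-validation on balanced accuracy to confirm the cluster labels
   are a learnable function of the 23 variables.

Because the underlying two-hospital dataset is not public, the package
includes a calibrated synthetic cohort generator (`simulate_cohort()`)
with a planted three-stratum structure whose expected outcome-by-stratum
table reproduces the published patient distribution (strata 45/156/93,
BCRL rates 4/45, 50/156, 16/93, overall prevalence 23.8%).

## Worked example

```r
library(bcrlmap)

cohort <- simulate_cohort(cohort_sim_config(seed = 42))
run <- run_bcrl_pipeline(cohort, pipeline_config(cv_repeats = 2))

glance(run$map)
#> # A tibble: 1 × 5
#>       n     k silhouette accepted graded
#>   <int> <int>      <dbl> <lgl>    <lgl>
#> 1   294     3      0.708 TRUE     TRUE

tidy(run$map)
#> # A tibble: 3 × 5
#>   cluster  size events prevalence risk_rank
#>     <int> <int>  <int>      <dbl>     <int>
#> 1       2    39      1     0.0256         1
#> 2       1    83     11     0.133          2
#> 3       3   172     48     0.279          3
```

The gate accepted a three-cluster map (silhouette 0.708); the graded
clusters span a tenfold prevalence range (2.6% → 27.9%), so cluster 3
reads as the high-risk group. The statistics battery quantifies the
association between cluster membership and BCRL:

```r
run$report$three_cluster$chi_square
#> # A tibble: 1 × 4
#>   statistic    df  p_value method
#>       <dbl> <dbl>    <dbl> <chr>
#> 1      16.2     2 0.000301 chi-square

run$report$two_cluster$prevalence
#> # A tibble: 1 × 6
#>   prevalence_1 prevalence_2 prevalence_ratio odds_1 odds_2 excess_odds
#>          <dbl>        <dbl>            <dbl>  <dbl>  <dbl>       <dbl>
#> 1       0.0984        0.279             2.84  0.109  0.387       0.278
```

After merging the two lower-risk clusters, the high-risk group has 2.8
times the prevalence of the rest and a 28-point excess in the
positive:negative ratio. Finally, the labels are almost perfectly
recoverable from the variables:

```r
head(tidy(run$cv_three), 3)
#> # A tibble: 3 × 4
#>   classifier mean_ba_pct sd_ba_pct n_folds
#>   <chr>            <dbl>     <dbl>   <int>
#> 1 lda               99.4     0.850      10
#> 2 et                99.0     1.93       10
#> 3 bayes             98.7     1.39       10
```

`autoplot(run$map)` draws the map (clusters as colours, BCRL as
crosses); `run_bcrl_pipeline(..., out_dir = "results")` writes the map
CSV, figure, risk-report JSON, CV JSON and a run log. A thin CLI over
the same functions ships in `inst/cli/bcrlmap.R` (subcommands
`simulate`, `run-all`, `characterize`, `classify`, `plot`).

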