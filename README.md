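# telofuse

Which telomeres fuse when *Drosophila* telomere capping fails?

In metaphases of telomere-capping mutants, chromosome ends join into
dicentric/multicentric chains and ring chromosomes. The *pattern* of those
fusions is informative: most capping mutants under-involve the telomeres
embedded in constitutive heterochromatin (YL, YS, XR, 4L), while peo-type
mutants over-involve exactly those and form ring Y chromosomes far more
often than chance. `telofuse` is a small R package for cytogeneticists and
modellers who want to test an observed fused-telomere count table against
the random-involvement null, or to simulate such data under a controlled
heterochromatin bias.

## The model in brief

A diploid cell has 16 telomere slots (sister chromatids collapsed),
reported in five categories: A (2L, 2R, 3L, 3R), XL, XR, 4th (4L + 4R,
indistinguishable cytologically) and Y (YL + YS). Under random involvement
a fusion joins a uniform unordered pair of distinct telomeres, so the
expected fraction of fused telomeres (FTs) in category *c* is
*m<sub>c</sub>* / 16:

* males: A 50%, XL 6.25%, XR 6.25%, 4th 25%, Y 12.5%
* females: A 50%, XL 12.5%, XR 12.5%, 4th 25%

and the probability that a fusing Y telomere closes a ring Y is 1/15
(1/6 given a heterochromatic partner). The simulator generalises the null
with a fusigenicity weight *w* on heterochromatin-class telomeres (pair
probability ∝ *w<sub>i</sub>w<sub>j</sub>*, sampled without replacement;
*w* = 1 is the null), and the inference stage provides the chi-square
goodness of fit, the Eu/Het (A + XL vs XR + 4th + Y) aggregation, the exact
binomial ring-excess test, and maximum-likelihood estimation of *w* with
bootstrap confidence intervals.

## Worked example

```r
library(telofuse)

kar <- build_karyotype("male")
expectation_table(kar)
#>   category member_count expected_freq expected_pct
#> 1        A            8        0.5000        50.00
#> 2       XL            1        0.0625         6.25
#> 3       XR            1        0.0625         6.25
#> 4      4th            4        0.2500        25.00
#> 5        Y            2        0.1250        12.50

# simulate a peo-like experiment: 5-fold heterochromatin bias, 250 cells
ct <- simulate_experiment(kar, bias_model(het_weight = 5), n_cells = 250,
  seed = 1)
ct
#> <count_table> 250 cells, 249 fusions (STA 27 / DTA 222), Y FTs 124 (ring 10)
#>   category ft_count
#> 1        A      136
#> 2       XL       10
#> 3       XR       68
#> 4   Fourth      160
#> 5        Y      124

res <- analyze_count_table(ct, kar, n_boot = 500, seed = 1)
res$gof
#> Chi-square goodness of fit: X2 = 180.7, df = 4, p = 5.32e-38
res$eu_het
#>  Eu Het
#> 146 352
res$ring
#> Ring-Y excess test: 10/124 rings (0.0806 observed vs 0.0667 expected), exact binomial p = 0.3136
res$bias
#> Heterochromatin fusigenicity weight: w_hat = 5.404 (95% CI 4.16-6.982)
#>   method = generative, n_FT = 498, bootstrap = 500
```

Reading it: 498 FTs distribute far from the null (chi-square p ≈ 1e-37),
the heterochromatic group holds 352/498 ≈ 71% of FTs against the 43.75%
null expectation, the ring-Y fraction (0.081) is not significantly above
its 1/15 null here, and the recovered bias ŵ ≈ 5.4 brackets the true
simulated *w* = 5.

The same pipeline from the shell:

```sh
Rscript exec/telofuse expectations --sex male
Rscript exec/telofuse simulate --sex male --het-weight 5 --cells 250 --seed 1 --out peo_like.tsv
Rscript exec/telofuse analyze --sex male --out report.tsv peo_like.tsv
```

Count tables are plain tab-separated text (`category` / `ft_count` body
plus a `#`-stanza of cell, fusion, STA/DTA and Y tallies); small synthetic
examples generated by `make_fixtures()` ship under `inst/extdata/` with
`.config` sidecars recording their generating parameters.

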