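---
title: "Telomere-fusion patterns: null model, simulator and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Telomere-fusion patterns: null model, simulator and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telofuse)
```

## The problem

When telomere capping fails in *Drosophila melanogaster*, chromosome ends
fuse. In mitotic metaphases these telomeric fusions (TFs) appear as
dicentric or multicentric chains of chromosomes and, when the two ends of a
single chromosome join, as ring chromosomes. Different capping mutants fuse
*different* telomeres: most mutants under-involve the telomeres embedded in
constitutive heterochromatin, while mutants of the peo type over-involve
exactly those, including a striking excess of ring Y chromosomes. Deciding
whether an observed fusion pattern deviates from chance therefore needs a
null model for *which* telomeres would fuse if every telomere were equally
fusigenic, plus statistics against that null. This package provides the
null model, a generative simulator for synthetic metaphase data, and the
inference stage.

## The karyotype and its reporting categories

A diploid cell is modelled at the unreplicated-chromosome level: 16
telomere slots for both sexes (sister chromatids are collapsed; this is the
only counting under which the canonical expected frequencies below come out
as the familiar rationals). Fused telomeres (FTs) are reported in five
categories: the major-autosome arms `A` (2L, 2R, 3L, 3R), `XL`, `XR`, the
fourth-chromosome telomeres `4th` (4L and 4R cannot be distinguished under
DAPI, so they are always reported in aggregate, and no 4L/4R asymmetry is
assumed anywhere by default), and `Y` (YL + YS). The euchromatic group is
`A + XL`; the heterochromatic group is `XR + 4th + Y`.

Independently of the reporting categories, each *arm* carries a
subtelomeric chromatin class: YL, YS, XR and 4L terminate in constitutive
heterochromatin, XL and the major autosome arms in TAS repeats, and 4R in a
chromatin type of its own. The heterochromatin *class* (not the reporting
group) is what the simulator's fusigenicity weight acts on. The marked-Y
variant (`build_karyotype("male", "marked_Y")`) models a Y whose YL end
carries an appended euchromatic fragment: same census, but YL leaves the
heterochromatin class.

## The random-involvement null

A fusion event joins an unordered pair of distinct telomeres chosen
uniformly among the $\binom{16}{2} = 120$ pairs. The marginal probability
that a fused telomere falls in category $c$ is then simply
$m_c / 16$, where $m_c$ is the category's slot count:

```{r null}
expectation_table(build_karyotype("male"))
expectation_table(build_karyotype("female"))
```

`enumerate_pair_space()` provides the same numbers by brute-force
enumeration and is used as an exact oracle in the test suite.

**Ring-Y expectation.** Conditioning is per fusing Y telomere: its partner
is uniform over the other 15 telomeres, exactly one of which is the other Y
arm, so the null ring fraction is $1/15$; restricted to heterochromatic
partners (the other Y arm, XR, four 4th telomeres) it is $1/6$. An
alternative conditioning on Y-involving *pairs* (the YL–YS pair is one of
29) gives $1/29$ and is exposed as
`ring_probability(..., method = "pair_space")`, but the per-telomere
convention is the package default and the `count_table` Y tallies follow
it: `y_fusions` counts fused Y telomeres and `y_rings` counts the fused Y
telomeres whose partner is the other arm of the same Y (two per ring
event), so `y_rings / y_fusions` converges to $1/15$ under the null.

## The simulator (synthetic-data generator)

`simulate_experiment()` emulates scored metaphase spreads:

* the number of fusion events per cell is Poisson with mean
  `events_per_cell_mean`, truncated at the 8 available slot pairs;
* events are drawn sequentially *without replacement*: a pair of free
  telomeres is chosen with probability proportional to $w_i w_j$, where
  $w_i = w$ (`het_weight`) for heterochromatin-class telomeres and 1
  otherwise, and both telomeres are then consumed. $w = 1$ recovers the
  null exactly (all telomeres are exchangeable, so depletion does not
  distort the marginal frequencies);
* each event is labelled DTA with probability `p_G1`, else STA;
* chains and rings are derived by treating chromosomes as nodes with two
  ports and events as edges (`derive_structures()`), reproducing the
  classical worked configurations — ring autosomes, the 4–YS·YL–XR
  tricentric, multicentric A–A–A–A "trains".

Defaults are the stated world of the weak-mutant regime: 250 cells per
genotype (the scoring effort reported for real genotypes), 1 event/cell
(weak mutants range from below 1 to above 5 TFs/cell; 1 keeps most cells
informative without saturating the complement), `p_G1 = 0.9` (a package
default reflecting the strong DTA excess reported for every fly TF mutant;
it is not a measured value), `het_weight = 1`. Two optional flags mimic
scoring conventions rather than biology: `allow_sister` adds
sister-chromatid self-fusions (2 FTs in one category, no interchromosomal
link), and `ha_dta_censoring` records every fusion between two
heterochromatic-group telomeres as a DTA, because sister chromatids cannot
be resolved in heterochromatin.

What the generator does *not* emulate: chromosome breakage, replication
timing, spatial (chromocenter-proximity) structure, cell-to-cell
heterogeneity in fusigenicity, or selection against aberrant cells. A green
simulator-based test therefore establishes internal consistency of model,
statistics and code — not that real cytology satisfies the model.

```{r sim}
kar <- build_karyotype("male")
ct <- simulate_experiment(kar, bias_model(het_weight = 5), n_cells = 250,
  seed = 1)
ct
```

## Inference

`chisq_gof()` compares per-category FT counts with expectations derived
from the sample's own total ($E_c = N f_c$, $df = k - 1$ because the null
frequencies are fixed by the karyotype, not estimated), and warns when any
expected count is below 5. `aggregate_eu_het()` collapses to the Eu/Het
split; `ring_excess_test()` is the exact upper-tail binomial test of
`y_rings` out of `y_fusions` against $1/15$ (or $1/6$). When several
genotypes are analysed together, `write_report()` adds Holm-adjusted
p-values next to the raw ones.

**A calibration caveat, on purpose.** The chi-square treats the $2N$ fused
telomeres as independent multinomial draws — this is the field's own
procedure and is implemented as such. Under the generative model it is
conservative: the two FTs of one fusion, and all FTs within one cell, are
drawn without replacement from 16 slots, which shrinks the count covariance
by a factor $\left(16 - 2\,\mathrm{E}[n^2]/\mathrm{E}[n]\right)/15 = 0.8$
at Poisson(1) events per cell. Measured on 2000 null-simulated datasets the
mean statistic is 3.22 against a nominal $df = 4$ and the type-I error at
$\alpha = 0.05$ is about 0.02. The package deliberately does not "correct"
the test (comparability with published practice matters more than exact
calibration, and the error is in the safe direction); the test suite's
calibration check documents this as a known failure rather than widening
the band.

## Estimating the fusigenicity weight

`estimate_bias()` fits $w$ by maximum likelihood, treating the category
counts as multinomial draws from model frequencies $q_c(w)$ — a composite
likelihood, since FTs are not strictly independent. Two models for
$q_c(w)$ are available:

* `method = "single_event"`: each fusion is an independent draw from the
  full pair space, $\Pr(i,j) \propto w_i w_j$. Closed form, adequate when
  fusions are rare.
* `method = "generative"` (default): the exact expected category
  frequencies of the simulator, computed by dynamic programming over the
  multiset of free telomeres with Poisson-weighted event ranks. This was
  made the default after measurement, not taste: at 1 event/cell the
  sequential depletion of the five heterochromatin-class telomeres lowers
  the realized heterochromatic FT fraction enough that the single-event fit
  is inconsistent (at true $w = 5$, 5000 cells, it converges to
  $\hat w \approx 4.24$ with a confidence interval of width $\approx 0.4$ —
  essentially zero coverage), while the generative fit recovers
  $w \in \{1, 2, 5\}$ with nominal-or-better coverage. The Poisson mean it
  needs defaults to the observed `n_TFs / n_cells`; tables without a cell
  count silently fall back to the single-event model.

Numerics: the likelihood is profiled on 201 log-spaced grid points on
$[10^{-6}, 10^{6}]$ (the upper end is the documented cap for degenerate
data, e.g. all counts heterochromatic) with 3-point parabolic refinement;
the grid of model frequencies is cached per karyotype/mean, making the
bootstrap cheap. Intervals are percentile bootstrap over resampled fused
telomeres (the event-level pair compositions are not part of the
observable; multinomial FT resampling slightly over-states the variance of
paired, depleted counts, so intervals err conservative). Estimates at
either grid edge are flagged `capped`.

```{r bias}
estimate_bias(ct, kar, events_per_cell_mean = 1, n_boot = 500, seed = 1)
```

## Design choices made where the design was open

* **Counting level.** Telomeres are counted at the chromosome level, two
  FTs per fusion; DTAs do not count double. Nothing else reproduces the
  printed expected frequencies.
* **Weighted set.** The fusigenicity weight acts on the heterochromatin
  *chromatin class* (YL, YS, XR, 4L), not on the Het reporting group; 4R
  keeps weight 1 unless the user overrides its class. Strong bias still
  drives the Het *group* fraction towards 1, because every
  heterochromatin-class telomere reports into the Het group.
* **Ring conditioning.** Per fusing telomere (see above); the pair-space
  alternative is a flag, never a silent default.
* **Tie-breaking and canonical form.** Chains are listed from the end
  giving the lexicographically smaller copy sequence; rings start at their
  smallest copy in the lexicographically smaller direction; structures are
  sorted by canonical key. Purely presentational, but it makes every
  topology test and report byte-reproducible.
* **RNG contract.** One root seed per simulated experiment, with draws
  consumed in a fixed documented order (event-count vector, batched
  one-event cells, multi-event cells, association labels). Identical
  arguments and seed give identical tables.
* **Degenerate inputs.** Zero Y fusions give a flagged, $p = 1$ ring test;
  all-one-group count tables give a capped, flagged $\hat w$; empty event
  lists are valid metaphases (eight singleton chains).

## Limitations

* The null and the simulator ignore nuclear architecture; a
  chromocenter-proximity mechanism would need a different null.
* The bias model has a single weight $w$; real mutants may differentiate
  YL from YS from XR from 4L. The category observable cannot resolve all
  of that anyway (YL vs YS in particular).
* Observed genotype-level TF frequencies from real cytology are inputs,
  not things this package can predict; only pattern-vs-null claims are in
  scope.
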