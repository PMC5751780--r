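# MultiDCoX

Multi-factor analysis of differential co-expression for gene expression
studies.

## What problem this solves

A gene set is *differentially co-expressed* (DCX) when the degree to which
its members move together — not their average level — changes between
biological conditions. In real cohorts every sample carries several
co-factors at once (genotype markers, mutation status, tumour grade,
treatment), and these factors are usually correlated with each other.
Single-factor differential co-expression tools cannot say *which* factor
drives a co-expression change or in which direction. MultiDCoX is an
untargeted, set-scoring method for exactly that question: it discovers DCX
gene sets de novo and attributes each set's co-expression to individual
factors with signed, gated calls.

It is aimed at analysts of bulk expression cohorts (microarray or
RNA-seq after log transformation and normalisation) with per-sample
clinical/genetic annotation, and at methods researchers who want a
seedable simulation benchmark for multi-factor DCX.

## The model

For gene set $I$ and samples $S_m, S_n$ sharing a co-factor vector
($B_m = B_n$, a *stratum*), co-expression between the two samples is
summarised by the squared mean expression change

$$A_{mn}(I) = \Big(\tfrac{1}{|I|}\sum_{i\in I}(E_{im}-E_{in})\Big)^2,$$

large when the set shifts coherently, near zero otherwise. Over all
within-stratum pairs, $A(I)$ is regressed on the factor vectors,

$$A(I) \sim \beta_0 + B\,F(I),$$

and the coefficient vector $F(I)$ is the set's differential co-expression
profile: $F_i > 0$ means co-expression intensifies at the high level of
factor $i$. A greedy search (seed gene pairs → coefficient-optimising
expansion → centroid-based augmentation → leave-one-out filtering) finds
the sets; effect-size thresholds from the pooled coefficient distribution
plus a label-permutation criterion gate which factors are reported as
influential. See the methods vignette
(`vignettes/multidcox-methods.Rmd`) for the full account.

## Worked example

Simulate the benchmark design — 12 strata from two binary factors (B1,
B2) and one 3-level ordinal factor (B3), with a 20-gene set co-expressed
only where B1 = −1, a 20-gene set co-expressed where B1 = +1 ∧ B2 = +1,
and a 20-gene always-co-expressed control — then run the full pipeline:

```r
library(MultiDCoX)

sim <- simulateDCX(nGenes = 1500, samplesPerStratum = 5, sigma = 0.2, seed = 7)
res <- runMultiDCoX(sim$dataset, dcoxConfig(seed = 7))
res
#> DCoxResults: 2 candidate sets, 2 reported after gating
#> CT = 0.853

for (s in dcxSets(res)) show(s)
#> DCXGeneSet of 20 genes; profile: B1=1 B2=1 B3=0
#> DCXGeneSet of 20 genes; profile: B1=-1 B2=0 B3=0

head(gatingTable(res), 6)
#>   set factor coefficient  p.value effectPass permFraction  h
#> 1   1     B1      1.8469 1.67e-05       TRUE        0.000  1
#> 2   1     B2      1.8469 1.67e-05       TRUE        0.000  1
#> 3   1     B3     -0.0554 9.13e-01       TRUE        0.108  0
#> 4   2     B1     -1.0429 5.87e-08       TRUE        0.000 -1
#> 5   2     B2     -0.3193 7.84e-02       TRUE        0.098  0
#> 6   2     B3     -0.4457 4.53e-02       TRUE        0.107  0
```

Both planted sets are recovered exactly, with the planted signed
profiles: the first set's co-expression rises with B1 and B2 (both
coefficients 1.85, beaten by 0% of label permutations), the second's
rises where B1 is low (coefficient −1.04); chance tilts of the inactive
factors (e.g. B3 on set 1) are zeroed by the permutation criterion
(≥ 1% of permutations beat them), and the always-co-expressed control
loads on the intercept and is never reported. Scoring against the planted
truth:

```r
sc <- scoreResult(dcxSets(res), sim$truth)
sc$jaccard; sc$fnr; sc$fdr
#> set1 set2  -> 1 1      (Jaccard with truth)
#> set1 set2  -> 0 0      (false-negative rate)
#> [1] 0                  (false-discovery rate)
```

On your own data: `readExpression()` + `readFactorTable()` +
`DCoxDataSet()`, then `runMultiDCoX()`; or from a shell,

```sh
Rscript inst/cli/multidcox.R run --expr expr.tsv --factors factors.tsv \
    --out results/ --config cfg.yaml --seed 1
```

(subcommands `run`, `simulate`, `benchmark`; all tunables and their
defaults are documented in `?dcoxConfig`).

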