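# mdgsea

Multidimensional gene-set enrichment analysis via logistic membership
models.

## What it does

Classical gene-set analysis ranks genes by a single statistic and asks
which functional modules (GO terms, KEGG pathways) concentrate at one
end of that ranking.  Many genomic studies, however, measure *two*
things per gene — differential expression and splicing, expression in
two diseases, SNP association and copy number — and the interesting
biology often lives in how a module behaves with respect to **both**
measurements jointly.

`mdgsea` models the probability that a gene belongs to a module *F* as a
logistic function of its ranking statistics.  For two statistics
X and Y:

    logit P(g in F) = eta0 + alpha*X + beta*Y + gamma*X*Y

`alpha` and `beta` are main effects, `gamma` the interaction; all are
log odds ratios of membership, tested by Wald statistics and corrected
per coefficient family with Benjamini–Hochberg across all analysed sets.
This is a *competitive, gene-sampling* test: a set is compared against
its complement in the same gene universe.

When `gamma != 0` the fitted log-odds surface is a saddle (hyperbolic
paraboloid) with saddle point `(-beta/gamma, -alpha/gamma)`, and the
set's genes concentrate in the quadrant opposite it; when only `gamma`
is significant the set is *bimodal* — split between two opposite
quadrants (1&3 for positive, 2&4 for negative interaction), a pattern no
univariate analysis can see.  Each analysed set is classified into a
15-label taxonomy (`q1i`…`q4i`, `b13`, `b24`, `q1f`…`q4f`, `xh`, `xl`,
`yh`, `yl`, `NS`) from the effective signs of its three coefficients.

The package also ships a fully seeded simulation harness (planted
patterns, intra-set correlation, type-I-error and power reports) so
every statistical claim can be checked without any external dataset.

## Worked example

Plant three bimodal sets (members split between the corners
(+1, +1) and (−1, −1)) in a universe of 2,000 genes and analyse them:

```r
library(mdgsea)

spec <- simulation_spec(n_genes = 2000, n_sets = 3, set_size = 40,
                        pattern = "b13", effect = 1, seed = 9)
d   <- simulate_dataset(spec)
res <- run_md_gsa(d$ranking, d$collection)
res[, c("set_id", "size", "lor_X", "lor_Y", "lor_I", "padj_I", "pattern")]
#>   set_id size  lor_X   lor_Y lor_I   padj_I pattern
#> 1 set001   40  0.040 -0.0339 0.391 7.61e-04     b13
#> 2 set002   40 -0.126  0.1900 0.516 1.84e-06     b13
#> 3 set003   40 -0.162  0.0976 0.611 8.40e-09     b13
```

Every planted set shows a significant positive interaction
(`lor_I` ≈ 0.4–0.6 log odds per unit X·Y, adjusted p < 0.001) with null
main effects — the signature of a `b13` bimodal module.  Its saddle
point sits near the origin, as it must when the main effects vanish:

```r
fit <- fit_bivariate(d$ranking,
                     membership_vector(d$collection, "set001",
                                       rownames(d$ranking)))
saddle_point(fit)
#> saddle point at ( 0.08663108 , -0.1022456 )
```

Real data enter through `read_ranking()` (per-gene TSV; one or two
statistic columns; `align_rankings()` merges two one-dimensional
rankings; `aggregate_subunits()` collapses exon-level values to
gene-level medians) and `read_gmt()` / `read_annotation_pairs()` for the
gene sets; `write_results(res, "results.tsv")` emits the table above as
deterministic TSV, and `plot_set()` draws a gene cloud with
confidence ellipses for universe and set.

A thin CLI wraps the same functions:

```sh
inst/scripts/mdgsea md --ranking xy.tsv --sets sets.gmt --out res.tsv
inst/scripts/mdgsea simulate --preset b13 --effect 1 --reps 200 --seed 1 --out report.tsv
```

See `vignettes/mdgsea-methods.Rmd` for the model, the pattern taxonomy,
all tunable parameters and the harness's design.

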