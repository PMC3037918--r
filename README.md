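# markerscreen

An R package for rank-based candidate biomarker screening across
multi-study disease expression compendia, and for the contingency-table
and rank-test statistics used to validate a candidate on an
immunohistochemistry tissue-microarray (TMA) cohort. It was built around
the screen that nominated liver-type fatty acid binding protein
(FABP-1/L-FABP) as a pancreatic adenocarcinoma biomarker and the
staining-cohort analysis that validated it, generalized into reusable,
tested components with seeded synthetic generators standing in for the
private compendium and cohort.

## The statistics at its core

**Rank-normalized expression change.** Within each sample of $G$ genes,
expression values are replaced by normalized average ranks
$\tilde{x}_g = (r_g - 1)/(G - 1) \in [0, 1]$. For a gene in one dataset,

$$\Delta_g = \overline{\tilde{x}_g}^{\,\text{disease}} - \overline{\tilde{x}_g}^{\,\text{normal}} \in [-1, +1],$$

so $\Delta = +1$ iff the gene moves from the bottom of every normal
sample's transcriptome to the top of every disease sample's. Per-dataset
values are aggregated across studies by a sample-size-weighted mean,
with unmeasured genes excluded rather than zero-imputed. Ranking makes
the statistic invariant to any monotone platform transformation, which
is what lets heterogeneous microarray studies be combined at all.

**The filter cascade.** Candidates are genes (1) selectively
upregulated — target $\Delta \ge$ 0.10 and comparator-disease
$\Delta \le 0$ wherever measured; (2) present in a disease-susceptibility
gene list; (3) present in a biofluid (blood/urine proteome) list,
i.e. measurable in an accessible fluid; the top 10 survivors by target
$\Delta$ are reported.

**TMA validation.** Staining scores (0-3 scale) binarized at score
$\ge 1$; Fisher's exact test (two-sided, minimum-likelihood rule) and
Pearson chi-square on the case/control table; crude odds ratio with
Woolf interval $\exp(\ln OR \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$;
tie-corrected Kruskal–Wallis across diabetes strata; pairwise
tie-corrected Wilcoxon rank-sum tests (normal approximation, no
continuity correction) with raw and Bonferroni-adjusted p-values; and
crude logistic regression with separation detection.

## Worked example

Screen a seeded synthetic compendium with five planted disease genes:

```r
library(markerscreen)

planted <- sprintf("g%04d", 1:5)
cfg <- compendium_config(n_diseases = 1, n_datasets_per_disease = 4,
                         n_genes = 300, n_samples_per_group = 20,
                         planted_up_genes = list(target = planted),
                         effect_shift = 3, missing_gene_fraction = 0,
                         seed = 42)
datasets <- generate_compendium(cfg)
lists <- generate_gene_lists(cfg$universe, 0.2, 0.2,
                             overlap_with = planted, seed = 43)
run_screen(datasets, lists$susceptibility, lists$biofluid,
           screen_config("target"))
#> Candidate screen: target 'target', 0 comparator(s), 300 genes scored
#>   selectivity (delta >= 0.10, comparators <= 0.00): 5 genes
#>   + susceptibility list: 5; + biofluid list: 5; final candidates: 5
#> Final candidates (by target delta):
#>   gene target_delta
#>  g0002    0.3647157
#>  g0005    0.3431438
#>  g0001    0.3382943
#>  g0004    0.3241639
#>  g0003    0.2426839
```

All five planted genes — and nothing else — pass every stage; their
deltas (~0.24-0.36) are the rank headroom a 3-SD expression shift buys,
far above the 0.10 threshold, while the null background sits within
about ±0.05.

Analyse the deterministic staining-cohort fixture (the published TMA
tables, rebuilt core for core):

```r
tma_report(build_paper_cohort())
#> TMA staining report: PaC vs normal (n = 81, positivity = score >= 1)
#>
#> Binary staining (rows = group, cols = positive/negative):
#>           1  0
#>   normal  1 20
#>   PaC    18 42
#>   Fisher's exact test (two-sided), p = 0.0183
#>   Pearson chi-square: statistic = 5.519, df = 1, p = 0.01882
#>   Odds ratio 8.57 (95% CI 1.07-68.8)
#> ...
#> Diabetes-stratified analysis (13 unknown-DM cases excluded):
#>   Kruskal-Wallis rank test: statistic = 8.184, df = 2, p = 0.01671
#>   Kruskal-Wallis rank test: statistic = 8.139, df = 2, p = 0.01708
#>   Pairwise score rank-sum tests:
#>    group_a   group_b   p_raw p_bonferroni
#>     normal PaC_no_DM 0.07413        0.222
#>     normal    PaC_DM 0.00435        0.013
#>  PaC_no_DM    PaC_DM 0.08909        0.267
```

Reading the output: carcinoma cores stain positive far more often than
normal pancreas (18/60 vs 1/21; Fisher p ≈ 0.02, odds ratio 8.6 with
Woolf 95% CI from 1.07), staining differs across the three diabetes
strata (Kruskal–Wallis p ≈ 0.02 on both the binary and score scales),
and the diabetic-carcinoma stratum drives the signal (pairwise rank-sum
p ≈ 0.004 vs normals).

A thin command-line wrapper over the same functions ships at
`inst/cli/markerscreen.R` with subcommands `simulate`, `screen`, `tma`
and `run-all`; `run_end_to_end()` writes every report plus a JSON
manifest from which any run can be regenerated.

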