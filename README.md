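# ratarget

Network-based prioritization of rheumatoid arthritis (RA) risk genes as
candidate therapeutic targets.

RA is a chronic autoimmune disease for which dozens of genetic risk
variants are known, but turning a list of GWAS hits into a ranked list of
druggable proteins requires integrating heterogeneous evidence: how often
a protein is reported in the curated literature, how central it sits in
the protein–protein interaction (PPI) network around the risk proteins,
how strongly it is expressed in patient-relevant tissue, and how densely
it is linked to disease entities in a multi-layer knowledge graph.
`ratarget` implements that integration as a tested, reusable pipeline for
computational biologists working on disease-gene prioritization.

## The scoring model

Each protein *p* receives four component scores, each scaled to [0, 1]:

* **Disease mapping** — the supporting-study fraction
  *S<sub>d</sub>* = |D<sub>p</sub>| / |D|, where |D<sub>p</sub>| counts
  curated studies reporting the protein's RA association and |D| the total
  studies in the catalog.
* **Molecular interaction** —
  *S<sub>m</sub>* = α·C<sub>d</sub> + β·C<sub>b</sub> + γ·C<sub>c</sub>,
  a mixture of degree, betweenness and closeness centrality in the
  confidence-filtered PPI network (channels summed and min–max-normalized;
  edges retained at combined confidence ≥ 0.9), min–max-scaled across
  proteins.
* **Biomedical knowledge** — *S<sub>b</sub>*, min–max-scaled expression in
  RA-relevant samples.
* **Knowledge graph** — *S<sub>k</sub>* = Σ<sub>i</sub> w<sub>i</sub>R<sub>i</sub>,
  the sum of importance-weighted relationship strengths between the
  protein and disease-relevant entities in the multi-layer knowledge
  graph, min–max-scaled across proteins.

The integrated inference score is the convex combination

> *I<sub>p</sub>* = w<sub>d</sub>·S<sub>d</sub> + w<sub>m</sub>·S<sub>m</sub> + w<sub>b</sub>·S<sub>b</sub> + w<sub>k</sub>·S<sub>k</sub>,  with w = (0.3, 0.3, 0.2, 0.2) by default,

and proteins with *I<sub>p</sub>* **strictly above 0.85** are classified
as high-confidence targets. Upstream, the risk-variant catalog is
deduplicated by rsID and filtered to GWAS with sample sizes ≥ 500,
Asian/European (or unrecorded) populations, and odds ratios strictly
above 0.7; gene-set over-representation uses the one-sided Fisher exact
test with Benjamini–Hochberg FDR control and fold enrichment
(k/n)/(K/N).

A synthetic-data generator (`simulation_config()` / `generate_bundle()`)
emits complete multi-layer input bundles with *planted* true targets that
carry elevated evidence in every layer, so the whole pipeline can be
benchmarked for recovery (recall@k, rank-sum) without any database
downloads.

## Worked example

Curate the packaged top-30 risk-variant table and score a synthetic
benchmark:

```r
library(ratarget)

catalog <- system.file("extdata", "table1_risk_variants.tsv",
                       package = "ratarget") |>
  read_variant_table() |>
  deduplicate_variants() |>
  filter_variants()
catalog
#> <curated_catalog> 30 variants, 30 genes
#> filter log:
#>   - deduplicate_rsid: removed 0
#>   - min_sample_size: removed 0
#>   - min_odds_ratio: removed 0
#>   - population: removed 0
```

All 30 published variants survive the curation filters (odds ratios run
0.86–1.81, all above the 0.7 cut; sample sizes and populations are
unrecorded in the table and therefore retained). Now a synthetic bundle
with 5 planted targets among 50 proteins:

```r
bundle <- generate_bundle(simulation_config(seed = 1))
ranked <- score_bundle(bundle)
tidy(ranked)
#> # A tibble: 50 × 8
#>   protein   s_d   s_m   s_b   s_k   i_p  rank classification
#> 1 P039     0.06 0.915 0.768 1     0.646     1 candidate
#> 2 P004     0.12 0.490 1     0.666 0.516     2 candidate
#> 3 P023     0.18 0.795 0.501 0.374 0.467     3 candidate
#> 4 P021     0.04 0.647 0.996 0.282 0.462     4 candidate
#> 5 P001     0.12 0.759 0.653 0.330 0.460     5 candidate
#> # ℹ 45 more rows

evaluate_recovery(ranked, bundle$truth, k = 5)
#> # A tibble: 1 × 4
#>       k recall_at_k rank_sum_w  rank_sum_p
#> 1     5           1        225 0.000000472
```

The five top-ranked proteins are exactly the five planted targets
(`bundle$truth`): recall@5 = 1, and the one-sided rank-sum test confirms
planted targets score far above the rest. (Synthetic scores land well
below the 0.85 high-confidence bar because min–max scaling pins each
component's best protein to 1 and different proteins top different
layers; the classification threshold is meant for the integrated
real-data evidence profile.)

`run_pipeline()` executes the same stages from files driven by a YAML
config and writes per-stage TSVs plus a JSON run report;
`validate_fixtures()` re-checks the packaged tables; `plot_enrichment()`,
`autoplot()` and `plot_score_components()` draw the standard panels.

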