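---
title: "Prioritizing rheumatoid arthritis therapeutic targets from multi-layer evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing rheumatoid arthritis therapeutic targets from multi-layer evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratarget)
```

## The problem and the model

Genetic studies of rheumatoid arthritis (RA) yield catalogs of risk
variants, but a variant list is not a target list. `ratarget` ranks
proteins by integrating four independent evidence layers into one
inference score per protein:

$$I_p = w_d S_d + w_m S_m + w_b S_b + w_k S_k$$

with default weights $w = (0.3, 0.3, 0.2, 0.2)$. The components are:

* $S_d = |D_p| / |D|$, the fraction of curated studies supporting the
  protein's RA association. $|D|$ is the total number of distinct studies
  in the curated catalog (the union of PubMed IDs), not the number of
  variant rows — one study typically reports several variants.
* $S_m = \alpha C_d + \beta C_b + \gamma C_c$: a mixture of degree,
  betweenness and closeness centrality in the high-confidence PPI
  network, min–max-scaled across proteins. The scaling factors default to
  equal thirds — a symmetric prior over the three centrality notions,
  since no evidence privileges one of them; all three are exposed as
  parameters.
* $S_b$: min–max-scaled protein expression in RA-relevant samples. The
  expression context (tissue, cell type) is a labeled input column; when
  a protein appears in several contexts its values are averaged before
  scaling, so the score reflects an aggregate profile unless the caller
  pre-filters to one context.
* $S_k = \sum_i w_i R_i$: the sum over knowledge-graph edges linking the
  protein to a disease-relevant entity, of relationship strength $R_i \in
  [0,1]$ times an importance weight $w_i \ge 0$, min–max-scaled across
  proteins.

Because every component lies in $[0,1]$ and the weights form a simplex,
$I_p$ is a convex combination and is guaranteed to lie in $[0,1]$ and to
be monotone in each component — both properties are enforced by tests.
Proteins with $I_p$ **strictly** greater than the classification
threshold (default 0.85) are flagged `high_confidence`; a protein scoring
exactly the threshold is a `candidate`. The strictness matters in the
packaged published ranking, where several previously studied proteins sit
exactly at 0.85.

## Curation assumptions

`filter_variants()` retains variants with GWAS sample size $\ge 500$,
population in {Asian, European} and odds ratio strictly above 0.7, each
threshold a parameter. Two policies deserve comment:

* **The odds-ratio rule is applied literally.** An OR below 1 is
  protective, so "above 0.7" admits some protective alleles while
  excluding strong protective ones; we reproduce the stated numeric rule
  rather than reinterpreting it (e.g. as $|\log OR|$), and expose
  `min_or` so other policies can be expressed.
* **Missing metadata never disqualifies a row.** Published top-variant
  tables typically print neither sample size nor population, and many
  source articles omit odds ratios; rows lacking any of these fields are
  retained. This is required for internal consistency: the packaged
  30-variant table must survive the very filters that produced it.

Deduplication merges rows by rsID, unioning PubMed-ID sets and keeping
first-seen values elsewhere. Compound locus labels such as
`GTF2IRD1-NCF1` are kept verbatim as single catalog entries, matching how
they are printed in source tables.

## Enrichment

`enrich()` performs one-sided (over-representation) Fisher exact tests:
the right tail $P(X \ge k)$ of the hypergeometric distribution, computed
through `stats::phyper` and cross-checked in the test suite against
exhaustive enumeration of all $\binom{N}{n}$ draws for universes up to
$N = 12$. Depletion is never tested. Only terms overlapping the query
($k \ge 1$) enter the Benjamini–Hochberg correction, matching common
enrichment-tool behavior and keeping the number of tests well defined;
significance uses strict $q < 0.05$ by default. Fold enrichment is
$(k/n)/(K/N)$. The background universe is a required input — enrichment
p-values are meaningless without a stated universe, and no default (all
annotated genes vs. all protein-coding genes) is imposed.

## Network construction and centralities

Interaction tables are read in the STRING-export dialect; channels on the
0–999 integer scale are auto-detected (any value above 1) and divided by
1000. The confidence threshold (default $\ge 0.9$, inclusive, STRING's
"highest confidence" convention) applies to the native 0–1 combined
channel *before* summation and min–max normalization of channel sums;
the normalized sum is kept as a reporting weight. Applying the cut to the
normalized sum instead would make retention depend on the rest of the
file, which we judged unintended.

Nodes are labeled `risk` (in the curated gene set), `neighbor` (adjacent
to a risk node) or `other`. Centralities are normalized so all three lie
in $[0,1]$ network-wide:

* $C_d = \text{degree}/(N-1)$;
* $C_b$ = shortest-path betweenness with each unordered pair counted once
  and credit split equally among equal-length shortest paths, divided by
  $(N-1)(N-2)/2$;
* $C_c$ = within-component closeness $(n_c-1)/\sum d$ scaled by
  $(n_c-1)/(N-1)$ (the Wasserman–Faust correction), so closeness remains
  comparable across components of a disconnected network.

Isolated nodes and single-node networks score zero on all three.
Components are ordered by descending size, then by smallest member
identifier; per-risk-protein edge capping breaks confidence ties by
ascending partner identifier. These tie rules exist purely for
reproducible output. The whole centrality stack is verified against a
brute-force oracle (BFS distances plus explicit enumeration of every
shortest path) on systematic and random graphs of up to 8 nodes.

Functional grouping of disconnected components summarizes each component
by its significantly enriched term set and merges components whose term
sets have Jaccard similarity at or above a caller-chosen threshold,
single-linkage; a component with no significant terms stays a singleton
labeled `unassigned` and never merges (Jaccard with an empty set is
defined as 0).

## Knowledge graph

Layers are typed edge tables (gene/protein/disease/pathway/drug/kinase/
tissue/cell-type nodes; interacts/associated_with/phosphorylates/
upregulated_by/member_of/expressed_in/co_expressed relations).
Deduplication is per `(src, dst, relation, layer)`: the same relationship
asserted by two layers contributes once per layer, so $S_k$ counts
independent sources as additional evidence. Three policies were genuinely
open and are resolved as explicit configuration:

* *Which entities are "disease-relevant"* is a declared identifier set
  (`ra_entities`), not an inferred property — this keeps the evidence sum
  testable and the policy visible.
* *Importance weights* $w_i$ default to 1 per relation and are
  overridable per layer; no published weighting scheme exists for them.
* *Inferred links* (proposed for protein–disease pairs sharing at least
  `min_shared` neighbors, with strength = Jaccard of neighbor sets) carry
  importance 0 and are excluded from scoring until the analyst assigns a
  weight and accepts them. Automatic trust in inferred associations would
  let the inference feed back into the score that motivated it.

## Numerical choices

* **Degenerate min–max maps to 0, not NaN.** Whenever all values are
  equal (single edge, constant expression, all-zero evidence), the scaled
  scores are all 0. This keeps every downstream weighted sum defined; the
  alternative (0.5, or NA propagation) would either invent evidence or
  poison the integrated score.
* $S_d$ is already a ratio in $[0,1]$ and is **not** re-normalized by
  default, so a protein reported in every study scores exactly 1; a
  `renormalize` flag forces min–max scaling for callers who want all four
  components on the same relative scale.
* Ranking ties are broken by ascending protein identifier, making the
  ranking invariant to input order.
* Empty inputs are domain errors for `min_max()`, `compute_sb()` and
  `evaluate_recovery()` (empty truth set); impossible contingency tables
  ($k > \min(n, K)$, $K > N$) are domain errors for the enrichment
  primitives.

## The synthetic benchmark

`generate_bundle()` emulates every input the pipeline consumes — variant
catalog, interaction table, annotation map, knowledge-graph layers,
expression and evidence tables — with a planted truth subset of the risk
proteins carrying elevated evidence in each layer independently:
supporting-study counts Poisson(5) against Poisson(1), a
2-standard-deviation expression shift, Poisson(5) against Poisson(1)
disease-entity links, and probability 0.5 of an extra high-confidence
edge to each risk protein. Those values are the strong-effect benchmark
conditions; setting each target parameter equal to its null counterpart
yields a null configuration whose planted labels are indistinguishable,
under which recovery must sit at chance ($|truth|/n$). Effects are
injected independently per layer so any single component can be validated
in isolation by zeroing the others.

Values the benchmark conditions leave open were fixed once at realistic
levels: background interaction probability 0.05 (sparse PPI sampling),
edge-confidence noise SD 0.03 around a 0.95 mean (high-confidence STRING
exports cluster near the top of the scale), a 50-study catalog total, 20
disease entities and 5 pathways in the knowledge graph, and a 50-protein
/ 10-risk / 5-target default problem size — small enough that the full
recovery benchmark (20 strong-effect plus 50 null replicates) runs in
seconds on one CPU, which is the scale the test suite and the acceptance
script use.

What the generator does **not** emulate: scale-free degree
distributions, literature citation dynamics, correlated evidence across
layers, batch structure in expression, or incomplete/biased annotation.
Passing recovery tests therefore demonstrates that the scoring machinery
ranks genuinely enriched multi-layer evidence highly and is calibrated
under the null — not that the pipeline would achieve the same recall on
real databases, where evidence layers are correlated and noise is not
independent.

## Limitations

* The published component inputs (per-protein study counts, expression
  values, knowledge-graph weights) are not public, so the packaged
  published ranking is consumed as a fixture for classification and
  counting checks, not regenerated from raw evidence.
* Network statistics from dated database snapshots (specific component
  counts and sizes) cannot be reproduced without those snapshots and are
  treated as documentation.
* The inference weights are fixed priors, not learned; sensitivity to
  them can be explored through `scoring_weights()` but is not optimized.
* One-sided enrichment only; no ontology-graph propagation of annotation
  terms.
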