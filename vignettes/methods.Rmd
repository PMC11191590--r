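---
title: "Methods: screening plastic additives for carcinogenic potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening plastic additives for carcinogenic potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`plastitox` turns a screening workflow for plastic additives into a set of
composable, tested stages. This vignette is the package's account of the
science in each stage: the models and rules, the parameters that matter,
the design decisions taken where several readings were defensible, and the
limits of what the test suite demonstrates.

## The registry and its key

Everything is keyed on CAS registry numbers under a one-to-one assumption
between CAS number and substance. A CAS number `NNNNNNN-NN-N` carries a
checksum: the digits other than the last, read right to left, are weighted
1, 2, 3, … and summed; the sum modulo 10 must equal the final digit.
`normalize_cas()` enforces this and strips leading zeros from the first
segment so that keys compare canonically — silent duplicates from
zero-padded variants are a real failure mode in hand-curated chemical
tables. Records failing validation are never dropped silently: readers
quarantine them to a rejects table for audit.

Source reviews disagree about names and confidence. When several records
share a CAS, `merge_source_records()` keeps the highest confidence on the
ordinal scale unknown < low < medium < high (a source that supplies no
confidence ranks lowest), unions the usage annotations, takes the name of
the highest-confidence record with lexicographic tie-breaking, and retains
every other name as an alias. The merge is idempotent and order-invariant,
which the suite checks by permutation.

Product strings are grouped into interpretable categories by
positive/negative substring rules: a product matches a category iff it
contains a positive string and no negative string of that category
(case-insensitive, whitespace-squashed). The canonical example is
"tablecloth", which a "cloth" positive would sweep into clothing unless
"tablecloth" is listed as a negative. Matching is monotone in the positive
list, a property the suite tests on random rule sets.

## Classification harmonization

Two public sources are harmonized. IARC groups map to a three-way
partition: Groups 1/2A/2B are *carcinogens*; carcinogens plus Group 3 are
*classified* (their carcinogenic potential has been evaluated); chemicals
absent from IARC or present without a group are *unclassified*. The
"present but unassigned" state is kept as its own level — these chemicals
count inside database coverage but outside the classified set — and the
partition invariant (carcinogen ⇒ classified; the three states tile the
registry) is asserted on every registry.

IRIS sometimes lists one chemical with different descriptors per exposure
route; `resolve_iris_multiroute()` keeps the most severe descriptor under
the order carcinogen > likely > probable > possible > suggestive >
noncancer, so a chemical carcinogenic by any route is carcinogenic for the
analysis.

Cross-database consistency needs a correspondence rule that the source
material never states explicitly. The package's default — IARC 1/2A/2B
agree with *any* IRIS cancer descriptor, including "suggestive evidence";
IARC Group 3 agrees with "noncancer"; anything absent or unassigned on
either side is not comparable — is an explicit, overridable table
(`consistency_check(..., correspondence = )`), because whether suggestive
evidence counts as a cancer verdict is genuinely open. Coverage summaries
report counts and percentages over two explicit denominators (whole
registry, database-present subset); percentages are kept at full precision
and rounded half-up only for display, since half-even rounding would
disagree with conventionally printed registry percentages in edge cases.

## Interactions and ortholog remapping

Interaction records are one regulation event per row with direction `up`
or `down`. A gene may appear in both directions for one chemical — that is
biological reality across studies and both records are kept; directions
only collapse when the ORA input is formed. Records are deduplicated on
(cas, gene_id, direction): over-representation uses presence, not report
multiplicity.

Nonhuman gene IDs are remapped through a user-supplied ortholog table.
A nonhuman gene with several human orthologs expands to all of them
(direction preserved); one with no ortholog goes to an unmapped bucket,
excluded from enrichment with a warning. Remapping an already-human table
is a fixed point, and every input record is accounted for either in the
remapped output or the unmapped bucket — both are property-tested.

## Over-representation analysis

The ORA input for a chemical is the deduplicated union of its up- and
downregulated genes. Gene sets are parsed from standard GMT, intersected
with the background universe *first*, and then size-filtered to 10–2,000
effective members — the intersection-first order matters, since a large
set thinly represented in the background should be judged by its effective
size. The background defaults to whatever universe the caller supplies
(the reference human protein-coding selection of ~13,049 genes in the real
screen; the generator's universe in synthetic runs); input genes outside
the background are dropped with their count logged.

The test is the upper-tail hypergeometric probability
P(X ≥ overlap) for drawing the input from the background with the set as
successes, computed with `stats::phyper`; the suite checks it against an
exhaustive enumeration of every possible draw for backgrounds up to 15, to
1e-12. The effect size is the enrichment ratio ER = overlap/expect with
expect = input_size × set_size / background_size; ER is 0 when the
expectation is 0 and is scale-invariant (doubling all sizes leaves it
unchanged), both asserted. Benjamini–Hochberg adjustment is applied per
chemical across *all* collections pooled — one submission is one testing
family; per-collection adjustment is available by flag — and cross-checked
against an independent hand-rolled step-up implementation. The
significance gate is FDR ≤ 0.25. Sorting of results is deterministic
(FDR, then ER descending, then set_id), so permuting the collection
never changes the output.

The ER matrix has one row per chemical that produced at least one
significant result and one column per filtered set; non-significant cells
are zero. Whether non-significant ERs should enter the matrix is an open
modeling question — zero-filling is the default because an enrichment that
failed its own significance gate is evidence-free for clustering — and the
row rule (chemicals with results, rather than all ORA-eligible chemicals)
mirrors clustering only additives that actually produced enrichment
output.

## Clustering

The clustering stage reduces the ER matrix by PCA to the smallest number
of leading components reaching 95% cumulative explained variance, embeds
the scores with UMAP, and partitions with k-means, scanning a grid:
`n_neighbors` over 2–20, `min_dist` over {0, 0.1, 0.25, 0.5, 0.8, 0.99},
k over 3–10, and five seeds applied in lockstep to UMAP and k-means
(defaults {0..4}; the five values are a documented package choice). UMAP
is treated as a pluggable contract — fixed inputs and seed give an
identical embedding (single-threaded uwot) — not as a reimplementation
target. When PCA leaves fewer columns than the embedding dimensionality,
spectral initialization is undefined and the stage falls back to seeded
random initialization.

The quality gate is the mean silhouette, computed **in the embedding
space where k-means ran**: per point, (b − a)/max(a, b) with a the mean
intra-cluster distance and b the smallest mean distance to another
cluster, singletons scoring 0. The implementation is cross-checked
against `cluster::silhouette`. The grid is walked in a deterministic
order (n_neighbors, min_dist, seed, k, all ascending); a strictly higher
silhouette wins, ties prefer the smaller k and then the earlier grid
position; the best solution is accepted only if its silhouette reaches
0.70, otherwise the same solution is returned flagged as a
below-threshold failure report. Grid points infeasible for the matrix
size (too few rows for the neighborhood or for k) are skipped.

Cancer-keyword subsetting retains columns whose pathway *names* contain
any of "cancer", "carcin", "metasta", "tumor" as case-insensitive
substrings (the keywords are lowercase, the names typically title case,
so case-insensitivity is forced), then rows with at least one nonzero
retained cell.

## Cluster profiles and group overlap

Within each cluster, the differentially enriched cancer pathways are the
candidate (cancer-collection) columns whose **raw-ER** sample standard
deviation (n−1) across the cluster's additives exceeds a per-cluster
threshold; the thresholds used on the real data (10, 10, 20) are ER-scale
numbers, which is why the SD is taken on raw rather than standardized
ERs, over all of the cluster's additives. Additives enriching none of the
selected pathways are dropped, the submatrix is column-standardized
(constant columns become zero with a warning), and additives and pathways
are ordered by agglomerative hierarchical clustering
(Euclidean/complete, the common heatmap defaults, configurable). Pathway
cancer-relation categories are a user-supplied lookup validated for
coverage — they are manual curations the package will not invent.

Per cluster, *central* pathways are the 50 with the most enriching
additives (ties by set_id), *uniquely enriched* pathways are central
pathways absent from every other cluster's central list, and *highly
enriched* pathways have at least one ER ≥ 100 in the cluster.

Group comparisons count shared upregulated genes, shared downregulated
genes (a gene reported in both directions contributes to both), and
shared significant pathways per chemical pair; rankings of query
chemicals against a reference group aggregate by sum over the reference
(per-pair max by flag — the aggregation is not dictated by the source
protocol, and sum rewards consistent similarity across many carcinogens).
The pathway-union profile reports, per query chemical, the percentage of
the reference group's pathway union it enriches. Raw counts only: no
significance is attached to overlap sizes, deliberately.

## The synthetic generator

`simulate_config()` defaults encode the real screen's composition: 2,712
chemicals; IARC tallies 23/36/108/112/12 present with the remainder
absent; IRIS 9/11/22/3/2 cancer descriptors plus 122 noncancer of 169
present; 428/2,712 chemicals with interaction records; a 13,049-gene
universe; set sizes 10–2,000 and 10–500 genes per chemical, both
log-uniform (pathway and list sizes in practice are heavy-tailed toward
small); directions 0.5/0.5; 5% of records relabeled nonhuman with
ortholog multiplicity 1/2/3 at probability 0.80/0.15/0.05 (most
orthology calls are one-to-one; the occasional expansion exercises the
many-match rule). Surrogate nonhuman IDs live in a reserved range
(original + 10^8) so they can never collide with the human universe.

Planted structure: interacting chemicals are split evenly among the
planted clusters; each draws a fraction *f* of its genes from the union
of its cluster's signature sets (signatures are carved from disjoint
blocks of the universe) and the rest uniformly elsewhere. *f* = 0 is the
pure-noise null. Two scaled presets define the package's validation
conditions: `strong_signal_config()` — 3 clusters × 32 chemicals, *f* =
0.9, 45 disjoint sets of 20–60 genes, 40–120 genes per chemical, a
2,000-gene universe — and `null_config()`, the same geometry with 240
chemicals and *f* = 0. These sizes were chosen once as the smallest
configuration in which signature enrichment is overwhelming (planted ERs
≈ 10–25 at vanishing FDR) while a laptop-scale grid search stays
comfortable; the reduced validation grid is `n_neighbors` {5, 10, 15} ×
`min_dist` {0, 0.5} × seeds {0..4} × k 3–10.

What the generator does *not* emulate: correlated pathway membership
(real collections overlap heavily), report multiplicity and evidence
codes, dose or study covariates, and chemicals whose gene lists mix
several mechanisms. Passing the recovery tests therefore shows the
pipeline recovers planted block structure under realistic sizes and
noise — not that three clusters exist in any real dataset.

## Numerical choices and known limitations

* Rounding for display is half-up at the printed precision; all stored
  percentages are full precision.
* All randomness flows through explicit seeds (`withr::with_seed`
  internally); generator outputs are identical across runs with the same
  config.
* Sorting tie-breaks (set_id, CAS, grid position) make every ranking
  deterministic.
* The grid search maximizes silhouette over hundreds of configurations,
  which is a multiple-comparisons process: on some generator
  realizations it over-splits a planted cluster into tight embedding
  fragments whose silhouette edges out the true k by < 0.02, and on rare
  null realizations the best solution can brush the 0.70 floor. The
  acceptance floor filters most, not all, structureless inputs — a
  genuine property of the protocol worth knowing before interpreting an
  accepted k.
* UMAP embeddings are only approximately invariant to row order
  (approximate nearest neighbors and SGD scheduling), so row-permuted
  inputs reproduce the partition but not bit-identical scores.
* Silhouette is evaluated in the embedding, not the original ER space;
  an accepted solution certifies separation of the embedded
  representation.
* Under the *f* = 0 null, the realized per-chemical false-enrichment
  rate (any significant call) observed in the suite is ≈ 0.09–0.13,
  consistent with BH control at the 0.25 gate under near-independence.
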