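---
title: "Integrative candidate-gene prioritization for flavonoid-vascular nutrigenetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative candidate-gene prioritization for flavonoid-vascular nutrigenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavoprior)
```

## The problem

Dietary flavonoids improve vascular function in humans on average, but
responses vary substantially between individuals, and genetic polymorphism is
one of the least-studied drivers of that variability. A practical way to
choose genes worth genotyping in a nutrigenetic trial is to ask which genes
sit at the intersection of two independent lines of evidence:

1. **Response evidence** — genes whose expression changes in peripheral
   blood when people consume flavonoids (differentially expressed genes,
   DEGs, from intervention studies), together with the upstream regulators
   (URs) predicted to drive those changes; and
2. **Susceptibility evidence** — genes in which genome-wide association
   studies (GWAS) have found variants associated with vascular dysfunction
   (hypertension, atherosclerosis, arterial stiffness).

A gene that a flavonoid intervention modulates *and* that carries known
vascular-risk variants is a strong candidate for explaining why the same
intervention helps some people more than others. `flavoprior` implements
this integration as a reproducible, file-driven pipeline: no step requires a
live database query, so a run is fully determined by its inputs and
configuration.

## Pipeline and model

The pipeline stages, each exposed as ordinary R functions:

1. **GWAS curation** (`read_gwas_export()`, `filter_associations()`,
   `build_trait_gene_set()`, `union_trait_sets()`). Association exports are
   filtered by case-insensitive substring rules on the trait text. The trait
   refinements are verbal in the source evidence (e.g. excluding pulmonary
   arterial hypertension, preeclampsia, treatment-resistant hypertension),
   so substring rules on editable phrase files are the faithful mechanism.
   Mapped-gene cells are split on `" - "`, `";"`, `","`, `" x "` (SNP-by-SNP
   interaction rows contribute genes from both sides) and `"(also GENE)"`
   annotations; intergenic placeholders contribute nothing.
2. **Cross-study recurrence** (`venn_partition()`, `genes_in_at_least()`).
   Study DEG lists are treated as sets; every union gene is assigned to
   exactly one membership region, and region sizes must sum to the union
   (asserted on every call).
3. **DEG x GWAS integration** (`candidate_degs()`): per study-by-trait
   intersections and their pooled union, the *candidate DEGs*. Genes hit by
   two traits within a study are reported separately.
4. **Pathway placement** (`placement_table()`, `run_ora()`): where the
   candidates sit in canonical KEGG/WikiPathways sets. The placement table
   is descriptive (hit counts with a minimum-hit filter); the
   over-representation test is the inferential companion.
5. **UR evidence** (`candidate_urs()`, `ur_overlap_scan()`): precomputed UR
   gene lists are intersected with the GWAS pool per study; alternatively, an
   open overlap-enrichment scan over a user-supplied regulator-target network
   stands in for proprietary knowledge-base scoring.
6. **Literature and variant evidence** (`top_genes()`, `rank_variants()`):
   publication-count tables select "most-studied" genes per query category;
   per-gene variants rank by population frequency.
7. **Prioritization** (`build_evidence_matrix()`, `criteria_intersections()`,
   `priority_report()`): six boolean intersection criteria over the evidence
   flags, with the priority set being their union, ranked by the number of
   criteria satisfied.

### The over-representation statistic

For a query of $n$ genes drawn from a universe of $N$ genes, of which $K$
belong to the pathway (or are targets of the regulator) under test, with $k$
observed in the query, the right-tail probability is

$$
p \;=\; P(X \ge k), \qquad X \sim \mathrm{Hypergeometric}(N, K, n),
$$

evaluated through the log-space-stable tail routine of `stats::phyper` and
verified in the test suite against exhaustive enumeration of all
$\binom{N}{n}$ draws for every parameter combination with $N \le 12$.
Benjamini–Hochberg step-up adjustment is applied across all sets (or
regulators) in a scan.

### The six criteria

Writing the evidence flags per gene as *candidate DEG* (DEG that is also a
GWAS vascular gene), *candidate UR*, *recurrent* (candidate DEG in $\ge 2$,
resp. $\ge 3$, studies), *placed* (member of the retained placement rows),
and *top-lit* (in any top-literature set):

| criterion | definition |
|---|---|
| a | recurrent ($\ge 2$) candidate DEG **and** placed |
| b | recurrent ($\ge 2$) candidate DEG **and** candidate UR |
| c | candidate DEG **and** top-lit |
| d | candidate UR **and** top-lit |
| e | placed **and** candidate UR |
| f | candidate DEG recurrent in $\ge 3$ studies |

The priority set is the plain union of (a)–(f), ranked by the number of
criteria satisfied, ties alphabetical. The union rule was a genuinely open
design point — "takes some of the central positions" admits several
formalizations — and we adopted the union because, evaluated on the curated
evidence bundled with the package, it reproduces the published 20-gene
top-priority set exactly, which we treat as confirmation of the
reconstruction. A stricter $\ge 2$-criteria mode is available via
`min_criteria`. Criterion (e) evaluates pathway membership over the
candidate-DEG placement table (the same gene universe as criterion (a)); an
alternative reading over all pathway annotations would need external
annotation the pipeline deliberately does not fetch.

## Tunable parameters

| parameter | default | where | rationale |
|---|---|---|---|
| `min_hits` | 2 | `placement_table()` | a pathway anchored by one lone gene is weak placement evidence; every retained row in the curated table has $\ge 2$ hits |
| ORA significance | $q \le 0.05$ | reporting convenience | conventional FDR level; the placement table itself is threshold-free |
| UR scan significance | $q \le 0.01$ | `ur_overlap_scan()` | regulator-target networks are dense and noisy; the stricter default compensates, and the value is config-exposed |
| literature `min_count` | 34 / 5 / 24 / 5 (DEG-cvd / DEG-nutrition / UR-cvd / UR-nutrition) | `default_literature_thresholds()` | reverse-engineered: the smallest counts that separate the published "largest" gene sets from the unlisted remainder; counts are a dated snapshot, so the thresholds are data, not dogma |
| mapped-gene separators | `" - "`, `";"`, `","`, `" x "` | `parse_mapped_genes()` | the separator set observed in catalog exports; exposed in the function signature |
| alias map | `PPRG→PPARG`, `IL8→CXCL8` | `default_alias_map()` | symbol variants present in the curated source tables; shipped as an editable two-column file |
| universe for ORA | union of collection members | `run_ora()` | the external enrichment service's background is unrecorded; the collection union is the reproducible default, overridable by a background file |

## The synthetic generator

`generate_bundle()` produces complete inputs with planted ground truth so
every stage is testable offline:

* **Studies**: five DEG sets of sizes 1693/717/554/2231/1401 over a
  20,000-gene universe (the magnitudes of the source studies), built as a
  shared core drawn once plus independent uniform draws; planted priority
  genes are placed in at least two studies.
* **GWAS export**: trait gene sets of 375/69/58 genes, a configurable
  fraction drawn from the DEG union (default 0.25, enough to produce a
  candidate pool of roughly the observed magnitude), wrapped in the
  association-export dialect with decoy rows carrying excluded trait
  phrasings.
* **Pathways and network**: background sets are uniform draws; planted sets
  and regulator target lists oversample DEGs by a factor (default 5).
* **Literature counts**: geometric-tail background capped below the
  threshold; planted genes at or above it.

One user seed drives one scrambled stream per stage (two exact
multiplicative congruential steps), so stages never share a stream, nearby
seeds are decorrelated, and identical (parameters, seed) reproduce identical
bytes on disk.

What the generator does **not** emulate: expression levels or fold changes
(only membership and an optional sign), linkage disequilibrium or genotypes,
correlated pathway co-membership, HGNC symbol structure, or the long-tailed
study-size heterogeneity of real catalogs beyond the configured sizes.
Passing recovery tests therefore show that the pipeline's set algebra and
statistics behave correctly under known signal — they do not certify
performance on real transcriptomic noise.

In the test suite and acceptance script, recovery simulations run on a
reduced problem (universe 4,000, study sizes 200–350, 50 seeds, 200 null
scans) whose DEG-union-to-universe ratio (~0.3) matches the full-size
conditions; that ratio is what the planted enrichment factors act against,
so the miniature preserves the signal geometry while keeping runs fast.

## Numerical and degenerate-case choices

* Tails are computed in log space (`phyper(..., lower.tail = FALSE)`);
  `k = 0` returns exactly 1.
* The hypergeometric test is **discrete**: under a true null the rejection
  probability at level $\alpha$ is the attained level
  $P(p \le \alpha) \le \alpha$, not $\alpha$ itself. Calibration tests
  therefore compare the empirical rejection fraction to the *exact* attained
  level computed from the null law (observed around 3% at nominal 5% for
  typical target-set sizes), plus a one-sided validity bound at the nominal
  level. A two-sided band around nominal 5% would be wrong for this test.
* All reported gene sets are sorted alphabetically; ranking ties break
  alphabetically; variant-frequency ties break by rsid in plain string
  order. These choices make every output byte-deterministic.
* Duplicate genes within a study collapse silently (probe-to-gene maps are
  many-to-one); conflicting duplicate directions drop the direction with a
  warning. Empty trait filters return empty sets with a warning, not an
  error; an empty universe or network is an error.
* The pooled GWAS gene count is catalog-version-dependent and is never
  asserted; likewise the per-source KEGG/WikiPathways tallies of the curated
  placement table (recounting gives per-source totals one off from the
  published split, while the 33-gene union reconciles exactly — only the
  union is asserted).

## Known limitations

* Live services (GWAS Catalog, PubMed, pathway databases, variant browsers,
  proprietary UR prediction) are replaced by file-based snapshots; results
  are only as current as the supplied tables.
* The UR overlap scan is a transparent substitute for knowledge-base causal
  scoring: it tests target-set overlap only, with no activation/inhibition
  z-scores and no literature-curated edge confidence.
* The five source studies' complete DEG lists are distributed as a
  supplementary appendix and are not redistributed here; regressions that
  need them (pooled DEG count, full recurrence counts, the 106-gene
  candidate pool) run only when a user installs those lists (see
  `read_supplementary_degs()`). Everything else is reconstructible from the
  curated lists bundled with the package.
* Literature "top gene" thresholds encode a published snapshot; with
  regenerated counts the thresholds should be revisited.
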