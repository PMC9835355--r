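---
title: "Community metabolic networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community metabolic networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comscope)
```

`comscope` treats a microbial community as a single metabolic agent: the
union of enzymatic functions detected in a metagenome defines a reaction
repertoire, and simulations over the directed compound graph ask what
that repertoire can consume and produce. This vignette explains each
model in the chain, the parameters that matter, the numerical choices
made where the design was genuinely open, and what the synthetic-data
module does and does not emulate.

## The reaction bank and the compound graph

A `reaction_universe` is a flat catalogue: each reaction has one or more
EC numbers, nonempty substrate and product compound sets and a
reversibility flag. We deliberately avoid stoichiometry and mass
balance: the downstream algorithms are purely set- and graph-based, and
a flat TSV/JSON dialect keeps the tool independent of any specific KEGG
snapshot or licence. Reaction directionality conventions differ between
database versions, so reversibility is an explicit input column rather
than something inferred.

Two semantics of the same reaction set are used:

* the **pairwise graph** (`build_graph()`): an edge substrate → product
  for every substrate/product pair, both directions for reversible
  reactions. This flattening is what the topological seed analysis needs.
* the **hyperedge view** (`expand_scope()`): a reaction fires only when
  *all* its substrates are available. Feasibility of reversible
  reactions is checked independently per direction, and firing consumes
  nothing (set semantics).

A reaction is considered available to an enzyme set when *any* of its
ECs is present — the presence of one annotated catalyst suffices.
Currency metabolites (water, ATP, ...) receive no special treatment by
default; an explicit exclusion list may be passed to `load_universe()`,
and exclusions are logged, because silent cofactor stripping is a common
source of irreproducible network results.

## Seed compounds: sources of the condensation

Compounds a community consumes but cannot produce sit in strongly
connected components with no incoming edges. `condensation_seeds()`
contracts SCCs, asserts the condensation is acyclic, and reports *all*
members of each source component as seeds with confidence
1/|component|: within an SCC the data cannot distinguish which member is
the true external resource, so reporting the full component with split
confidence is both deterministic and honest. A single node whose only
edge is a self-loop is a legitimate (degenerate) source component and is
reported. A `min_confidence` cutoff is exposed but defaults to 0 (keep
everything), since no principled component-size cutoff exists a priori.

Sub-networks built from differentially abundant enzymes alone are
highly fragmented and predict many artificial sources; only compounds
that are *also* seeds of the full meta-network are kept
(`intersect_seeds()`). The intersected list is the treatment's
environment proxy and feeds the expansion.

## Expansion and knockouts

`expand_scope()` computes the least fixed point of "fire every feasible
reaction, add its products". The scope is provably independent of scan
order (each iteration fires the complete feasible frontier), monotone in
both seeds and enzymes, and idempotent — all three properties are
checked against a naive shuffled-scan oracle in the test suite. The
iteration trace is retained for inspection but is not part of result
equality.

Knockouts (`knockout_group()`, `knockout_all()`) remove *enzymes*, not
reactions: a reaction disappears only when every one of its ECs present
in the enzyme set is dominated by the group being removed, so functions
with an alternative catalyst survive — this is what lets the simulation
expose redundancy and hierarchical position, which static
pathway-completeness profiling cannot. The reference scope is the
treatment-specific expansion; impact is reported as metabolite count
(compound-set difference), with per-group reports independent of one
another and a combined all-groups removal reported alongside.

## Taxa dominance of enzymatic functions

For each enzyme and sample we take the distribution of taxonomic
affiliations of its supporting reads and compute the Simpson index in
its dominance form `D = Σ p_i²`. The dominance form (rather than the
diversity form `1 − Σ p_i²`) is the deliberate choice: the calling rule
thresholds *dominance* at `D > 0.4`, and the diversity form would invert
the inequality. Note a structural floor: any two-taxon distribution has
`D ≥ 0.5`, so sparse enzymes carried by two taxa clear the threshold
easily — which is why the second condition exists. An enzyme is called
dominated in a treatment only when the mean `D` across that treatment's
replicates exceeds the threshold *and* the argmax taxon is identical in
every replicate. Replicates with zero reads for the enzyme are excluded
from both conditions and counted, rather than breaking the agreement
condition: absence of evidence in a shallow replicate should not veto an
otherwise consistent call. Argmax and modal-taxon ties are broken
lexicographically and logged, so results are order-invariant and
reproducible.

"Mean across all samples" is interpreted as the mean across the
treatment's replicates only — dominance is treatment-specific by
construction, which is what makes knockout simulations
environment-specific.

## Differential abundance

The DA stage is an ordinary two-group count test and is implemented as
TMM normalization plus a conditional negative-binomial exact test with a
single pooled dispersion:

* **TMM** follows the standard defaults: reference column = library
  size closest to the mean, 30% two-sided trim on M values, 5% on A
  values, inverse-variance weights, factors rescaled to geometric mean
  one. The test suite verifies bit-level agreement with edgeR's
  `calcNormFactors` on simulated data.
* **Dispersion** is a pooled method-of-moments estimate,
  `φ = Σ_f (s²_f − m̄_f) / Σ_f m̄_f²` over within-group moments on
  pseudo-counts, floored at 1e-6. This is not edgeR's
  quantile-adjusted CML; we do not attempt bit-exact replication, and
  `read_precomputed_da()` provides an injection port for verbatim edgeR
  output. On simulated data the p-values correlate with edgeR's
  `exactTest` at r > 0.999.
* **The exact test** conditions on the feature's total pseudo-count;
  the p-value sums the probabilities of all group splits at most as
  likely as the observed one. Swapping group labels negates the fold
  change and leaves p unchanged, by symmetry of the construction.
* Features with an all-zero group get 0.5 added to both group means
  for the fold-change report only (never to the test), keeping log
  fold changes finite.

Calibration is verified by simulation: 1000 null NB features (mean 50,
dispersion 0.1, 5 vs 5) give an empirical type-I error at `p ≤ 0.05`
close to nominal (pooled across three seeds it sits within
[0.035, 0.065]), and 8-fold spike-ins are recovered at ≥ 90% power at
`q ≤ 0.05`. Significance defaults to FDR-adjusted `q ≤ 0.05`.

## Enrichment

`enrich_terms()` is a one-sided hypergeometric over-representation test
with BH adjustment over the terms actually tested (overlap ≥ 1). The
background set is a real choice the data do not dictate: for compound
enrichment we default to the compounds appearing in any scope under
comparison, and for KO/module enrichment to the KOs observed in the
merged count table; both are arguments, not constants. The
`dominance_filtered_terms()` reporting filter (≥ 6 entities, ≥ 85% from
one treatment) reproduces the convention of showing only terms with a
clear treatment signature.

## The synthetic-data module

`synth_spec()` fixes the study conditions; `generate_universe()` and
`generate_counts()` realise them deterministically from the seed. The
generator emulates:

* a **layered reaction universe** in which the planted seed compounds
  are the only sources (every other compound is the product of a
  reaction whose substrates come strictly earlier), so the ground-truth
  seed set is exact by construction;
* **treatment-specific resources**: each treatment owns a private block
  of seeds plus a shared block, and the reactions consuming a
  treatment's seeds carry that treatment's planted differentially
  abundant ECs. This mirrors the biology being modelled — amendment-
  derived resources consumed by amendment-enriched functions — and
  guarantees the DA sub-network contains the seed-consuming reactions;
* **NB counts** with variance = mean + φ·mean² (defaults: mean 200,
  φ = 0.1, 5 replicates × 2 treatments, 12 DA ECs per treatment at
  8-fold);
* **planted dominance**: three taxa each own a terminal private chain
  of four compounds reachable only through four dedicated ECs; in the
  treated samples those ECs give their taxon 90% of reads
  (`D ≈ 0.9² + 7·(0.1/7)² ≈ 0.81`, comfortably above 0.4), while in
  control samples they fall back to the shared profile. Non-dominated
  ECs draw taxon profiles from a symmetric Dirichlet with concentration
  5 over all eight taxa, for which `E[D] = (α+1)/(kα+1) ≈ 0.15`; a
  concentration of 1 was rejected because its draws cross the 0.4
  threshold often enough to make "non-dominated" ground truth
  ill-defined.

Sizes default to ~80 backbone compounds, ~107 reactions and ~70 ECs,
chosen so the complete pipeline (including the calibration simulations)
runs in seconds on one CPU while every planted signal remains
recoverable at the stated rates.

What the generator does **not** emulate — and what passing tests
therefore do not demonstrate about real data: assembly and annotation
noise (chimeric contigs, wrong LCA calls; each synthetic gene sits on
its own contig, so the contig majority rule is exercised on hand-built
fixtures instead), multi-mapping reads, compositional biases beyond
what TMM corrects, cofactor hubs and the heavy-tailed degree
distribution of real metabolic networks, and reversibility
misannotation. Results on real data inherit all the uncertainty of the
upstream annotation pipeline.

## Numerical and degenerate-input conventions

* Ties (modal contig taxon, dominant taxon) break lexicographically and
  are logged.
* Unknown seeds passed to `expand_scope()` are dropped with a warning —
  treatment seed lists routinely reference compounds absent from an
  EC-restricted bank.
* Unknown ECs in `restrict_to_ecs()` yield no reactions and a logged
  message; the empty enzyme set yields an empty graph, whose seed set
  and scope are empty.
* A zero-total distribution has no Simpson index (error at the single-
  distribution level; excluded-and-counted at the calling level).
* The condensation is asserted acyclic; seed and scope outputs are
  sorted, so all results are insertion-order invariant.

## Known limitations

Qualitative set semantics cannot capture rates, yields or
concentration-dependent effects; seed prediction reports whole source
components and cannot localise the true resource within a cycle; the NB
exact test supports two-group designs only (no covariates or paired
designs); and the common-dispersion assumption is shared across
features, which is mildly anticonservative for features with unusually
high dispersion. Where these matter, the DA injection port and the
per-module TSV interfaces let individual stages be replaced.

```{r example}
spec <- synth_spec(seed = 1)
dir <- tempfile()
invisible(synth_all(spec, dir))
res <- run_pipeline(dir, treatment = "SM", control = "NTC")
res$knockouts$summary
```
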