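# crosspath

Shared-pathway and common-module discovery across related diseases.

Groups of distinct but related diseases -- neurodegenerative disorders
such as Alzheimer's, Parkinson's and Huntington's disease are the
archetype -- often share symptoms, suggesting partly shared pathogenic
mechanisms. `crosspath` turns that observation into a concrete network
analysis for computational biologists who have, per disease, a
susceptibility gene panel, plus a protein-protein interaction network and
a pathway database:

1. **Panel expansion** (optional): a sparsely annotated disease panel is
   expanded by random walk with restart (RWR) over the interaction
   network, iterating `p[t+1] = (1 - γ) W p[t] + γ p0` with restart
   probability γ = 0.75 and keeping the top 400 ranked genes.
2. **Common genes**: the panels' intersection, with a permutation test
   (random panels of the same sizes drawn from the network) for its
   size. Empirical p-values use the add-one rule; a Poisson fit to the
   null counts supplies a parametric companion below the empirical
   resolution floor.
3. **CFNN**: the common-gene first-neighbor network -- the induced
   subgraph on the common genes and all their interaction partners.
4. **Enrichment**: every pathway is tested two-sidedly
   (enrichment/depletion) under Hypergeometric(N, m, n), with
   Benjamini-Hochberg correction and significance at adjusted p < 0.05.
5. **Clustering and modules**: significant pathways are clustered by
   cosine distance between their binary associated-gene profiles
   (average linkage, tree cut 0.9 by default); each cluster's shared
   associated genes induce a *common module* inside the CFNN, whose
   average clustering coefficient measures how tightly it is wired.
6. **Expression evaluation** (optional): per-gene Welch t-tests with BH
   correction, and a permutation test for the number of differentially
   expressed multi-protein pathway components (a component counts as hit
   when any of its member proteins is differentially expressed).

A synthetic-data generator (`generate_synthetic_study()`) produces all
inputs with planted ground truth -- a scale-free network, panels with a
known common-gene set, pathways enriched around a planted 6-gene clique
module, and expression with planted effects -- so the entire pipeline is
testable end to end with no downloads.

## Worked example

```r
library(crosspath)

study <- generate_synthetic_study(synth_config(seed = 42))
cfg <- pipeline_config(
  network = study$network, panels = study$panels, pathways = study$pathways,
  components = study$components, expression = study$expression,
  n_replicates = 10000, seed = 42,
  component_pathways = study$truth$planted_enriched_pathway_ids[1]
)
run <- run_pipeline(cfg, "example_run")
```

The run narrates each stage:

```
[load] n_genes=1500, n_interactions=7506, n_panels=3, n_pathways=120
[overlap] n_common=10, p_empirical=9.99900009999e-05, p_parametric=1.47526133293677e-13
[cfnn] n_nodes=266, n_edges=848, avg_cc=0.215047741863443
[enrich] n_tested=120, n_significant=9
[cluster] n_associated_genes=192, n_clusters=2
[diffexpr] n_tested=1500, n_significant=371
[components] n_pathways_tested=1
```

The three panels share 10 genes -- exactly the planted common set -- and
no random panel triple matched that in 10⁴ replicates:

```r
run$overlap_test
#> Permutation test: observed = 10, 0/10000 null replicates >= observed
#>   p (empirical, add-one)  = 9.999e-05
#>   p (parametric, poisson; null mean 0.241) = 1.475e-13
```

The most enriched pathways are the planted ones (55 of pathway pw004's
72 genes lie in the 266-gene CFNN, against a null expectation of ~13):

```r
head(run$enrichment[, c("pathway_id", "category", "k", "m", "p_adj", "direction")], 4)
#>   pathway_id   category  k  m        p_adj direction
#> 1      pw004    disease 55 72 1.453849e-26  enriched
#> 2      pw056    disease 57 79 1.063832e-25  enriched
#> 3      pw009    disease 50 67 1.527313e-23  enriched
#> 4      pw119 functional 35 48 1.486692e-15  enriched
```

Clustering the significant pathways finds the planted module -- a fully
connected 6-gene core shared by all 8 planted pathways -- and the
expression data confirm the tested pathway's components:

```r
run$modules[["1"]]
#> Common module (cluster 1): 8 pathway(s), 6 common gene(s)
#>   subnetwork: 6 nodes, 15 edges; avg clustering coefficient 1.000

run$component_tests[[1]]
#> Component test for pathway 'pw004': 32/49 components hit, p = 9.999e-05 (10000 replicates)
```

A module clustering coefficient of 1.0 against a CFNN-wide 0.22 is the
signature of a densely wired core; `summarize_run("example_run")` writes
a one-page report of all of the above from the stored artifacts.

Every stage writes plain TSV/JSON files plus a `manifest.json`
(parameters, seeds, per-stage tallies), and identical config + seed
reproduces every artifact byte for byte. Pipelines can also be driven
from YAML (`pipeline_config_from_yaml()`); a minimal config:

```yaml
network: network.tsv      # 2-column edge list (or SIF)
panels: panels.gmt        # >= 2 disease panels
pathways: pathways.gmt
n_replicates: 10000
seed: 42
```

`inst/scripts/crosspath.R` wraps `simulate`, `run` and `summarize` for
shell use.

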