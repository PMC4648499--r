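---
title: "Methods: shared-pathway and common-module discovery with crosspath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shared-pathway and common-module discovery with crosspath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosspath)
```

## The problem

Distinct but related diseases -- the motivating case is the
neurodegenerative triad of Alzheimer's, Parkinson's and Huntington's
disease -- often share symptoms, which suggests partly shared pathogenic
mechanisms. `crosspath` operationalizes that intuition: given each
disease's susceptibility gene panel and a protein-protein interaction
network, it asks which genes the diseases share, whether that sharing is
more than chance, which biological pathways the shared genes' network
neighborhood is enriched for, and which densely connected network modules
sit behind groups of those pathways.

The pipeline has six stages, each exposed as ordinary R functions and
orchestrated by `run_pipeline()`:

1. *Panel expansion* (optional). A disease with few annotated genes is
   expanded by random walk with restart (RWR) over the interaction
   network.
2. *Common genes.* The panels are intersected; the intersection size is
   tested against a permutation null of random panels of the same sizes.
3. *CFNN.* The common genes plus all their direct interaction partners
   form the common-gene first-neighbor network.
4. *Enrichment.* Each pathway in a database is tested for enrichment or
   depletion of CFNN genes (two-sided hypergeometric, BH-corrected).
5. *Clustering and modules.* Enriched pathways are clustered by the
   cosine similarity of their associated-gene profiles; each cluster's
   shared genes induce a common module within the CFNN.
6. *Expression evaluation* (optional). Two-group differential expression
   feeds a permutation test on differentially expressed multi-protein
   pathway components.

## Random walk with restart

The walk iterates

$$p_{t+1} = (1-\gamma)\, W p_t + \gamma\, p_0,$$

where $W$ is the column-normalized adjacency matrix, $p_0$ places equal
mass on the seed genes, and $\gamma$ is the restart probability. We use
$\gamma = 0.75$, the standard choice in network-based disease-gene
prioritization, and keep the top 400 ranked genes (seeds included) as the
expanded panel by default; both are configurable via `rwr_config()`.

Numerical choices, all of them ours since the model itself does not fix
them:

- **Convergence.** The iteration is a contraction with factor
  $1-\gamma$, so we stop when the L1 change drops below `1e-10` (a few
  dozen iterations at $\gamma = 0.75$), with a cap of `1e5` iterations.
  Each iterate provably conserves probability mass; `rwr_propagate()`
  records the running sums and residuals so tests can assert both.
- **Dangling nodes.** Isolated genes cannot carry walk mass. Rather than
  inventing a teleport rule, the walk removes them (with a message) and
  refuses seed sets containing them.
- **Ties.** Ranking ties are broken lexicographically by gene
  identifier, so panel selection is deterministic.
- **Seeds** retain restart mass and in practice always rank near the
  top; they are *not* forced into the selection, but a warning names any
  seed that falls outside it.

## Significance of the common genes

`overlap_permutation_test()` draws panels of the observed sizes uniformly
without replacement from the network's gene set, independently of one
another, and records each replicate's intersection size. The empirical
p-value uses the add-one rule $(b+1)/(R+1)$, where $b$ counts replicates
at or above the observed value -- the standard convention that avoids
reporting zero.

An empirical estimate from $R$ replicates cannot resolve below
$1/(R+1)$, yet genuinely extreme overlaps deserve a sharper number. We
therefore also fit a Poisson distribution to the null intersection counts
-- a natural family for rare-overlap counts, whose adequacy the null mean
in the output lets you judge -- and report its upper tail as a parametric
companion p-value. The output labels the family explicitly; when the two
p-values disagree materially, trust the empirical one.

## CFNN semantics

`build_cfnn()` keeps the common genes present in the network plus all
their neighbors and returns the *induced* subgraph: edges between two
first neighbors are retained even when neither endpoint is a common gene.
This matches the interpretation of the CFNN as a network neighborhood
rather than a star expansion, and it is the semantics under which
neighborhood density (clustering coefficients) is meaningful. Isolated
common genes have no neighborhood and are excluded with a warning.

## Pathway enrichment

For a query of $n$ genes and a pathway with $m$ genes inside a universe
of $N$, the overlap $k$ is referred to Hypergeometric$(N, m, n)$.
Conventions:

- **Two-sided p.** Twice the smaller of the upper and lower tail,
  capped at 1. Doubling is transparent and exactly checkable against
  enumeration of all draws, which the test suite does for every
  parameter combination with $N \le 20$.
- **Direction.** "Enriched" when $k \ge nm/N$ (ties count as enriched),
  "depleted" otherwise. Zero-overlap pathways are still tested; a
  pathway can be significantly depleted.
- **Universe.** Defaults to all genes annotated to at least one pathway
  in the database; pass the network's gene set or a custom list to
  change the reference population. All counts ($k$, $m$, $n$, $N$) are
  computed inside the chosen universe.
- **Correction.** Benjamini-Hochberg across all tested pathways;
  significance at adjusted $p < 0.05$ by default.

## Pathway clustering and common modules

Genes present in both the CFNN and at least one significant pathway are
the *associated genes*. The binary gene-by-pathway membership matrix
yields pairwise pathway distances $1 - \cos$ on raw 0/1 profiles (no
weighting or centering -- the profiles are genuinely binary). Significantly
*depleted* pathways can have empty profiles; they carry no clustering
signal and are dropped from the matrix with a message.

Agglomerative clustering then cuts the tree at a fixed height. The
default is **average linkage with a cut of 0.9**: with average (or
complete) linkage on cosine distances every merge height lies in
$[0, 1]$, so a cut slightly below 1 separates pathway groups that share
any appreciable gene signal from unrelated singletons. Cut heights above
1 are only reachable under linkages that inflate merge heights (e.g.
Ward); `cluster_pathways(..., linkage = "ward")` supports that
convention, including the cut of 1.1 sometimes used with it. Cluster
numbering is assigned by each cluster's lexicographically smallest
pathway, making reports stable under input reordering.

Each cluster's *common module* is the intersection of its member
pathways' associated-gene sets, together with that set's induced
subnetwork in the CFNN. An empty intersection is reported as "None"
(average clustering coefficient `NA`). The average clustering coefficient
treats nodes of degree below 2 as contributing 0 -- the dominant
convention, and the one that keeps the statistic defined on all graphs;
on non-degenerate graphs it simply averages the per-node triangle
fractions.

## Differential expression and component tests

`de_test()` runs a per-gene Welch two-sample t-test on log-scale values
with BH correction. A moderated (empirical-Bayes) t would borrow strength
across genes; we deliberately keep the engine a plain, dependency-free
two-group test -- the pipeline's contract is "a per-gene two-group test
plus BH", and the engine is documented and swappable. Inputs are assumed
already normalized; the package does no array preprocessing. Genes with
zero variance in both groups are marked non-testable and excluded from
the BH denominator rather than assigned $p = 1$, which would dilute the
adjustment.

Pathway diagrams collapse interchangeable proteins into single
*components* (an alpha-Catenin node standing for CTNNA1/2/3, say). A
component counts as differentially expressed when *any* member is.
`component_permutation_test()` compares the observed number of hit
components to draws of equally many random genes from a universe that
defaults to the genes measured on the array -- the set the observed DEG
list was itself selected from; any custom universe can be supplied.

## The synthetic generator

`generate_synthetic_study()` produces inputs with the statistical
structure the analysis assumes, plus ground truth, so the whole pipeline
is testable without external databases. What it emulates, and the
defaults (`synth_config()`), scaled roughly tenfold down from a
genome-scale study:

- **Network:** a connected preferential-attachment graph on 1500 genes
  (5 attachment edges per node), giving the heavy-tailed degree
  distribution characteristic of interaction networks. The planted
  module -- 6 genes wired into a clique -- is attached to a designated
  anchor hub that is always part of the planted common genes, which
  guarantees the module lies inside the CFNN, mirroring a disease
  module sitting in the shared genes' neighborhood.
- **Panels:** sizes 100/60/90 with 10 planted common genes. The draw is
  repeated until the three-way intersection equals the planted set
  *exactly*, so intersection recovery is a sharp test rather than a
  probabilistic one; `enforce_exact = FALSE` yields fully uniform
  panels for null calibration.
- **Pathways:** 120 sets of 15-80 genes; 8 planted enriched pathways
  draw 70% of their members from the module plus the planted common
  genes' neighborhood (and always contain the full module), the rest
  uniformly. Every pathway is partitioned into components, 30% of them
  multi-protein (2-3 members).
- **Expression:** Normal(0, 1) baseline over all genes, 10 samples per
  group; 375 planted genes (25% of the matrix) get a +2 log-unit shift
  in cases, biased toward the enriched pathways' members.

The planted-DE fraction is a *power design choice*: with effect 2, noise
sd 1 and 10 samples per group, the self-consistent BH threshold at a 25%
planted fraction gives closed-form Welch power ≈ 0.94, so the planted
genes are recoverable at adjusted $p < 0.05$ with margin and a recovery
test probes correctness rather than marginal power. At, say, a 5%
planted fraction the same closed-form calculation gives power ≈ 0.78 --
a configuration in which even a perfect implementation recovers barely
three quarters of the planted genes.

```{r power, eval = FALSE}
ncp <- 2 / sqrt(2 / 10); df <- 18; pow <- 0.9
for (i in 1:50) {
  a <- 0.05 * 0.25 * pow           # self-consistent BH threshold
  crit <- qt(1 - a / 2, df)
  pow <- 1 - pt(crit, df, ncp) + pt(-crit, df, ncp)
}
pow  # ~0.94
```

For permutation-calibration checks the generator is used in a *null*
configuration with large panels relative to a 2000-gene universe (e.g.
800/700/750, no planting), and the component test with an inventory of
300 components. These sizes are chosen so the null statistic is spread
over many values: with the default sparse panels the null intersection is
almost always 0 or 1, the empirical p-value is dominated by ties, and a
uniformity check is uninformative rather than wrong.

What the generator does **not** emulate: probe-level microarray noise,
correlated expression between interacting genes, literature or annotation
bias in the panels, pathway overlap structure from a real curated
database, and inter-database identifier conflicts. Passing recovery tests
therefore demonstrates correctness of the computations under the model's
assumptions, not performance on any real disease.

## Determinism and problem sizes

All randomness flows from explicit integer seeds (`synth_config(seed=)`,
`pipeline_config(seed=)`); generators derive independent sub-streams from
the master seed, the pipeline derives stage seeds, and RNG state is
restored after every internal draw, so the same configuration reproduces
a run byte for byte -- the test suite asserts md5 equality of all
artifacts across repeated runs.

The test suite exercises the default study (1500 genes) for end-to-end
recovery, 200-run calibration loops at 199 permutation replicates, and
400-gene studies for the faster structural checks; these sizes keep the
whole suite under a minute while leaving all statistical margins
comfortable (the design calculations above are evaluated at the actual
sizes used).

## Known limitations

- Gene identifiers are opaque case-sensitive strings; cross-namespace
  mapping (protein to gene, probe to gene) must happen upstream.
- The parametric overlap p-value assumes a Poisson null; for universes
  or panel sizes where the null overlap is broad and underdispersed,
  the empirical p-value is the one to report.
- The enrichment universe convention affects results materially, as it
  does in every enrichment tool; the default (annotated genes) is
  conservative when the network is much larger than the database.
- Average-linkage cosine clustering cannot produce merge heights above
  1; cut heights above 1 silently yield a single cluster under that
  linkage, which is why the cut and the linkage are configured jointly.
- The DE engine is an unmoderated Welch test; for very small sample
  sizes a moderated test would have more power, at the cost of an
  external dependency.
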