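---
title: "Quantifying proteome-level functional redundancy in microbiome samples"
author: "proteoFR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying proteome-level functional redundancy in microbiome samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoFR)
```

## The question

A gut microbiome can lose many taxa and keep working, because different taxa
express overlapping sets of functions. Most attempts to quantify this
*functional redundancy* work at the genome level: what a taxon *could* do.
proteoFR works at the proteome level: what the community's members are
*actually expressing*, as captured by metaproteomics. The package builds
weighted bipartite taxon-function networks from protein and peptide tables,
computes redundancy indices from them, and provides the topological and
simulation machinery needed to interpret those indices.

## Networks

Two networks describe one sample:

* the **proteomic content network (PCN)**: genera x expressed functions,
  weighted by protein-group intensity, and
* the **genomic content network (GCN)**: genera x encoded functions,
  weighted by metagenomic read counts.

Both are stored as an `S x F` matrix whose row `i` is normalised by the
taxon's total signal, so `P_ia` (or `G_ia`) is the *relative* investment of
taxon `i` in function `a`. Every PCN edge should be a GCN edge: expression
requires a gene.

Metaproteomic search engines identify *protein groups*, not taxa, so the PCN
is built with a peptide-protein bridge. Each group's member peptides are
looked up in the peptide table; peptides flagged unique whose
lowest-common-ancestor (LCA) lineage reaches genus level vote for their
genus, and the group's intensity is split across genera proportionally to
the summed unique-peptide intensity per genus. The split conserves the
group's total intensity exactly. Peptides whose LCA sits above genus carry
no taxonomic signal at the working rank and are excluded from both the
bridge and the biomass profile. Function labels merge two annotation
namespaces: a group's KEGG KO is used when present, otherwise its COG;
groups with neither carry no functional information and are dropped before
row normalisation.

Relative taxon biomass `p_i` comes from the same peptide table: the summed
intensity of genus-resolved unique peptides per genus, normalised across
genera.

## Redundancy indices

With the row profiles in hand, the functional distance between two taxa is
the weighted Jaccard distance

$$d_{ij} = 1 - \frac{\sum_a \min(P_{ia}, P_{ja})}{\sum_a \max(P_{ia}, P_{ja})} \in [0, 1],$$

zero for identical expression profiles and one for disjoint ones. Four
within-sample indices follow:

* taxonomic diversity (Gini-Simpson) $TD = 1 - \sum_i p_i^2$,
* functional diversity (Rao quadratic entropy)
  $FD = \sum_i \sum_{j \ne i} d_{ij}\, p_i p_j$,
* functional redundancy
  $FR = TD - FD = \sum_i \sum_{j \ne i} (1 - d_{ij}) p_i p_j$, and
* normalised redundancy $nFR = FR / TD$.

`nFR` is the expected functional overlap of two members drawn at random
from different taxa: 1 when everyone expresses the same profile, 0 when all
profiles are disjoint. Distances are always computed *within* the sample,
never against a pooled cross-sample reference, because expression responds
to the sample's own environment; pooling would blur exactly the signal the
proteome-level index is meant to capture. For a single-taxon sample
(`TD = 0`) we define `nFR = 0`: there is no pair to be redundant. The
Gini-Simpson index is used without small-sample correction so that the
`FR = TD - FD` identity is exact.

```{r extremes}
p <- AbundanceProfile(c(A = 0.5, B = 0.3, C = 0.2))
same <- TaxonFunctionNetwork(matrix(rep(c(0.2, 0.5, 0.3), each = 3), 3,
  dimnames = list(c("A", "B", "C"), c("K1", "K2", "K3"))), "pcn")
nfr(functionalRedundancy(p, weightedJaccard(same)))  # identical proteomes: 1
```

## Topology

`connectance()` (links over possible links), `degreeDistribution()` and
`nodf()` characterise the binarised network (presence is weight > 0; no
abundance cutoff, since none is implied by the data model). NODF is the
classical nestedness metric based on overlap and decreasing fill, reported
on the [0, 1] scale: over all row pairs and column pairs, the fraction of
the sparser line's links shared with the strictly denser line, with ties in
fill contributing zero. A strict staircase scores 1; equal fills and
checkerboards score 0. The implementation is checked in the test suite both
against a brute-force pair enumeration and against `vegan::nestednodf`
(with fill-ordering, unweighted), which serves purely as an independent
reference. Convention differences around tie handling exist between NODF
implementations; we follow the classical rule.

## Null models

To ask how much of the observed redundancy is explained by network
topology, a natural PCN is randomized under its GCN background: every
randomized edge must be a GCN edge. Four variants tighten the constraints
stepwise: null-1 fixes only the edge count; null-2 preserves each taxon's
degree; null-3 each function's degree; null-4 both degree sequences.
Null-1 to null-3 are direct uniform draws (over GCN edges, per-taxon GCN
subsets, and per-function GCN subsets respectively). Null-4 uses a
swap-chain restricted to GCN-admissible cells: a trade moves one function
between two taxa in each direction and is accepted only if both destination
cells are GCN edges; we run 5x(edge count) accepted trades as burn-in and
between successive samples. On small instances the chain visits all
feasible configurations approximately uniformly (tested by enumeration).

Randomization only fixes the binary edge set, so weights must be
re-assigned. The default gives each taxon's new edges equal weight
(`1/degree`) — the least-assumption choice; the `"permute"` policy instead
redistributes the taxon's original weight multiset over its new edges and
is available when taxon degrees are preserved (null-2/null-4). The two
policies answer different questions: uniform weights remove all weight
heterogeneity (and tend to *raise* overlap between rows), while permuted
weights isolate the effect of *which* functions the weights sit on. The
packaged comparison of a strongly nested synthetic sample uses the permute
policy for exactly that reason.

## The assembly simulation

Why would expressed networks be so much sparser than encoded ones, and does
that matter ecologically? The package includes a MacArthur consumer-resource
model with cross-feeding: taxa `i` consume resources `a` with flux
`J_in = C_ia R_a`; a leakage fraction `l` of consumed flux returns to the
environment as byproducts routed by a matrix `P` (columns are consumed
resources, rows byproducts, columns summing to 1 so leaked mass is
conserved); the rest becomes biomass with yield `Y`. Resources and microbes
share the supply/dilution environment:

$$\dot R_\alpha = h_\alpha - D R_\alpha + \sum_i N_i (J^{out}_{i\alpha} - J^{in}_{i\alpha}), \qquad
  \dot N_i = N_i \left[ Y (1 - l) \sum_\alpha J^{in}_{i\alpha} - D \right].$$

The headline experiment draws a consumption matrix whose connectance
matches a GCN (0.22), subsamples it to PCN connectance (0.05) keeping the
same rates, and assembles both communities from the same byproduct matrix,
supply and initial conditions (S = M = 100, D = 0.2 h⁻¹, l = 0.5, 20 of
100 resources supplied). Final richness (taxa above the extinction
threshold) is compared across pairs with a two-sided Mann-Whitney U test.
Sparser, PCN-like consumption consistently sustains higher richness.

Choices that the model statement leaves open are fixed as package defaults,
all exposed as arguments: yield `Y = 1`; supply rate 1 concentration h⁻¹
for each supplied resource; initial abundances `N_i(0) = 0.01`; initial
resources at the supply equilibrium `h/D`; horizon 2000 h with early stop
once the maximum relative derivative falls below 1e-7; extinction threshold
1e-6. Integration uses `deSolve::lsodar` (rtol 1e-8, atol 1e-10) with
states clipped at zero, since extinctions make the system stiff near the
boundary. The single-taxon, no-leakage system has the closed-form fixed
point `R* = D/(YC)`, `N* = (h - D R*)/(C R*)`, used as an exact check, and
summing the equations at equilibrium gives the mass balance
`sum(h) = D (sum R + sum N / Y)`, checked on random multi-species systems.

## Distance distributions across samples

`collectPairs()` pools per-sample `d_ij` values into a long table after a
*dataset-wide* biomass filter: genera holding the top 95% of the mean
biomass profile across samples are retained (per-sample filters would make
pair sets incomparable across samples). A pair missing from a sample
(one genus unobserved there) is simply absent — absence of evidence is not
maximal distance. Distributions are compared with a histogram
Jensen-Shannon divergence (50 equal-width bins on [0, 1], pseudo-count
1e-10, base-2 logs so the value lies in [0, 1]); bin count and pseudo-count
are arguments. Per-pair group differences use the two-sided Wilcoxon
rank-sum test with Benjamini-Hochberg correction across pairs, reported
alongside the log2 fold-change of mean `d_ij` (defined as 0 when the two
group means are equal, which avoids 0/0 at identical groups).

## The synthetic-data generator

Real deposited datasets require mass-spectrometry pipelines, so the
package generates synthetic inputs that exercise every code path. The
binary GCN scaffold is a noisy threshold graph — taxa and functions carry
attractiveness scores, an edge appears with probability
`plogis((s_i + t_a - theta)/T)` — which produces the nested, fat-tailed
degree structure typical of real content networks with a single
temperature knob `T`. The PCN expresses a per-taxon fraction of GCN edges,
biased toward high-attractiveness functions. `T` is calibrated against the
realized NODF of the built PCN so the requested nestedness target is met
within 0.1 (infeasible targets fail loudly; very low targets are
unreachable at small dimensions because tie-heavy fills bound NODF away
from 0). One scaffold is shared by all samples of a dataset; per-sample
lognormal noise perturbs weights and abundances, and an optional group
effect multiplies a chosen fraction of functions' intensities in one group,
giving a known ground-truth shift for the distance statistics.

The generator emulates table *schemas* and network *structure*, not
mass spectrometry: peptide sequences are random strings, there is no
missingness structure, ionisation bias, or shared-peptide ambiguity beyond
a sprinkling of non-unique peptides with above-genus LCAs. Green tests
therefore demonstrate correctness of the computations, not robustness to
MS artefacts. `strainProteome()` and `assembleInsilicoCommunity()` cover
the complementary use case of composing communities from measured
single-strain proteomes; `perturbProteome()` emulates condition-dependent
expression shifts (multiplicative lognormal noise plus a shifted function
block).

## Problem sizes and numerics

Default test fixtures use 8-12 taxa and 27-40 functions, where brute-force
oracles (direct double sums for the indices, full pair enumeration for
NODF) are exact and fast; property suites run over hundreds of seeded
random instances at S <= 6, F <= 10. The packaged assembly experiment at
S = M = 100 is run at 25-100 pairs. Row normalisation tolerates 1e-9;
the FR identity is held to 1e-12; Jaccard values are clipped to [0, 1]
against floating-point drift. Ties in the top-biomass filter include all
genera tied at the boundary, keeping the selection deterministic under
relabeling.

## Limitations

* Networks are genus-level; species-level construction would need
  species-resolved unique peptides throughout.
* The proportional intensity split of shared protein groups is one
  defensible convention; razor-peptide style assignment would give
  different (also defensible) weights.
* Whether to row-normalise before or after dropping unannotated groups is
  a real choice; we normalise after, so weights describe the *annotated*
  proteome.
* The CRM is a caricature of gut ecology (universal byproduct matrix,
  shared dilution, single yield); it is used for directional claims about
  connectance and richness, not quantitative prediction.
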