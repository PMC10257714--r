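# proteoFR

Quantifies **proteome-level functional redundancy** of microbiome samples.
Genome-level analyses tell you what a community *could* do; metaproteomics
tells you what it is *actually expressing*. proteoFR builds weighted
bipartite taxon–function networks from metaproteomic protein-group and
peptide tables (proteomic content networks, PCNs) and metagenomic gene
tables (genomic content networks, GCNs), and computes within-sample
redundancy indices from them, for microbiome researchers working with
MetaLab/MaxQuant-style search outputs.

## The indices

With row-normalised functional profiles, the distance between taxa *i* and
*j* is the weighted Jaccard distance

> d_ij = 1 − Σ_a min(P_ia, P_ja) / Σ_a max(P_ia, P_ja)

and, with biomass proportions p_i from unique-peptide intensities:

- TD = 1 − Σ p_i² (Gini–Simpson taxonomic diversity)
- FD = Σ_i Σ_{j≠i} d_ij p_i p_j (Rao quadratic entropy)
- **FR = TD − FD** (functional redundancy)
- **nFR = FR / TD** ∈ [0, 1] (normalised; the expected functional overlap
  of two randomly drawn members)

Around the indices the package provides network topology (connectance,
degree distributions, NODF nestedness), GCN-constrained null networks
(four degree-preserving variants), distance-distribution statistics
(Jensen–Shannon divergence, per-pair rank-sum tests), a cross-feeding
consumer–resource model for community-assembly simulations, and a
synthetic-data generator with controllable nestedness so the whole
pipeline is testable without mass-spectrometry data.

## Worked example

```r
library(proteoFR)

# synthetic dataset: 12 genera, 40 functions, calibrated nestedness
ds  <- generateSyntheticDataset(syntheticSpec(seed = 7))
s1  <- ds$samples$S01
pcn <- buildPCN(s1$proteins, s1$peptides)   # peptide-protein bridge
gcn <- buildGCN(s1$genes)
prof <- biomassProfile(s1$peptides)         # unique-peptide biomass

pcn
#> TaxonFunctionNetwork (PCN): 12 taxa x 27 functions, 157 links, connectance 0.485

sampleSummary(pcn, prof)
#> DiversitySummary: TD 0.730061  FD 0.577201  FR 0.152860  nFR 0.209379

topologySummary(pcn, "S01")
#>   sample_id n_taxa n_functions links connectance      nodf
#> 1       S01     12          27   157   0.4845679 0.6820695
```

Read: two random members of this sample come from different genera with
probability 0.73 (TD); their expressed profiles differ by 0.58 on average
(FD); the redundancy nFR ≈ 0.21 means about a fifth of the taxonomic
diversity is functionally interchangeable. The PCN is clearly nested
(NODF 0.68): specialists express subsets of what generalists express.

Null models and the assembly experiment:

```r
nullFRComparison(pcn, gcn, prof, variants = "null4", nReplicates = 10,
                 seed = 3, weightPolicy = "permute")
res <- pairedRichnessExperiment(nPairs = 25, seed = 17)  # S = M = 100
```

A command-line wrapper with subcommands `synth`, `build`, `metrics`,
`topology`, `nulls`, `crm` and `distances` is installed at
`inst/scripts/pcntool.R` (all logic is in `pcnCLI()`).

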