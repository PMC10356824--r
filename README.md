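# casoil

Soil quality and 16S bacterial community analysis for multi-scenario
conservation-agriculture (CA) field trials.

Long-term tillage-cum-crop-establishment experiments compare farmers'
practice (FP), partial CA (pCA) and full CA management across replicated
scenarios, measuring replicate-level soil chemistry (pH, EC, SOC, N, P, K,
Fe, Mn, Zn, Cu), earthworm density, and 16S rRNA amplicon OTU tables.
`casoil` implements the complete downstream analysis such a study needs —
and a seeded synthetic-data generator that emulates a seven-scenario study
design, so every stage is testable without sequencing data.

## What it computes

**Alpha diversity** (from first principles, per sample):

- Shannon `H = −Σ pᵢ ln pᵢ` (nats), Gini-Simpson `1 − Σ pᵢ²`
  (finite-sample variant available)
- Chao1 (bias-corrected) `S_obs + F₁(F₁−1)/(2(F₂+1))`, ACE with rare
  cutoff 10, Fisher's alpha solving `S = α ln(1 + N/α)`
- exact hypergeometric rarefaction
  `E[Sₙ] = Σᵢ (1 − C(N−cᵢ, n)/C(N, n))`, in log space

**Beta diversity**: Bray-Curtis `Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ)`, principal
coordinate analysis (Gower double-centring `B = −½ J D² J`, symmetric
eigendecomposition), and the rank-based ANOSIM permutation test
`R = (r̄_between − r̄_within)/(M/2)` with a seeded `(1+k)/(1+B)` p-value.

**Soil quality index (SQI)**: one-way-ANOVA significance screening,
correlation-matrix PCA, minimum-data-set (MDS) selection (PCs with
eigenvalue ≥ 0.9 explaining > 5 % variance; indicators within 10 % of the
top |loading| or with |loading| ≥ 0.40; redundancy pruned at Pearson
|r| ≥ 0.60), non-linear sigmoid scoring `S = a/(1 + (x/x₀)^b)` ("more is
better" except EC), PCA-derived weights, and `SQI = Σ Wᵢ Sᵢ`.

**Group statistics**: one-way ANOVA, Duncan's multiple range test with a
compact letter display (studentized-range critical ranges at protection
level `αₚ = 1−(1−α)^(p−1)`), tie-corrected Kruskal-Wallis, Pearson
correlation with two-sided significance.

**Community structure**: rank-level relative abundances with a 1 %
"others" lump, the copiotroph/oligotroph ratio
(Proteobacteria / (Acidobacteria + Chloroflexi)), shared-OTU Venn
partitions across FP/pCA/CA, and a Pearson correlation network among
major phyla.

**Synthetic data**: replicate soil values drawn Normal(mean, SE·√n) from
the per-scenario means/SEs; OTU counts drawn Dirichlet-multinomial
(concentration θ·composition) with geometric within-phylum abundance
profiles. All randomness flows through one seed with deterministic
per-scenario substreams.

## Worked example

```r
library(casoil)
specs <- defaultStudySpecs()                  # seven scenarios, FP/pCA/CA
soil  <- simulateSoilTable(specs, seed = 42)  # 7 x 3 soil replicates
tab   <- simulateOTUTable(specs, depth = 60000, seed = 42)  # 7 x 5 samples

D <- distanceMatrix(tab)
anosimTest(D, sampleScenario(tab), nPermutations = 999, seed = 42)
#> ANOSIM: R = 0.45663, p = 0.001 (999 permutations)

res <- sqiPipeline(soil)
res$selection
#> MDSSelection:
#>   PC1: Cu, SOC
#>   PC2: Mn, pH
#>   PC3: Zn, earthworms
#>   weights: Cu=0.284, SOC=0.284, Mn=0.118, pH=0.118, Zn=0.098, earthworms=0.098
res$sqi@perScenario
#>   scenario  mean      se n
#> 1      scI 0.424 0.01645 3
#> 2     scII 0.422 0.00503 3
#> 3    scIII 0.505 0.01137 3
#> 4     scIV 0.526 0.00365 3
#> 5      scV 0.547 0.01461 3
#> 6     scVI 0.504 0.00379 3
#> 7    scVII 0.536 0.00721 3

phy <- aggregateTaxa(tab, "phylum")
round(tapply(copiotrophOligotrophRatio(phy), managementClass(tab), mean), 2)
#>   CA   FP  pCA
#> 2.11 1.06 1.61
```

The ANOSIM p-value of 0.001 says the scenario labels explain the
community dissimilarity structure; the SQI table ranks the FP scenarios
(scI, scII, ~0.42) clearly below the pCA/CA scenarios (0.50-0.55); and
the copiotroph/oligotroph ratio roughly doubles from FP to full CA,
reflecting the Proteobacteria-enriched communities that conservation
tillage fosters.

A full run — simulation, alpha/beta diversity, SQI, Duncan letters,
community analytics, and a JSON manifest — is one call:

```r
res <- runPipeline(pipelineConfig(seed = 42, outdir = "out"))
```

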