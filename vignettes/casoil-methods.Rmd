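---
title: "Methods and design notes for casoil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for casoil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`casoil` analyses multi-scenario conservation-agriculture (CA) trials
that combine replicate-level soil chemistry, earthworm counts and 16S
rRNA amplicon OTU tables. This vignette documents the statistical
procedures, the tunable parameters and their defaults, the design of the
synthetic-data generator, and the choices made where the methodology was
genuinely open.

## The study design being modelled

The reference design has seven tillage-cum-crop-establishment scenarios
(`scI` … `scVII`) grouped into three management classes: farmers'
practice (`FP`: scI, scII), partial CA (`pCA`: scIII, scV, scVI) and full
CA (`CA`: scIV, scVII). Soil chemistry and earthworm density come from
three field replicates per scenario; microbiome profiles come from five
DNA replicates per scenario. The generator deliberately exposes both
replicate counts (`nSoilReps = 3`, `nMicrobiomeReps = 5`) rather than
forcing them to agree: the two data streams genuinely have different
replication in designs of this kind, and downstream code never assumes
they match.

## The synthetic-data generator

`simulateSoilTable()` draws every indicator replicate from
Normal(mean, SE·√n): published scenario tables report the standard error
of the mean over n = 3 replicates, so the replicate-level standard
deviation is reconstructed as SE·√n. Chemistry values are truncated at a
floor of 10⁻⁶ of their mean — the study-scale means are orders of
magnitude above zero, so the floor is purely defensive. Earthworm counts
are rounded half-up and clipped at zero.

`simulateOTUTable()` uses a Dirichlet-multinomial model. For each sample
the phylum proportions are drawn Dirichlet(θ·composition); the default
concentration θ = 200 produces between-replicate compositional standard
deviations of roughly √(p(1−p)/201) — about 3 percentage points for a
phylum at 25 % — which is the magnitude of replicate scatter typical for
field amplicon data. Within each phylum, OTU relative abundances follow
a fixed geometric series with ratio 0.7 (configurable); a geometric
profile was chosen over a log-series because it has a closed form, is
trivially normalised, and still produces the singleton/doubleton tails
the richness estimators need. Counts are drawn multinomially at the
requested depth, so row sums equal the depth exactly. The default pool
is 80 OTUs per phylum at depth 60,000.

The default phylum compositions encode the community contrast the design
is about: Proteobacteria (copiotrophic) enriched under CA, Acidobacteria
and Chloroflexi (oligotrophic) enriched under FP, Actinobacteria and
Crenarchaeota higher under full CA, with residual mass lumped as
`Other`. Two anchor values pin the Proteobacteria range (0.233 in scVI,
0.283 in scV); the published narrative also claims every pCA/CA scenario
exceeds FP by 2–13 %, which cannot hold simultaneously with scVI being
the global minimum — the generator keeps the two anchors and places the
FP scenarios slightly below 0.233 so the class contrast is preserved.

What the generator does **not** emulate: sequencing error, chimeras,
read-length effects, spatial correlation between plots, non-normal soil
measurement error, and phylum-soil covariance (soil values and community
composition are drawn independently given the scenario). Passing tests
therefore demonstrate correctness of the estimators and procedures under
a controlled model, not that real data would yield the same magnitudes.

One global seed fans out into per-scenario substreams (the i-th draw of
`sample.int()` under the global seed, in spec order), so a scenario's
data do not change when other scenarios are added or removed.

## Alpha diversity

All estimators are computed from first principles per sample:

* Shannon uses the natural log — index magnitudes near 5 for communities
  of ~1,000 OTUs are consistent with nats, not bits.
* "Simpson" is reported as Gini-Simpson 1 − Σpᵢ², the
  diversity-oriented form (values near 0.98 in this literature imply
  1 − D, not dominance D). The unbiased finite-sample variant
  1 − Σcᵢ(cᵢ−1)/(N(N−1)) is available via `finiteSample = TRUE`; the two
  cannot be distinguished from published tables at typical depths, so
  both are provided.
* Chao1 defaults to the bias-corrected form, which is well defined when
  there are no doubletons; the classic form is a flag.
* ACE uses the standard rare/abundant split at 10. When every rare OTU
  is a singleton the coverage estimate is zero and ACE is undefined; the
  function falls back to Chao1 with a warning.
* Fisher's alpha solves S = α ln(1 + N/α) by bracketed root-finding
  followed by Newton polishing to |f| < 10⁻¹⁰. S = N (all singletons)
  is a divergence error.
* Rarefaction uses the exact hypergeometric expectation computed via
  `lchoose` in log space; subtractive cancellation is not an issue
  because each term is a probability in (0, 1).

Indices are computed on raw counts by default. Rarefying to a common
depth before estimation discards data and is not required for the
estimators to be comparable at near-equal depths; an optional
`rarefyDepth` performs seeded subsampling without replacement for users
who want it.

## Beta diversity

Bray-Curtis is computed on raw counts by default (the generator holds
depth constant, making raw and relative forms equivalent); a
`relative = TRUE` flag divides by sample totals for variable-depth data.
PCoA reports all eigenvalues but builds coordinates and explained
proportions only on positive ones; no Lingoes/Cailliez correction is
applied, since small negative eigenvalues merely reflect the
non-Euclidean part of Bray-Curtis and the standard practice in this
literature is to ignore them. Axis signs are fixed deterministically
(largest-magnitude coordinate positive).

ANOSIM ranks all n(n−1)/2 dissimilarities with average ranks for ties
and uses the (1+k)/(1+B) permutation p-value estimator, which cannot
return zero. Whether to group by the seven scenarios or the three
management classes is a genuine analysis choice; both groupings are
exposed (`grouping` in `pipelineConfig()`), with scenarios as the
default since that matches the experimental unit.

## The soil quality index

The pipeline is: significance screen → correlation PCA → minimum-data-set
selection → PCA weights → non-linear scoring → weighted sum.

* **Screening** keeps indicators whose one-way ANOVA across scenarios
  has p ≤ 0.05. An untestable indicator (zero within-group variance) is
  retained with a warning rather than silently dropped.
* **PCA** is always on the correlation matrix (indicators have wildly
  different units); loadings are eigenvectors scaled by √λ with the
  largest-|loading| variable per PC forced positive. It runs on
  replicate-level observations by default — scenario means would leave
  only 7 observations for up to 11 indicators; a `useScenarioMeans` flag
  exposes the alternative.
* **Selection thresholds** default to: PC eigenvalue ≥ 0.9 explaining
  > 5 % variance; candidate indicators within 10 % of the PC's top
  absolute loading *or* with |loading| ≥ 0.40; redundancy resolved by
  keeping the highest-|loading| member of each cluster of indicators
  correlated at |r| ≥ 0.60 (ties broken lexicographically for
  determinism). The "0.40" rule is read as a loading floor: in the MDS
  literature it is loadings, not eigenvalues, that are compared to 0.40,
  and a 0.40 eigenvalue threshold would be redundant with the 0.9 rule.
* **Weights**: each PC that contributes indicators receives weight
  proportional to its variance share; a PC's weight is split equally
  among its indicators so ΣWᵢ = 1 exactly (a flag gives each indicator
  the full PC weight, renormalised).
* **Scoring** uses S = a/(1 + (x/x₀)^b), a = 1, |b| = 2.5 by default
  with the sign of b set by direction. The baseline x₀ is the
  indicator's grand mean over all observations. Reading x₀ as "the mean
  of the observation's own treatment" would make every treatment-mean
  score exactly 0.5 and the index uninformative, so the grand mean is
  the default and x₀ is user-configurable. The slope magnitude 2.5 is a
  conventional mid-steepness choice (scores 0.15/0.85 at x = x₀/2 and
  2x₀); it is configurable per indicator. EC is the only default
  "less is better" indicator (salinity); the direction map is
  user-configurable.

The index is invariant to row order and scenario relabelling, strictly
increasing in any "more is better" indicator, and bounded in (0, 1).

## Group statistics

Duncan's multiple range test uses studentized-range quantiles
(`stats::qtukey`) at Duncan's protection level αₚ = 1−(1−α)^(p−1) for a
span of p ordered means, critical range Rₚ = q·√(MSE/n). A pair differs
iff its gap exceeds Rₚ and no enclosing span was declared
non-significant. Letters come from the insert-and-absorb compact letter
display, assigned in descending-mean order starting at "a". Unequal
group sizes use the harmonic mean of n with a warning. Note that by
construction the familywise null error of the full k-group span is
1−(1−α)^(k−1), not α — Duncan's test is deliberately liberal, and the
calibration tests assert the behaviour the protection levels imply.
ANOVA, Kruskal-Wallis (tie-corrected) and Pearson tests delegate to the
standard `stats` implementations behind thin validating wrappers;
normality screening is left to the user, who chooses DMRT or
Kruskal-Wallis per variable.

## Community structure

Aggregation sums counts by the chosen rank with empty ranks rendered
`unclassified`; the 1 % "others" lump uses the mean abundance across all
samples (a per-scenario option exists in spirit via subsetting). The
shared-OTU Venn defaults to the most inclusive presence rule — at least
one read in at least one sample of a class — with both the count and the
prevalence thresholds exposed; the partition is exhaustive and disjoint
under every setting. The correlation network is built on per-scenario
mean abundances by default (seven observations, matching the scale on
which phylum-soil correlations are usually reported) and applies no
multiple-testing correction, since raw pairwise significance is what the
source tables in this literature report; a Benjamini-Hochberg flag is
available.

## Numerical and reproducibility choices

* Permutation tests, subsampling and all simulation flow through
  explicit integer seeds; the pipeline writes a JSON manifest with the
  seed and every effective threshold, and repeated runs with one seed
  are byte-identical.
* Eigen-decompositions use `eigen(symmetric = TRUE)`; PCoA eigenvalue
  positivity uses a relative tolerance of 10⁻⁹ of the largest magnitude.
* Degenerate inputs fail loudly: all-zero samples, all-zero
  dissimilarity pairs, constant indicators in PCA, singleton groups in
  ANOSIM, zero within-group variance in ANOVA.
* Test problem sizes were chosen once as the package's own benchmark
  conditions: 100-vector oracle sweeps for the estimators, 5,000-draw
  resampling for rarefaction, 500 null simulations for ANOSIM
  calibration (12 samples, so permutation-distribution discreteness does
  not bias the size estimate), 1,000 nulls for ANOVA/Kruskal-Wallis,
  200 random datasets for the DMRT oracle, 50 seeds for planted-factor
  recovery, and depth-2,000 pipelines for byte-identity checks.

## Limitations

Magnitudes that depend on the real sequencing data — per-scenario
diversity values, the exact ANOSIM R, the published index maximum, the
shared-OTU core size — are not reproducible from summary statistics, and
the package does not pretend otherwise: the simulated study reproduces
the qualitative structure (detectable scenario signal, FP below CA/pCA
on the index, a copiotroph gradient) under its own documented
conditions. Phylogenetic diversity metrics, PERMANOVA/NMDS, heatmap
rendering and network layout are out of scope.
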