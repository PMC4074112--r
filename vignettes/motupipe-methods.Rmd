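---
title: "Methods: fungal ITS1 MOTU pipeline and community analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fungal ITS1 MOTU pipeline and community analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motupipe)
```

`motupipe` re-implements, as tested and reusable functions, the analysis
chain used to characterise leaf- and root-associated fungal assemblages from
ITS1 amplicon sequencing along elevation gradients: reads are clustered into
molecular operational taxonomic units (MOTUs), MOTUs receive a consensus
taxonomy from tabular BLAST hits, low-quality MOTUs are discarded, richness
is estimated by singleton-adjusted rarefaction with a group-redistribution
estimator, and composition is analysed on presence/absence matrices by
correspondence analysis and nested PERMANOVA. A synthetic-data module
simulates the whole study design with known ground truth, so every stage can
be validated end to end without sequencing data.

## The study design being emulated

The sampling hierarchy is three mountain regions with three, five and three
elevation sites respectively and three plots per site — 33 plots, each
yielding one leaf (phyllosphere) and one root sample, 66 samples in total.
Per-sample sequencing depths are drawn uniformly from the observed ranges:
1 506–15 830 sequences for leaf samples and 552–3 622 for root samples.
These are the defaults of `design_spec()`.

`generate_design()` builds the environment table per plot. Within a region,
site elevations span a montane range and mean annual temperature follows a
negative lapse rate (0.005–0.0065 °C/m) from a region-specific sea-level
baseline, so temperature always decreases with elevation within a region.
Precipitation increases with elevation. Soil pH is drawn independently of
elevation — in the field data pH was the one variable uncorrelated with
elevation — and varies mostly between sites with small plot-level jitter.
Carbon, nitrogen and phosphorus covary loosely at the site level.

## The simulated community

`generate_community()` draws a pool of taxa whose phylum composition
follows, by default, the combined-dataset proportions of the beech survey
(Ascomycota 55.4 %, Basidiomycota 31.0 %, Zygomycota 3.2 %, other fungal
lineages 0.3 %, unknown 10.1 %). "Unknown" taxa carry a true phylum in the
ground truth but their taxonomy is withheld from the simulated reference
database; downstream they produce no BLAST hits, which is exactly how
phylum-unknown MOTUs arise in practice. A configurable fraction of
basidiomycete genera (default 0.31 of basidiomycete taxa) is flagged
ectomycorrhizal; EcM taxa are root-restricted, other taxa receive a
Beta(0.7, 0.7) leaf/root affinity, which produces habitat specialists with
some generalists.

Abundances follow a lognormal regional species-abundance distribution
modulated by Gaussian niche responses to mean annual temperature (default
breadth 2 °C) and soil pH (default 0.75 pH units), with independent optima
per taxon. The Gaussian niche is the simplest mechanism that produces the
composition–environment correlation the PERMANOVA stage must detect; a
breadth of 2 °C over a gradient spanning roughly 7–13 °C yields strong but
not trivial turnover. Setting a breadth to `Inf` removes that response
(used for null simulations), and a breadth of 0 makes each taxon a
single-site specialist. Counts are multinomial draws at each sample's depth.

The observed dataset is singleton-rich: 37.8 % of its MOTUs are supported
by a single sequence. The generator treats this fraction as a calibration
target: the lognormal sigma is root-found so that the expected
combined-dataset singleton fraction (under a Poisson approximation of the
pooled counts) matches the target. A pure lognormal saturates below the
target at realistic pool sizes and depths, so when sigma alone cannot reach
it the generator additionally lifts taxa whose expected pooled count falls
below a calibrated floor up to that floor. This rare-tail floor emulates
the trace-level transients and sequencing artefacts that make real amplicon
data singleton-rich; it is reported here as a modelling device, and the
abundance family remains configurable (`singleton_target_fraction = NULL`
uses the lognormal as given).

`generate_sequences()` gives each taxon a random ancestor of 150–300 bp and
emits reads as iid-substituted copies at a configurable divergence (default
0.005, i.e. roughly one substitution per read). Random ancestors are nearly
always mutually dissimilar (< 90 % identity), so distinct taxa are
separable at the 97 % clustering threshold. Flowgram noise, homopolymer
errors, chimeras and adaptor structure are deliberately out of scope, so
passing tests demonstrate correctness of the clustering logic, not
robustness to platform-specific artefacts.

`generate_blast_table()` writes up to ten hits per query. Congruent hits
carry the query taxon's genus (and, for the species-congruent subset, its
species) and its GI number, with identities centred on a per-taxon "true"
reference identity of 98.5–100 %; decoy hits are drawn from pool members of
a *different* genus, so congruence counting is well defined, and are always
valid under the assignment gates (identity 90.5–95 %, e-value below 1e-50)
so that they act as genuine incongruent votes.

## MOTU clustering

Reads shorter than 100 bp are removed (`filter_by_length()`, boundary
inclusive). Clustering (`greedy_cluster()`) is deterministic greedy centroid
clustering at 97 % identity: reads are dereplicated, unique sequences are
processed in decreasing order of copy number with ties broken
lexicographically by the smallest read id, each sequence joins the first
centroid at or above the threshold, and centroids never change. The search
heuristics of the original Uclust step (word filtering, reject counts) are
intentionally not reproduced: the scientifically meaningful content is the
97 % threshold, and an explicitly ordered greedy algorithm makes the
procedure reproducible and exactly testable.

Identity is computed on a global alignment with end gaps penalized
(match +1, mismatch −1, gap column −2) as identical columns over alignment
columns; `N` counts as a mismatch against everything, including itself.
Amplicons of one locus are near-full-length, so a global alignment is the
appropriate comparison; the scoring is stated so that an independent
dynamic-programming oracle reproduces it exactly. The kernel is implemented
in C++ with a deterministic traceback (diagonal, then up, then left), and
arguments are canonically ordered so identity is exactly symmetric.

## Consensus taxonomy

For each MOTU, hits with identity ≤ 90 % or e-value ≥ 1e-50 are discarded
(both inequalities strict, matching the printed thresholds). The genus is
assigned when at least eight remaining hits agree on the genus name, or —
when fewer than eight hits remain — when all of them agree. Species
assignment additionally requires the identity gate: some valid hit must
reach `100 − v` percent identity, where `v` is the phylum's ITS1
intraspecific variability (Ascomycota 2.88, Basidiomycota 4.98,
Chytridiomycota 7.81, Glomeromycota 9.48, Zygomycota 4.13 percent;
`weighted_variability()` recomputes such values from per-species records as
sequence-weighted means). The species name then needs six congruent hits,
or unanimity below six. The source text for the gate reads as "identity
greater than the variability", which taken literally is vacuous (any
identity above a few percent passes); the only reading under which the
variability functions as a similarity cut-off is `identity ≥ 100 − v`, and
that is what is implemented.

Congruence is exact string equality after whitespace trimming — synonym
resolution against nomenclature databases is out of scope. With at most ten
hits, two genera cannot both reach eight votes and two species cannot both
reach six, so ties are impossible at the default gates; a lexicographic
fallback is nevertheless in place in case the gates are reconfigured.

The phylum is a majority vote over *all* hits of the query, with
lexicographic tie-breaking; no identity gate is applied at this rank because
phylum-level information does not require a close match (in the original
procedure even no-hit MOTUs were rescued to phylum level by an additional
manual BLAST). Whether the original analysis gated phylum assignment is not
stated; majority vote is this package's documented choice.

Pipeline order is cluster → assign → merge → filter. `merge_motus()` links
MOTUs sharing an assigned species, or sharing a GI number among hits with
identity strictly above 90 % and e-value strictly below 1e-45, and merges
connected components (union–find), summing counts; the merged MOTU keeps
the most abundant member's identity and the most resolved member
assignment. Filtering after merging matters: singletons are defined on the
merged combined dataset. `apply_filters()` then removes, in order,
non-fungal MOTUs (known non-fungal phylum; phylum-unknown MOTUs are kept),
singletons, and no-hit MOTUs supported by fewer than ten sequences.

## Richness estimation

Before rarefaction one sequence per MOTU is discarded from each sample.
Which sequence is discarded is irrelevant at the count level, so
`discard_one_per_motu()` decrements every positive count deterministically —
count-equivalent to the random removal described originally, without seed
dependence.

`rarefied_richness()` evaluates the analytic expectation
`E[S] = Σ_m (1 − C(N−N_m, d)/C(N, d))` with binomial coefficients in log
space; `rarefy_counts()` draws the corresponding multivariate hypergeometric
subsample (via `vegan::rrarefy`, seeded). Default depths are 1 400 (leaf)
and 500 (root) sequences, the lowest depths available per habitat in the
study.

The group estimator assumes the share of a group among phylum-unknown MOTUs
equals its share among assigned MOTUs:
`R_ij = (N_ij / N_assigned) × ER_j`. Group proportions are computed on the
unrarefied post-filter sample while `ER_j` is computed on the adjusted,
rarefied sample — proportions are better estimated at full depth. Whether
the original analysis computed proportions before or after rarefaction is
not stated; this is the package's documented interpretation, and simulation
tests show the pooled mean estimate recovers the ground-truth expectation to
within a few percent at pool 2 000 and depth 500. By construction
`Σ_i R_ij = ER_j` exactly whenever the groups partition the assigned MOTUs.
`shannon_diversity()` uses natural logarithms (the base was not stated
originally; nats are the vegan default).

## Composition analysis

`prepare_composition()` rarefies every sample to a common depth, binarizes,
and drops MOTUs present in fewer than three plots, which would otherwise
distort the ordination. Correspondence analysis (`coa()`) decomposes the
standardized residuals `D_r^{-1/2}(P − r cᵀ)D_c^{-1/2}` by SVD; eigenvalues
are squared singular values (bounded by 1, with 1 indicating a disconnected
block structure), rows are reported in principal coordinates and columns in
standard coordinates. Scaling conventions differ between CA
implementations; this one is fixed and documented, and eigenvalues agree
with other implementations regardless of scaling.

The dissimilarity underlying the PERMANOVA was not named in the original
analysis; on presence/absence data the default Bray–Curtis of `adonis`
reduces to the Sørensen index `1 − 2a/(2a + b + c)`, which is what
`sorensen_dissimilarity()` computes (configurable by supplying any other
`dist` to the test).

`permanova_nested()` implements the permutational MANOVA directly: squared
distances are Gower-centered, sums of squares are partitioned sequentially
(Type I) in the printed term order — region, soil pH, temperature,
site-within-region — and pseudo-F statistics are referenced to permutations
of the distance matrix restricted to within-region (strata) exchanges. With
the 33-plot design this yields the degrees of freedom 2/1/1/7 with 21
residual. P-values use `(1 + #{F* ≥ F})/(1 + n_perm)` with a default of 999
random permutations, or exact enumeration of the within-strata permutation
group (`complete = TRUE`) when it is small; the permutation stream is
seeded, so p-values are reproducible. Note that a term constant within
strata (region itself) has a degenerate permutation distribution under
restricted permutation — its p-value is reported but should be read with
that caveat, as with any strata-restricted `adonis` fit.

Environmental screening mirrors the original workflow: `pearson_table()`
(pairwise tests on n − 2 degrees of freedom), `env_pca()` (PCA of
standardized variables with per-variable axis contributions), and
`quadratic_trend()` (least-squares `richness ~ T + T²` with a t-test on the
quadratic term and peak location `−b₁/(2b₂)`), used to describe the
mid-temperature richness peak of ascomycetes. The published PCA axis
percentages depend on whether plot-level or site-averaged covariates were
used, which is not recoverable from the printed tables, so they are not
treated as reproducible quantities here.

## Numerical and testing choices

Degenerate inputs are rejected with informative errors: empty sequences,
depths exceeding sample totals (naming the sample), zero-margin rows or
columns in CA, zero assigned MOTUs in the group estimator, constant columns
in the PCA. CA axes with singular values below `1e-9` of the leading one
are dropped. Enumeration of within-strata permutations refuses above
2 × 10⁵ permutations.

The validation suite uses problem sizes chosen to exercise the statistics
without waste: estimator recovery at pool 2 000 and depth 500 over 20
seeds; PERMANOVA calibration over 1 000 null simulations (iid communities,
niche breadths `Inf`) at 199 permutations, where the type-I rate at
α = 0.05 must fall in [0.03, 0.07]; power against niche-driven turnover
over 100 simulations at 33 samples; Monte-Carlo rarefaction checks at 10⁴
draws on 50 random fixtures within three standard errors. Exact arithmetic
(summary percentages, hypergeometric fixtures, enumeration p-values,
chi-square inertia) is asserted at printed precision or 1e-9.

## Limitations

The generator does not simulate platform error profiles, chimeras, primer
or length biases, copy-number variation of the rDNA operon, or phylogenetic
structure among taxa; sequences are random ancestors, so clustering
difficulty (taxa near the 97 % boundary) is under-represented relative to
real ITS1 data. Taxonomic noise is parametric and symmetric, unlike curated
reference databases. The linear mixed models fitted downstream of the
richness table in the original study are out of scope — `richness_table()`
exports exactly the per-plot table such models consume.
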