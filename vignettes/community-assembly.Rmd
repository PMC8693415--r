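---
title: "Quantifying stochastic and deterministic community assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stochastic and deterministic community assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Microbial communities are shaped by a mixture of deterministic processes
(selection by the environment acting on organismal traits) and stochastic
ones (ecological drift, random dispersal). `gutassembly` implements the
null-model toolkit that microbial ecologists use to weigh these forces
from three inputs: an OTU count table (samples x taxa), a rooted
phylogeny with branch lengths covering the taxa, and sample metadata
(e.g. gut region and diet group for a feeding trial with several animals
per group). The motivating design is a 2 gut-region x 4 diet-group x 6
animal study, but nothing in the package depends on that layout.

## The statistics

**Phylogenetic turnover.** For a single community, MNTD is the
(abundance-weighted) mean distance from each taxon to its nearest
phylogenetic neighbour in the same community; between two communities,
betaMNTD takes each taxon's nearest neighbour *in the other* community.
Both are compared against a tip-shuffle null — taxon labels are permuted
across all tips of the tree, so each sample keeps its richness and
abundances and only the taxon-tip mapping changes — giving the z-scores

* NTI = (mean(MNTD~null~) − MNTD~obs~) / sd(MNTD~null~), signed so that
  positive values mean phylogenetic clustering;
* betaNTI = (betaMNTD~obs~ − mean(betaMNTD~null~)) / sd(betaMNTD~null~).

A pair with betaNTI < −2 is read as homogeneous selection (less
phylogenetic turnover than chance), betaNTI > +2 as variable selection.
The same tip permutation is reused for every pair within one null
repetition, and z-scores use the n−1 sample standard deviation. Pairs
whose null distribution is degenerate (sd = 0, e.g. two identical
samples, which remain identical under every shuffle) are flagged
undefined rather than scored.

**Compositional null deviation.** For pairs with |betaNTI| ≤ 2 the
Raup–Crick deviation on Bray–Curtis distances asks whether the pair is
more or less dissimilar than expected under stochastic assembly. The
null community generator preserves each sample's richness and total
abundance exactly: it draws richness-many taxa without replacement with
probability proportional to occupancy frequency in the sample pool,
seats one individual per drawn taxon, and fills the remaining total by a
multinomial draw with probabilities proportional to pool relative
abundance. RC = 2[(# null pairs less dissimilar than observed) + ½(#
ties)]/reps − 1 lies in [−1, +1]; RC > +0.95 is dispersal limitation,
RC < −0.95 homogenizing dispersal, and the remainder drift. The
weighted draw without replacement uses the exponential-keys
construction, which is distribution-identical to sequential weighted
sampling but vectorized.

**Five-process partition.** `partition_processes()` applies the decision
tree exactly in that order — selection first, RC only when |betaNTI| ≤ 2
— and reports per-pair labels and the label fractions. Boundary values
(betaNTI = ±2, RC = ±0.95) fall to drift; pairs with undefined betaNTI
are excluded and counted.

**Normalized stochasticity ratio.** For every within-group pair, the
observed dissimilarity D is compared with the null expectation E (the
mean dissimilarity of null community pairs from the same generator): the
pair ratio is D/E when D ≤ E and (1−D)/(1−E) otherwise, and the group
NST is 100 x the mean ratio. Values above 50% indicate stochastic
dominance. Pairs with E exactly 0 or 1 are degenerate and excluded. The
divergent-case normalization (1−D)/(1−E) keeps the ratio in [0, 1] on
both sides of the null expectation, so convergence (selection pulling
communities together) and constrained divergence both register as
determinism.

**Null pools.** The occupancy/abundance pools behind RC and NST are
computed from the sample set the caller passes (`pool =`). For a survey
of one region the region's samples are the natural pool; for a
designed contrast between habitats the full metacommunity is, because a
per-habitat pool conditions the null on the very selection outcome under
test and drives NST toward 100% regardless of regime. `nst()` defaults
to the group itself; `community_assembly()` defaults to all samples.

**Supporting statistics.** Shannon (nats) and Gini–Simpson delegate to
vegan; Faith's PD is the rooted subtree branch-length sum. Bray–Curtis
and Jaccard (presence/absence) matrices come from `vegan::vegdist`.
PCoA is classical scaling of the double-centred −D²/2 with negative
eigenvalues reported but excluded from coordinates. PERMANOVA, MRPP and
PERMDISP delegate to vegan (`adonis2`, `mrpp`,
`betadisper`+`permutest`); PERMDISP uses centroids in PCoA space and
permutes raw group labels. The null-model dispersion test pools the
observed samples with RC-null replicas of each and runs PERMDISP on the
observed/null labelling. Co-occurrence networks use Spearman
correlations with average ranks, a strict |rho| > 0.5 edge rule, no
multiple-testing filter, and metrics on the unsigned skeleton.
Group comparisons (Kruskal–Wallis, rank-sum, two-way ANOVA with
interaction) delegate to stats.

## The synthetic generator

Validating assembly inference requires data whose true regime is known.
`simulate_communities()` builds a regional pool — a birth–death
phylogeny (`ape::rphylo`), a Brownian niche trait (variance = rate x
branch length), and lognormal regional abundances — and assembles each
sample in three steps:

1. **selection**: per-taxon weight pool~t~ · exp(−s (trait~t~ −
   optimum~g~)²) for the sample's group g;
2. **dispersal**: the weight vector is mixed with the unfiltered pool in
   proportion to the immigration rate m (`dispersal_rate`), so m = 1 is
   mass effects;
3. **drift**: the realized composition is a Dirichlet draw around the
   weights with concentration m(J−1)/(1−m) — the immigration–drift
   equilibrium of a neutral local community of size J — followed by a
   multinomial draw of J individuals.

With s = 0 this is the pure neutral model; with m = 1 the Dirichlet
step degenerates and sampling is exactly multinomial from the weights.
An early design without the drift step proved unable to express
homogeneous selection at all: samples of a group were iid multinomials
from identical weights, so within-group turnover was confined to the
rare tail and mean within-group betaNTI never fell below about −1 at
any selection strength or community size.

### Canonical regimes

`assembly_regime()` freezes the two reference conditions used by the
package's validation and acceptance script.

The **neutral** regime mirrors the motivating study design: 48 samples
(2 regions x 4 diet groups x 6 animals), 300 taxa, 10,000 individuals
per sample, m = 0.3 (a literature-typical immigration estimate for gut
microbiota under Sloan's neutral model), lognormal pool with sdlog 1.5,
selection 0 everywhere.

The **deterministic** regime is a two-habitat filtering contrast whose
geometry is dictated by how nearest-taxon statistics behave:

* the filter kernel width is 0.2 trait SD. Much sharper kernels select
  phylogenetically near-random tips (sister taxa already differ by about
  one within-branch SD under Brownian motion), much broader ones select
  weakly clustered halves of the tree;
* the pool is large and sparsely sampled (3,000 taxa, per-sample
  richness near 130). Nearest-taxon contrasts saturate once richness x
  clade size approaches the pool size, because even a tip-shuffled
  partner community then offers a same-clade neighbour by chance;
* habitat optima sit at ±2 trait SD, so the two filters select disjoint
  clade sets (between-habitat betaNTI is strongly positive — variable
  selection — while within-habitat betaNTI is strongly negative);
* drift is strong (m = 0.001, J = 3x10⁵, concentration ≈ 300) so that
  taxon turnover *within the selected clades* carries the
  homogeneous-selection signal, and the regional abundance distribution
  is steep (sdlog 2) so that observed Bray–Curtis is anchored by a few
  stable dominants and NST registers determinism.

Because the two habitats share one regional pool, their separate NST
values are strongly anti-correlated (whichever habitat dominates the
pooled abundance vector receives the lower null expectation), so
regime-level summaries pool the within-group pair ratios of both
habitats, exactly as the mean within-group betaNTI pools both habitats'
pairs.

### What the generator does not emulate

No 16S copy-number variation, chimeras, sequencing noise, or
compositional artefacts of library size; communities are exchangeable
within groups, whereas real animals contribute individual effects.
Passing validation on these simulations therefore shows the statistics
recover known regimes under the model's assumptions — conserved traits,
Gaussian niches, a single shared pool — not that any real dataset meets
those assumptions.

## Numerical choices and degenerate inputs

* Null repetitions default to 999 (betaNTI, RC) and 1000 (NST); the
  validation suite uses 60–200 so the full battery runs on a laptop in
  minutes. z-scores need at least ~100 repetitions to be stable.
* Seeds are explicit everywhere; per-pair substreams are derived
  symmetrically from the master seed, so RC(i, j) = RC(j, i) exactly
  and results are bit-reproducible.
* All-zero samples, taxa missing from the tree, duplicate identifiers
  and undersized groups fail with the offending name; phylogenetic
  operations never prune silently (`prune_to_tree()` is explicit).
* Tip-shuffle nulls with sd = 0 yield flagged NA, not ±Inf.
* Ties: top-N taxa and network hubs break ties lexicographically;
  Spearman uses average ranks; RC counts ties as ½.
* Patristic distances are computed once into a dense tip-distance
  matrix, acceptable to a few thousand tips.
* No rarefaction by default; `rarefy_table()` exists for sensitivity
  analysis.

## Design choices on open points

* "Most abundant" taxa are ranked by mean relative abundance across the
  selected samples, the convention behind top-N composition figures.
* Shannon uses natural logarithms; Simpson is the Gini–Simpson form;
  Faith's PD includes the root path; Jaccard is presence/absence — the
  standard abundance/incidence pairing.
* The paper-shaped pipeline treats the phylogeny as an input; how a
  tree was built upstream (e.g. from representative 16S sequences) is
  out of scope.
* The betaNTI null shuffles labels across all tree tips (the
  "taxa.labels" scheme); abundance weighting is on by default.
* One null-community generator (the RC construction) serves RC, NST and
  the dispersion test, so all compositional nulls are mutually
  consistent.
* Two-way ANOVA includes the interaction term.

## Limitations

Homogeneous selection is intrinsically hard to detect with weighted
nearest-taxon statistics when communities share most of their taxa:
shared taxa contribute zero distance under both the observed and the
shuffled mapping, so the z-score is carried entirely by non-shared
abundance mass. Designs with little within-group turnover (tightly
coupled communities, very large immigration) will show betaNTI near 0
even under strong selection; NST and the RC partition are the more
sensitive instruments there. Conversely NST depends on the null pool
choice, as described above. The acceptance machinery reports both views.
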