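---
title: "Methods: trait spaces, hull-based diversity and null models in fespace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait spaces, hull-based diversity and null models in fespace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fespace)
```

`fespace` quantifies how an environmental gradient erodes the functional
structure of a benthic community: which combinations of life-history traits
survive, how much of the community's trait space is lost, and whether the
loss is selective (environmental filtering) or a random consequence of
losing species. This vignette explains the model choices, the tunable
parameters, and the limits of what the bundled synthetic data can show.

## From species to functional entities

The unit of analysis is the *functional entity* (FE): a group of species
with an identical vector of categorical trait values. The package ships a
benthic schema of 15 traits and 73 categories (morphological form,
solitary–colonial life history, maximum longevity, height, width,
epibiosis, energetic resource, photosynthetic pigments, feeding, age at
reproductive maturity, asexual reproduction, growth rate, calcification,
chemical defenses, mobility). Trait kinds follow the nature of the codes:
numbered scale codes (longevity, height, width, age at maturity, growth
rate, solitary–colonial) are ordinal; lettered codes are nominal; yes/no
traits are binary. Schemas are YAML, so any of this is overridable.

Missing trait values are rejected rather than imputed: FE membership is
exact vector equality, and an imputed value would silently create or merge
entities. Intraspecific trait variability is out of scope — each species is
one vector.

## The functional space

Pairwise FE dissimilarity is the Gower distance: the unweighted mean over
traits of per-trait dissimilarities, so every trait counts equally and the
result lies in [0, 1]. Nominal and binary traits contribute 0/1. For
ordinal traits the package defaults to plain range-scaled ranks — category
positions in the declared order, scaled by the range *observed in the
table* — which is the simplest defensible reading of "Gower distance with
ordered categories". Podani's tied-rank correction and a nominal fallback
are available (`gower_dist(..., ordinal =)`) because the literature is
genuinely split; on the bundled data the choice moves distances by at most
a few percent. A trait with a single observed ordinal category has no
usable range and contributes 0 while remaining in the denominator.

The distance matrix is embedded by classical scaling (PCoA). Axes with
positive eigenvalues are retained with coordinates scaled by the square
root of the eigenvalue; negative-eigenvalue axes (the non-Euclidean
residual that Gower distances generally produce) are dropped and their
total magnitude is reported rather than corrected — a Cailliez or Lingoes
correction would change all distances to repair axes the analysis never
uses. The default dimensionality is `d = 4`, balancing embedding quality
against the cost and robustness of hull geometry in higher dimensions.
Quality is summarised by the mean squared deviation (mSD) between the
original and the embedded distances, both rescaled to [0, 1] by their own
maxima before comparison (so mSD is scale-free; a perfect embedding gives
exactly 0). mSD is non-increasing as axes are added, which the test suite
checks as a property.

The space is built on FEs, not species: members of an FE are identical by
construction, so species-level and FE-level Gower agree and the FE-level
embedding is simply smaller.

## Hull-based richness and β-diversity

Functional richness of an assemblage is the volume of the convex hull
around its occupied FEs, expressed as a percentage of the global pool's
hull volume. The hull is computed exactly by a compiled randomized
incremental (beneath-beyond) algorithm that also returns the facet
half-space representation. Numerical safeguards, in order: a visibility
threshold of 1e-9 times the coordinate span; an explicit consistency check
that every input point satisfies every facet inequality; and, on failure
(typically exactly coplanar inputs), a deterministic seeded joggle of
magnitude 1e-9 times the span with up to five retries. Assemblages with
fewer than `d + 1` affinely independent FEs are *degenerate*: they get
volume 0, not a reduced-dimension volume, because a 3D volume is not
commensurable with a 4D one and percentage shares of the pool must stay
comparable across zones.

Functional β-diversity needs the volume shared by two hulls. The exact
intersection is the polytope satisfying both hulls' facet inequalities: a
strictly interior point is found by maximizing the minimal slack (a
log-sum-exp smoothed minimax minimized by BFGS at decreasing temperature —
the smooth convex analogue of the usual phase-one LP), the half-spaces are
dualized about it, the dual hull's facets are mapped back to primal
vertices, and the vertex hull's volume is the intersection volume. If no
interior point with slack above 1e-8 of the span exists the hulls overlap
at most in a lower-dimensional set and the shared volume is 0. A
Monte-Carlo mode (rejection sampling in the overlap of the bounding boxes,
with a standard error) serves as fallback and cross-check; the suite
verifies exact-vs-MC agreement on random hull pairs and the analytic
overlap of offset squares.

Both taxonomic and functional β use the additive Jaccard partition
(total = turnover + nestedness-resultant), with species counts or
hypervolumes as the shared/unique magnitudes. Reported percentages follow
the field convention of printing functional β ×100 while taxonomic
components stay proportions; JSON reports always store proportions.
`nested_fraction()` — the share of one assemblage's hull volume contained
in another's — is provided separately because "X% of zone A's richness is
nested in zone B" is a volume ratio, not a β component.

## Null models

The null hypothesis is that species are randomly assigned to FEs, keeping
the zone's species count and FE count fixed, each FE getting at least one
species. Hull volume depends only on *which* FEs are occupied, so the null
reduces to drawing the occupied FE set uniformly from the pool; the
package implements that reduction for speed but retains the species-level
surjection sampler (`method = "assignment"`), and the suite checks the two
induce the same occupied-set law. Significance is bilateral:
`p = min(1, 2·min(P(null ≤ obs), P(null ≥ obs)))` with the add-one
`(r+1)/(n+1)` correction, so p can never be exactly zero and is bounded
below by `2/(n_sim+1)`. The default `n_sim = 9999`; the suite calibrates
the test at a reduced `n_sim = 999` over 1000 replicate true-null datasets
and finds the 5% level held within Monte-Carlo error. Tail counts use a
relative tolerance of 1e-9 because recomputing the volume of the same FE
set in a different insertion order jitters at floating-point level.

## Redundancy and vulnerability

Redundancy of an FE is the number of species (and their summed relative
cover) belonging to occupied FEs within a fixed radius of it in the
functional space; vulnerability is the proportion of occupied FEs whose
neighbourhood holds a single species. The radius is `k_frac = 0.01` (1%)
of the maximum FE–FE distance *of the global pool*, not of the zone — the
pool normalizer keeps radii comparable across zones, which the phrase
"maximum distance between FEs in the functional space" leaves ambiguous.
The boundary is inclusive; at 1% this matters only for exactly coincident
FEs. Cover within the radius is normalised by the zone's total cover so
profiles are comparable across zones. Profiles at 0.5% and 5% radii
rank-correlate strongly with the 1% profile on the bundled data (a suite
check), so conclusions are not an artefact of the radius.

Two "mean species per FE" statistics are offered and deliberately kept
apart: `naive` (species count over FE count) and `radius` (mean
neighbourhood species count). They answer different questions and can
differ by an order of magnitude when FEs are co-located; neither is
claimed to be the other's substitute.

## The synthetic data, and what it can and cannot show

The generator emulates the statistical structure the analysis assumes,
not the biology of any real reef:

* **Pools** are drawn around four benthic trait syndromes (calcified
  heterotrophic massive long-lived forms; calcified autotrophs; fleshy
  erect seasonal algae; small encrusting/turf forms), because in real
  pools calcification, trophy, longevity and stature covary. Each species
  copies a syndrome and mutates traits independently (defaults 0.2 per
  trait; 0.45 for the turf syndrome, which is naturally the most
  heterogeneous), with the syndrome-defining quartet — energetic resource,
  feeding, calcification, mobility — frozen. Without syndrome structure,
  category-targeted filtering cannot deplete a coherent region of trait
  space and no method could (or should) detect filtering.
* **Filtering** removes species carrying listed trait categories with
  stated probabilities; rules combine independently. When a zone has a
  target richness, exactly that many species survive, removed by
  filter-odds-weighted sampling without replacement — the survivors are
  the filter-passing set, and a zone with no rules (the ambient control)
  removes uniformly, i.e. is a true null sample of the pool.
* **Covers** are Dirichlet draws per quadrat scaled to a total around 90%
  (totals are not forced to 100% — canopy layers overlap), with a 0.01%
  detection floor; lower concentration packs cover into fewer entities,
  emulating the dominance shift of heavily filtered zones. Trait-vector
  duplicates (multi-species FEs) are placed in the filtered syndromes, so
  the gradient erodes redundancy as well as richness.
* The deterministic fixture (`benthic_gradient_fixture()`) fixes the
  survey shape — 72 species in 68 FEs (two FEs of three species), zones of
  55/45/22 species in 51/42/21 FEs over 2 sites × 12 quadrats × 3 zones,
  an extreme-low zone of exclusively non-calcified photosynthetic
  autotrophs — so printed-count arithmetic and end-to-end behaviour are
  reproducible to the byte.

Passing tests on these data show the *pipeline* is correct and that
planted filtering of the stated strength is recovered (the suite uses 100
replicate gradients with 999-simulation null models, and 1000 replicates
for the type-I calibration — sizes chosen to make Monte-Carlo error small
relative to the tested margins). They do not show that any real gradient
filters traits, nor validate the trait assignments of a real species list;
with field tables the package's conclusions inherit whatever uncertainty
those trait codings carry. Surveys from different years are treated as
independent quadrats (concatenated, not averaged), and sites are pooled
within zones — per-site analyses are possible by filtering the survey
table, but no site-effect model is fitted.

## Reporting conventions and other numerical choices

* Printed pool percentages round to the nearest integer with base R's
  round-half-to-even; full precision is kept internally and in JSON.
* Eigenvalues are considered positive above `max(eigenvalue) × 1e-9`.
* FE identifiers are deterministic (lexicographic trait vector, then first
  member name), so reruns and tests are stable under row permutation.
* Every stochastic step consumes the caller's RNG stream; pipeline runs
  record their seed in every report and rerun byte-identically.

## Known limitations

* Exact hull intersection assumes both hulls are full-dimensional; two
  degenerate (flat) assemblages overlapping in a lower-dimensional set
  report shared volume 0 by design.
* Convex hulls measure range, not occupancy density: a single outlying FE
  can dominate the volume. The abundance-weighted redundancy profile is
  the counterweight, not a fix.
* The Gower/PCoA space drops some non-Euclidean structure (reported as
  negative-eigenvalue mass); strongly non-Euclidean trait sets deserve a
  check of that mass before trusting 4 axes.
* Sørensen-family β-partitions and multi-assemblage β are not implemented;
  the Jaccard family is the one used throughout.
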