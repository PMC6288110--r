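# fespace

Trait-based functional diversity analysis for benthic communities surveyed
along environmental gradients — built for the kind of study where per-cent
cover of algae and invertebrates is scored in quadrats across zones of an
environmental gradient (for example the ambient / low / extreme-low pH zones
of natural CO₂ vent systems) and the question is how much *function*, not
just how many species, the gradient removes.

It is aimed at community ecologists who work with categorical life-history
traits and want the full pipeline — functional entities, ordination-based
trait spaces, convex-hull richness, β-diversity partitioning, null models
and redundancy — as tested, scriptable R functions.

## The approach

1. **Functional entities (FEs).** Species are described by a schema of
   categorical traits (a bundled benthic schema has 15 traits with 73
   categories: morphology, longevity, size, trophy, calcification, ...).
   Species with identical trait vectors collapse into one FE.
2. **Functional space.** Gower distances among FE trait vectors (nominal
   traits contribute 0/1, ordinal traits range-scaled rank differences,
   equal weights) are embedded by principal coordinates analysis; the
   first 4 axes are kept and the embedding quality is summarised by the
   mean squared deviation (mSD) between rescaled original and embedded
   distances.
3. **Functional richness.** The volume of the convex hull around an
   assemblage's FEs, expressed as a percentage of the global pool's hull
   volume. Hulls and their exact intersections are computed in arbitrary
   dimension by a compiled beneath-beyond algorithm (no external geometry
   library required).
4. **β-diversity.** Jaccard dissimilarity partitioned additively into
   turnover and nestedness-resultant components
   (β_jac = (b+c)/(a+b+c), β_jtu = 2·min(b,c)/(a+2·min(b,c)),
   β_jne = β_jac − β_jtu), computed on species sets (taxonomic) and on
   hull hypervolumes with exact hull–hull intersections (functional).
5. **Null models.** Observed functional richness is compared with 9999
   random assemblages keeping species and FE counts fixed (random
   species-to-FE assignment), with a bilateral test at α = 5%.
6. **Redundancy and vulnerability.** For each FE, the number of species
   (and their cover) within a radius of 1% of the maximum FE–FE distance;
   vulnerability is the proportion of FEs supported by a single species.
7. **Sensitivity.** Every trait carries a coarse (2–4 category) recoding;
   the whole analysis can be rerun on the coarsened FEs.

A seeded synthetic-data module generates species pools around benthic
trait syndromes and surveys them under configurable trait-targeted
filtering, so the entire pipeline is testable without any field data; a
deterministic fixture mirrors the survey structure of a 72-species vent
gradient (68 FEs, zone richness 55/45/22).

## Worked example

```r
library(fespace)

fx    <- benthic_gradient_fixture()          # deterministic synthetic survey
space <- build_space(fx$traits, fx$schema, d = 4)
space
#> Functional space: 68 entities on 4 PCoA axes
#>   mSD = 0.008551 | dropped negative-eigenvalue mass = 3.6

asm <- aggregate_zones(fx$surveys)
richness_summary(space, asm, nrow(fx$traits))
#>          zone n_species n_fes pct_species pct_fes hull_volume pct_volume
#> 1     ambient        55    51          76      75     0.02001      89.32
#> 2         low        45    42          62      62     0.01381      61.66
#> 3 extreme_low        22    21          31      31     0.00105       4.67
```

The extreme-low zone keeps 31% of the species and 31% of the FEs but only
4.7% of the pool's functional-space volume — functional loss far exceeds
taxonomic loss. The null model asks whether that could arise from randomly
assigning species to FEs:

```r
set.seed(42)
null_functional_richness(space, occupied_fes(asm$extreme_low, space$partition),
                         zone_n_species = 22, n_sim = 9999)
#> Null functional richness (occupancy, 9999 simulations):
#>   observed 4.67% | null 42.76% +/- 8.62 | SES -4.42 | two-sided p = 0.0002
```

so the filtered zone sits far below the null — environmental filtering of
trait values, not chance. Redundancy and functional β-diversity follow the
same pattern:

```r
redundancy_profile(space, space$partition, asm$extreme_low)
#> Redundancy profile (zone 'extreme_low', k = 1% -> radius 0.008047):
#>   21 occupied FEs | mean species within radius 1.05 | vulnerability 0.952

functional_beta(space, occupied_fes(asm$ambient, space$partition),
                occupied_fes(asm$extreme_low, space$partition))
#> functional beta-diversity (exact): total 0.951 = turnover 0.122 + nestedness 0.829
```

`run_pipeline(run_config(...))` sequences all of the above (plus the
coarse-schema sensitivity rerun) and writes JSON/TSV reports; a thin
command-line front end lives at `inst/cli/fdgradient.R` with `run`,
`simulate`, `space`, `beta`, `nullmodel` and `redundancy` subcommands.

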