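# fisheggs

Identification of drifting fish eggs and larvae from COI DNA barcodes,
and inference of spawning phenology from the identified egg pool.

Rivers carry the eggs of whatever is spawning upstream, but an egg has
almost no diagnostic morphology. Sequencing the standard COI barcode from
each egg and comparing it against a reference library recovers the
species — if the comparison rules are explicit. `fisheggs` packages the
full decision pipeline used in drifting-egg barcoding surveys for anyone
who needs it reproducible: fisheries ecologists summarising a season of
ichthyoplankton samples, and methodologists who want every threshold and
tie-break testable.

## What it computes

**Assignment cascade.** Each query is ranked against every reference by
percent identity (matches over compared columns of an ends-free affine-gap
alignment; gap and ambiguity columns excluded). With best and second-best
identities taken per species, the cascade applies in order: species when
best > 99% and runner-up species < 99%; genus when both clear 99% within
one genus; species when the top-100 hits agree (best still > 99%); then
the fallback tier — species on top-five consensus above 99%, genus above
the 95% floor (majority of the top five), otherwise unidentified. A
declarative exclusion list handles species ruled out on ecological
grounds: their hits are removed and the cascade re-runs once.

**Verification by distance.** Kimura two-parameter distances
(`d = -½ ln[(1−2P−Q)√(1−2Q)]`, transitions *P* and transversions *Q* over
pairwise-deleted sites), neighbor-joining trees with column-bootstrap
supports, and single-linkage lineage delimitation at the 1% boundary —
the tree-side cross-check that each assigned species is one coherent
cluster.

**Phenology.** Taxon-by-month occurrence tables in the familiar
community-table layout, monthly richness, spawning-period spans with
continuity, family composition and sequencing success/failure accounting.

**Survey simulator.** Generates reference libraries and egg surveys with
a configurable barcoding gap, species-specific spawning windows,
off-library taxa and amplification dropout, plus a truth table — so the
whole pipeline is testable against known answers.

## Worked example

Simulate a six-species survey with the default 38% dropout, assign every
egg, and summarise the season:

```r
library(fisheggs)

p   <- simulation_params(n_species = 6, individuals_per_species = 2,
                         monthly_sampling = 10, dropout_rate = 0.38,
                         seed = 7)
ref <- simulate_reference(p)
sv  <- simulate_survey(ref)
res <- assign_batch(sv$sequences, ref$library, run_config(),
                    metadata = sv$metadata)
res
#> Barcode assignments: 92 queries (90 species-level, 0 genus-level, 2 unidentified)

occurrence_matrix(res, months = p$months)
#> Occurrence matrix: 7 taxa x 5 months
#>  Family  Taxon             May June July August September
#>  Family3 Genus3 sp1        +   +
#>  Family1 Genus1 sp1            +    +    +      +
#>  Family1 Genus1 sp2            +    +    +
#>          Unknown species 1     +                +
#>  Family3 Genus3 sp2            +
#>  Family2 Genus2 sp1                 +    +      +
#>  Family2 Genus2 sp2                 +    +
#>          Total             1   5    4    4      3
```

Of the ~150 simulated eggs, 92 survived dropout; every in-library egg was
assigned to its true species, and the two eggs drawn from an off-library
taxon surfaced as an unknown lineage rather than a wrong name. The
package also ships the community table of a published May–September
survey as a plain-text fixture:

```r
fx <- egg_community_fixture()
monthly_richness(fx$occurrence)
#>       May      June      July    August September
#>         7        11         9        10         1

composition_summary(fx$taxa, fx$counts)
#> Selected eggs 641; high quality 397 eggs + 17 larvae; failed 244 (38.1%)
#> Eggs assigned to species: 392 (98.7%)
#> Species-level taxa: 14
#> Family composition:
#>   Cyprinidae         10 (71.4%)
#>   Botiidae            2 (14.3%)
#>   Mastacembelidae     1 (7.1%)
#>   Serranidae          1 (7.1%)
```

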