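# fledgemove

Movement-mode classification and trajectory statistics for juvenile seabird
tracking data.

## The scientific problem

Juvenile albatrosses and petrels disperse from their natal colony once,
unaccompanied, and stay at sea for months to years. Tracking devices record
where they go; the question is *what strategy* the trajectory expresses. Five
canonical modes recur across species: staying within a **home range**,
**nomadic** wandering across ocean basins, **half-migration** (a directed
outward trip ending in settlement in a distant water mass), full **migration**
(outward trip and return), and **large-scale looping** (repeated
multi-thousand-kilometre circuits past the colony). `fledgemove` classifies
tracks into these modes, summarises trajectories over 15-day periods
(daily distance travelled, sinuosity, bearings, latitude), annotates habitat
from bathymetry/SST/chlorophyll grids, and compares groups with mixed models
and exact rank-sum tests.

## The model

The classification variable is net squared displacement (NSD): squared
great-circle distance from the colony as a function of days since departure.
Four parametric curves — asymptotic (home range), linear (nomad), logistic
(half-migration) and double-logistic (migration) — are fitted by
Levenberg–Marquardt least squares; the winner is the model with the highest
Lin's concordance between observed and fitted NSD, subject to a biological
plausibility screen (settlement must be observed within the track, fitted
plateaus must be flat in the data, scales must not exceed what the trajectory
covers). Looping defeats any displacement model, so it is detected
geometrically instead: a periodic NSD combined with directionally consistent
winding of the colony-to-bird bearing (net sweep ≥ π with at least half the
total sweep in one rotational sense). For circumpolar birds, displacement is
unwrapped across the antimeridian before fitting, since great-circle distance
saturates at half the Earth's circumference and would otherwise make a
steadily eastward nomad look like a returning migrant.

A seeded trajectory simulator produces all five phenotypes with realistic
deployment artefacts — duty-cycled transmission (about 0.7 fixes per day) and
Argos- or geolocator-scale positional noise — and is the validation harness
for the classifier.

## Worked example

```r
library(fledgemove)

# a 180-day juvenile that disperses ~4000 km and settles
track <- simulate_track(default_sim_config("half_migration", seed = 3))
cls <- classify_movement(track, seed = 1)

cls$movement_type
#> [1] "half_migration"

round(cls$cc, 3)
#>     home_range          nomad half_migration      migration
#>          0.902          0.586          0.983           -Inf

unlist(cls$params)
#>        delta        theta          phi
#> 1.556771e+07 1.009219e+01 1.986650e+00
```

The logistic model wins with concordance 0.983 (the migration fit is rejected
as implausible, hence `-Inf`). The fitted asymptote `delta` implies a
settlement distance of `sqrt(1.556771e+07)` ≈ 3946 km, reached through a
transit centred on day 10.1 lasting about `4 * phi` ≈ 8 days — and the
observed 3-month range agrees:

```r
cls$range_3mo
#> [1] 4083.32
cls$scale
#> [1] "medium"
```

The full pipeline (simulate or ingest, speed-filter, classify, period
statistics, circular summaries, habitat annotation, group contrasts) runs
from one config:

```r
res <- run_pipeline(run_config(n_per_mode = 10, seed = 1, out_dir = "out"))
```

or from the installed command line entry point:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/fledgemove.R", package="fledgemove"))')" \
  run --seed 1 --out out
```

## Reproduction

Install and test:

```sh
R CMD INSTALL --no-docs --no-html --no-help .
Rscript -e 'testthat::test_dir("tests/testthat", package = "fledgemove",
                               load_package = "installed")'
```

The acceptance run simulates the default 50-track cohort (10 per mode),
classifies every track and writes the headline quantities as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

With `--seed 1` this reports, among others, `mode_recovery_accuracy: 1`,
`looping_detector_sensitivity: 1`,
`looping_detector_false_positive_rate: 0`,
`nomad_daily_distance_median_kmday: 342.6` and
`rayleigh_type1_rate: 0.054`. Everything is deterministic in the seed;
rerunning with the same seed reproduces the file byte for byte.

## Package layout

| Module | Contents |
|---|---|
| `R/geo-core.R` | spherical geometry: haversine, bearings, rhumb lines, destination points |
| `R/track.R` | track objects, delimited I/O, speed filter, GLS smoothing |
| `R/nsd-models.R` | NSD curves, LM fitting, concordance selection, plausibility screen, looping detector, `classify_movement()` |
| `R/trajectory-stats.R` | period statistics, daily distance, sinuosity, circular summaries, Rayleigh test |
| `R/habitat.R` | ASCII grid I/O, raster lookup, neritic/oceanic rule, settlement habitat |
| `R/group-comparison.R` | mixed-model Tukey contrasts, exact rank-sum latitude comparison |
| `R/synthetic-data.R` | five-phenotype simulator, duty cycle, positional noise, cohorts |
| `R/pipeline.R` + `inst/cli/` | end-to-end pipeline and command line interface |

See `vignettes/movement-classification.Rmd` for the methods in full.
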