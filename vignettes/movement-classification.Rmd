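---
title: "Classifying juvenile seabird movement strategies from tracking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying juvenile seabird movement strategies from tracking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fledgemove)
```

## The problem

Fledgling albatrosses and petrels leave their natal colony once and are then
on their own, often for years. The first months at sea decide whether a bird
commutes to a fixed foraging ground, drifts with the wind field, settles in a
distant water mass, or rides a great ocean gyre back towards home. Satellite
transmitters and geolocators give us the trajectory, but the strategy has to
be inferred: `fledgemove` classifies each track into one of five canonical
movement modes — home range, nomadism, half-migration (outward trip that ends
in settlement), full migration (outward trip and return), and large-scale
looping — and computes the per-period trajectory statistics used to compare
species, age classes and habitats.

## Net squared displacement and the model family

The classification variable is the net squared displacement (NSD): the square
of the great-circle distance between each fix and the colony, as a function of
days since departure. Each mode leaves a distinct NSD signature, captured by a
four-model family evaluated with `eval_nsd_model()` and fitted with
Levenberg–Marquardt least squares (`fit_nsd_model()`, via `minpack.lm`):

* **home range** — asymptotic: $\kappa\,(1 - e^{-t/\tau})$. Displacement
  saturates at the home-range scale $\sqrt{\kappa}$.
* **nomad** — linear: $\beta t$, the diffusive signature of undirected
  large-scale wandering.
* **half-migration** — logistic:
  $\delta / (1 + e^{(\theta - t)/\phi})$. The bird departs around day
  $\theta$, travels for a transit of scale $\phi$, and settles at distance
  $\sqrt{\delta}$.
* **migration** — double logistic: the half-migration rise followed by a
  mirrored descent centred on $\theta_2 > \theta$; the bird comes home.

Selection among fitted models uses Lin's concordance correlation coefficient
(`concordance()`) between observed and fitted NSD — a stricter criterion than
$R^2$ because it penalises scale and location shifts, not just scatter. Ties
within $10^{-6}$ go to the model with fewer parameters.

### Why displacement is unwrapped for fitting

Great-circle distance can never exceed half the Earth's circumference, so the
haversine NSD of a circumpolar nomad is non-monotone: a bird flying steadily
east appears to turn back once it passes the antipode, and the linear model
can never win. `classify_movement()` therefore fits the model family on an
*unwrapped* displacement (`compute_nsd(..., unwrap = TRUE)`) that accumulates
longitude across antimeridian crossings, while the reported ranges
(`range_at()`, `range_3mo`) remain true great-circle distances.

## Plausibility screening

A flexible model can achieve high concordance with parameters that make no
biological sense, so every fit passes `plausibility_check()` before it can be
selected. A fit is rejected when any of the following holds:

1. a timing parameter ($\theta$, $\theta_2$) falls outside $[0, 1.5 \times$
   track duration$]$;
2. the implied displacement scale ($\sqrt{\delta}$ or $\sqrt{\kappa}$) exceeds
   1.25 times the largest observed colony distance;
3. a transit or relaxation scale ($\phi$, $\phi_2$, $\tau$) exceeds the track
   duration;
4. a nomad fit implies a 3-month range beyond what sustained flight can cover;
5. the claimed settlement (or return) is not actually observed within the
   track: $\theta + 2\phi$ (and for migration $\theta_2 + 2\phi_2$) must not
   exceed the track duration. A logistic whose plateau lies beyond the data is
   a settlement claim the trajectory cannot support — and because an unbounded
   nomadic NSD is convex, such a fit would otherwise always out-score the
   linear model;
6. the observed NSD over the fitted plateau must be flat: if its linear trend
   across the plateau window exceeds half the fitted asymptote, the bird was
   still in transit where the model claims residency;
7. for migration, the observed NSD after the fitted return must have decayed
   (mean below a quarter of the asymptote) — otherwise a circumnavigating bird
   whose unwrapped displacement happens to arc would be read as a completed
   round trip.

If every model of the family is implausible or weak, the track is reported
with its best remaining concordance and flagged accordingly.

## The looping detector

Large-scale looping — repeated multi-thousand-kilometre circuits that return
near the colony — defeats the whole NSD family: its NSD is roughly periodic,
every model fits badly, and the most flexible model (migration; a single loop
*is* an out-and-return in NSD terms) usually "wins" the junk fit.
`detect_looping()` works on the geometry instead, firing when both hold:

* **periodicity** — the 5-day block-median NSD falls by at least 25% of its
  running maximum at some point after the first month (the bird comes back);
* **consistent winding** — the bearing from the colony to the bird, taken on
  fixes at least 100 km out, accumulates a net signed sweep of at least
  $\pi$ radians *and* that net sweep is at least half the total absolute
  sweep. The consistency requirement matters: net winding alone is diffusive
  and heavy-tailed for a home-ranging wanderer, and fires on about half of
  them.

When the detector fires and the 3-month range is below the looping ceiling,
the track is labelled `large_scale_looping` regardless of which NSD model
fitted least badly. A genuine migration never trips the detector, because its
colony-bearing sweep has no rotational consistency.

## The trajectory simulator

`simulate_track()` generates hourly latent paths for each phenotype and then
degrades them exactly as a real deployment would: duty-cycled transmission
windows (`apply_duty_cycle()`, default 12 h on / 60 h off at a 6-h fix
cadence, about 0.7 locations per day) and positional noise
(`add_positional_noise()`, Argos-scale 15 km per axis or geolocator-scale
with 180 km median radial error). Generator geometry worth knowing:

* **home range** is *progressive range expansion*: the patrolled colony
  distance grows as $r\sqrt{1 - e^{-t/\tau}}$, which makes the NSD asymptotic
  by construction — the defining property of the mode. Exploration is
  tangential within a bounded bearing sector (a bird that orbits the colony
  is, by definition, looping, not home-ranging), with small mean-reverting
  radial jitter.
* **nomad** is a correlated random walk with persistent eastward drift in the
  subantarctic westerlies band.
* **half-migration** is directed transit to a settlement distance followed by
  ring-regulated wandering; **migration** adds the timed return leg.
* **looping** is a noisy circuit whose centre is offset from the colony by
  0.6 of the loop radius, so the colony lies *inside* the circuit. A circuit
  passing through the colony would flip the colony bearing by $\pi$ at each
  passage and cancel the winding signal the detector relies on.

`simulate_cohort()` derives one seed per track from the master seed in order,
so any single track of a cohort can be reproduced standalone.

## Downstream statistics

`period_stats()` summarises each track over consecutive 15-day periods:
daily distance travelled (gap-aware, `daily_distance()`), sinuosity, and mean
latitude. Departure and two/three-month rhumb bearings feed
`circular_summary()`, which reports the mean direction, resultant length and
the Rayleigh uniformity test. Groups are compared with a mixed model
(individual as random effect, optional AR(1) within-individual correlation)
and Tukey-adjusted contrasts (`compare_groups()`); juvenile–adult latitude
contrasts use the exact rank-sum test for small samples
(`compare_age_latitude()`). `annotate_track()` and `settlement_habitat()`
attach bathymetry, SST and chlorophyll-a from ASCII grids, with the
neritic/oceanic split at −3000 m.

## A worked classification

```{r classify}
cfg <- default_sim_config("half_migration", seed = 3)
track <- simulate_track(cfg)
cls <- classify_movement(track, seed = 1)
cls$movement_type
round(cls$cc, 3)
cls$range_3mo
```

The full pipeline — simulate or ingest, filter, classify, summarise, compare,
annotate — runs from one configuration object:

```{r pipeline, eval = FALSE}
cfg <- run_config(n_per_mode = 10, seed = 1, out_dir = "out")
res <- run_pipeline(cfg)
truth <- read.csv(file.path("out", "truth.csv"))
cls <- res$classification
table(truth$mode, cls$movement_type[match(truth$id, cls$id)])
```

## Limitations

* The NSD family assumes a single strategy per track; birds that switch
  strategy mid-track are assigned the dominant signature.
* The looping detector needs at least a month of data and fixes beyond
  100 km; short or colony-bound tracks cannot loop by definition.
* Geolocator noise (median radial error 180 km) makes the home-range /
  half-migration boundary unreliable below settlement distances of a few
  hundred kilometres; classifications of small-scale modes from geolocator
  data should be treated as indicative.
* Tracks shorter than 80 days are flagged `partial`; their settlement-phase
  statistics cover whatever tail exists.
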