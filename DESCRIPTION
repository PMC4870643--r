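Package: fledgemove
Title: Movement-Mode Classification and Trajectory Statistics for Juvenile Seabird Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing large-scale dispersal of fledgling seabirds
    from satellite (Argos) and geolocator (GLS) tracking data. Implements
    net-squared-displacement (NSD) model fitting for four canonical movement
    modes (home range, nomadism, half-migration, full migration) with
    concordance-based model selection, parameter-plausibility screening and a
    post-hoc detector for large-scale looping movements; per-track trajectory
    statistics over 15-day periods (departure bearings, rhumb bearings at two
    and three months, sinuosity, daily distance travelled, mean latitude) with
    circular summaries and the Rayleigh uniformity test; habitat annotation
    from bathymetry, sea-surface temperature and chlorophyll-a rasters with a
    neritic/oceanic depth rule; mixed-model group comparisons with Tukey
    contrasts and exact rank-sum age-class comparisons; and a seeded
    correlated-random-walk trajectory simulator with duty-cycled sampling and
    Argos/GLS positional noise for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    nlme,
    multcomp,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
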