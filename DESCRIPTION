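Package: no2commute
Title: Population-Based Simulation of Commuter Exposure to NO2
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates population-based commuter exposure to nitrogen dioxide
    from annual-mean air pollution surfaces of differing spatial resolution.
    Provides a synthetic scenario generator (latent concentration field,
    multi-resolution rasters, road network, commuter travel diaries, monitoring
    station time series), deterministic shortest-route simulation on a road
    network, main/side road classification of commuter legs, hour-of-day
    temporal adjustment factors derived from street and background monitoring
    stations, length-weighted extraction of grid concentrations along routes,
    time-weighted exposure and ventilation-adjusted inhaled-dose estimation,
    and inter-model comparison statistics (Bland-Altman limits of agreement,
    Spearman correlation, polynomial relation fits, Wilcoxon signed-rank and
    Fisher-Pitman permutation tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
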