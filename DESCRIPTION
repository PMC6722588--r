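Package: aroidnet
Title: Quantitative Analysis of Aroid-Insect Trophic Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of bipartite insect-host
    interaction networks built from per-infructescence rearing records.
    Implements network-level and species-level specialization (H2', d'),
    Morisita-Horn niche overlap, Kleinberg HITS hub/authority centrality,
    Barber's weighted bipartite modularity maximized by repeated-restart
    label propagation, Patefield fixed-marginal null models with Z-scores,
    first-order jackknife richness estimation with sample-based accumulation
    curves, Baselga's balanced/gradient partition of Bray-Curtis
    dissimilarity, a frequency/abundance dominance index (IFA), and the
    Williams-corrected G-test of guild-by-host independence. Ships the
    printed data tables of an aroid-infesting insect survey as curated
    fixtures, reconstructs the integer count web from its column-percentage
    presentation, and provides a synthetic community generator with planted
    module structure, dominance and elevational turnover for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
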