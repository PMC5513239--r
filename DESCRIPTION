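Package: gtrio
Title: Grandparentage Trio Assignment and Life-History Inference for
    Near-Completely Sampled Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exclusion-based parentage and one-parent-known grandparentage
    (Gtrio) assignment for multi-generation genetic pedigrees built from
    highly polymorphic microsatellite panels, motivated by trap-and-haul
    salmon reintroductions where nearly every anadromous adult is sampled.
    Provides a forward pedigree simulator with genotyping-error injection,
    planted unsampled spawners and panel degradation; simulation harnesses
    that quantify how much genotyping error, missing adult genotypes and
    mis-sexed adults explain offspring with one unassigned parent;
    expected-false-Gtrio calculations (analytic and Monte Carlo); and
    downstream life-history classification (precocial resident versus
    adfluvial spawners) with cohort-replacement-rate updates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
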