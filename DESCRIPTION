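Package: sedmeth
Title: Thermodynamics, Isotope Systematics, and Community Succession of
    Methane-Cycling Archaea in Marine Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of the sedimentary methane cycle
    in diffusion-dominated continental margin sediments. Computes in situ Gibbs
    energies of six methanogenic, methanotrophic and acetate-cycling reactions
    along porewater depth profiles using temperature- and pressure-corrected
    standard-state energies and fixed activity coefficients; solves the narrow
    hydrogen concentration window in which syntrophic acetate oxidation and
    hydrogenotrophic methanogenesis are simultaneously exergonic; estimates
    carbon isotope fractionation factors between dissolved inorganic carbon and
    methane; assigns geochemical zones (bioturbation, sulfatic, sulfate-methane
    transition, methanic) from sulfate and methane profiles; and quantifies
    depth-related succession of methane-cycling archaea from qPCR totals and
    marker-gene read tables, including absolute-abundance trend classification
    and diversity metrics. A seeded synthetic-data generator emulating a
    four-station water-depth gradient makes the full pipeline testable end to
    end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
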