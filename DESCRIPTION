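Package: cnlsim
Title: Five-Colour Nutrition Label Scoring, Dietary Profiling and Food
    Substitution Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores foods and beverages with the (French-modified) FSA/Ofcom
    nutrient profiling model and allocates the five ordered colour classes of
    the 5-Colour Nutrition Label (5-CNL). Assembles weighted daily intakes from
    repeated 24-h dietary records, screens energy under-reporters with the
    Goldberg/Black cut-off on Schofield-predicted basal metabolic rate, and
    profiles individuals by the share of non-alcohol energy drawn from each
    colour class. Clusters individuals into dietary profiles (Ward seeding plus
    k-means refinement, with R-squared, semi-partial R-squared, pseudo-T-squared
    and cubic-clustering-criterion diagnostics), simulates three label-guided
    within-food-group substitution scenarios, and evaluates nutritional adequacy
    against configurable French recommendations before and after substitution.
    Includes a synthetic-data generator producing food tables, populations and
    24-h records with known ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    ggplot2
Config/testthat/edition: 3
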