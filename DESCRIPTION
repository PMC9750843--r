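Package: gardensim
Title: Neighborhood-Crowding Bias in Common-Garden Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatially explicit, individual-based simulation of common-garden
    (transplant garden) experiments, built around a distance-decay crowding
    kernel for plant-plant interactions. Generates grid garden layouts with
    mortality gaps, propagates posterior parameter uncertainty through paired
    growth predictions with and without neighborhood effects, and quantifies
    how planting distance distorts between-group ANOVA outcomes via a
    relativized F-statistic and full/base correlation-convergence curves.
    Includes a synthetic posterior generator calibrated to sagebrush
    (Artemisia) subspecies-cytotype orderings, a least-squares parameter
    recovery fitter for forward-model validation, and a configurable
    end-to-end pipeline that recommends minimum planting distances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
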