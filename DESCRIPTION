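Package: swimperiod
Title: Latent-Class Trajectory Analysis of Swim Training Periodization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify elite swimmers' weekly training loads from
    blood-lactate intensity zones, compute the normalized Total Training Load
    (TTL) statistic and its week-to-week variability, cluster 25-week TTL
    trajectories with a latent-class linear mixed model (spline mean curves,
    subject random effects, multinomial class membership, EM estimation with
    AIC/BIC model search), and characterize the resulting periodization
    profiles (progressivity, compositional intensity distribution via the
    isometric log-ratio transform, relative performance). Includes a synthetic
    cohort generator with known latent-class structure for validation.
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
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
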