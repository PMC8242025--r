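Package: gfbascan
Title: Simulation and Sliding-Window Analysis of Global Feature-Based
    Attention ERP Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating and analysing event-related potential (ERP)
    experiments on global feature-based attention (GFBA) measured with the
    unattended probe paradigm. Provides a synthetic-data generator for trial
    tables, behaviour and multichannel EEG with injected attention effects;
    preprocessing (behavioural filtering, mastoid re-referencing, epoching,
    peak-to-peak artifact rejection, baseline correction); condition averaging
    and difference-wave derivation; sliding-window repeated-measures ANOVA with
    Greenhouse-Geisser correction, a sampling-rate-aware corrected alpha and a
    consecutive-samples onset rule; reaction-time median/quartile and
    target-repetition trial splits; and a toy minimum-norm least-squares source
    estimation stage with leadfield-based sensor repositioning.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
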