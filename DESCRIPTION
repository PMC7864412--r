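Package: stmfexcess
Title: Weekly Excess Mortality Estimation from Short-Term Mortality Fluctuation Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates weekly excess mortality from short-term mortality
    fluctuation (STMF) style tables of weekly death counts and rates by age
    group and sex. Provides six reference-level baselines (week-specific
    averages, week-specific ordinary-least-squares trends, week-specific
    lower-quartile means, and three within-year constant baselines: yearly
    average-week, summer average-week, and yearly lower-quartile-week),
    excess/deficit interval detection, selection summaries, static figures,
    a synthetic STMF-format data generator with known ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, grDevices, graphics, tools
Suggests: testthat (>= 3.0.0), withr, jsonlite, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
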