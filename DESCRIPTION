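Package: ftlmap
Title: Fluorescent-Tetrad Crossover Analysis and Meiosis Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tetrad-based analysis of meiotic crossovers scored with pollen
    fluorescent tagged lines (FTLs): classification of tetrads into parental
    ditype, tetratype and non-parental ditype classes, Perkins map distances
    with multinomial delta-method standard errors, crossover-interference
    ratios from adjacent-interval conditioning with a Z-score comparison
    between conditions, Welch group comparisons for cytological focus counts,
    and comparative-CT (delta-delta-CT) qPCR analysis with ANOVA and Tukey
    post-hoc tests. Includes a meiosis simulator with interfering (Type I,
    gamma-renewal) and non-interfering (Type II, Poisson) crossover pathways,
    double-strand-break homeostasis, and mutant/temperature scenarios, so that
    every analysis stage can be exercised and calibrated on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
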