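Package: tvspm
Title: State-Space Surplus Production Models with Time-Varying Productivity
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Continuous-time state-space surplus production modelling for
    data-moderate stock assessment, with maximum net productivity and
    carrying capacity allowed to vary through time as mean-reverting
    (Ornstein-Uhlenbeck) processes on the log scale. Supports Schaefer,
    Fox-limit and Pella-Tomlinson production curves, multi-fleet lognormal
    CPUE observation models, Laplace-approximated marginal maximum
    likelihood estimation via 'TMB', time-varying MSY-based reference
    points, AICc model comparison, one-step-ahead residual diagnostics,
    retrospective analysis, and a post hoc environmental-linkage workflow
    (iterative VIF screening and generalized additive models). Includes a
    full synthetic-data generator for the assessed population, its fishery
    observations and a correlated environmental covariate table.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    TMB,
    mgcv,
    jsonlite,
    stats,
    utils
LinkingTo:
    TMB,
    RcppEigen
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
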