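Package: dctitp
Title: Bayesian Longitudinal Dose-Response Modelling for Hybrid
    Decentralized Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits the DCT-ITP model, a Bayesian extension of the
    integrated two-component prediction (exponential-decay) longitudinal
    dose-response model for hybrid decentralized clinical trials in which
    the same subject contributes both onsite (centralized) and offsite
    (decentralized) measurements. Decentralization shifts in the
    time-effect rate and in the Emax terminal dose-response, together
    with inflated residual variability, are modelled explicitly and
    regularized with spike-and-slab (or horseshoe) priors so that
    decentralized data are pooled adaptively rather than naively.
    Missing outcomes are handled by Bayesian data augmentation under
    missingness at random. Includes a decentralized-trial simulator
    (visit jitter, onsite/offsite schedules, outcome-dependent dropout
    and intermittent missingness), comparator model variants fit to
    onsite-only, pooled, or all-onsite data, clinical estimands (AUC of
    the longitudinal mean curve, terminal mean response, and their
    placebo-subtracted contrasts), and simulation-study metrics
    (dose-averaged bias, RMSE, coverage, and interval length).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
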