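Package: biomtte
Title: Target-Trial Emulation of Hearing-Aid Effects on Plasma Dementia Biomarkers
Version: 0.1.0
Authors@R: person("biomtte", "authors", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for emulating point-treatment target trials of hearing-aid
    treatment strategies with plasma biomarkers of Alzheimer's disease and
    related dementias (pTau181, NfL, GFAP, Abeta42/Abeta40) as outcomes.
    Provides a synthetic-cohort generator with known ground truth
    (confounded treatment, death before follow-up, MAR/MNAR missingness),
    eligibility screening and strategy assignment, multiple imputation by
    chained predictive mean matching with LASSO-selected auxiliaries and
    delta-adjustment (NARFCS) sensitivity analysis, targeted maximum
    likelihood estimation of survivor-conditional mean contrasts,
    inverse-probability-weighted quantile contrasts, marginal structural
    models for effect modification with restricted cubic splines,
    multivariate adaptive regression spline nuisance fits, and
    bootstrap-then-imputation confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
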