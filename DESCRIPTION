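Package: cacCEA
Title: Cost-Effectiveness of Coronary Artery Calcium Testing to Guide Statin Allocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov state-transition cost-effectiveness model of coronary artery
    calcium (CAC) testing for statin allocation in asymptomatic, intermediate-risk
    adults. Generates synthetic cohorts matching the MESA intermediate-risk
    subsample composition, advances them through annual cycles of first coronary
    heart disease (CHD) or cardiovascular disease (CVD) events with life-table
    background mortality, statin adverse events and QALY accrual, and compares
    CAC-guided treatment thresholds against treat-all and ATP III guideline
    strategies over 5- and 10-year horizons. Includes probabilistic sensitivity
    analysis with beta, gamma and triangular parameter distributions,
    cost-effectiveness acceptability curves, scenario grids and break-even search.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
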