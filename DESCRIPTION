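Package: itpclaims
Title: Corticosteroid Treatment Patterns and Risks in Immune Thrombocytopenia
    from Administrative Claims
Version: 0.1.0
Authors@R:
    person("ITP Claims", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacoepidemiological analysis of corticosteroid (CS)
    use in adult primary immune thrombocytopenia (ITP) from administrative
    claims tables: new-user cohort construction with look-back washout,
    prescription episode merging with drug-specific gap periods,
    prednisolone-equivalent dose quantification (weekly dose grid, cumulative
    dose, duration), time-to-withdrawal Kaplan-Meier analysis with log-rank
    comparison across calendar eras, treatment-line and switch-pattern
    derivation with Sankey export, and a nested case-control assessment of
    CS-associated adverse outcomes via risk-set sampling and matched-set
    conditional logistic regression. Includes a synthetic claims generator
    with known ground truth for end-to-end parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
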