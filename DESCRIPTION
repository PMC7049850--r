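Package: tumorimmune
Title: Tumor-Immune Interaction Dynamics with CD4+ T Cells, Immunotherapy
    and Chemotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates a seven-state ordinary differential equation model of
    tumor growth under immune surveillance, coupling tumor cells with natural
    killer cells, CD8+ T cells, CD4+ T cells, circulating lymphocytes, the
    IL-2 cytokine and a chemotherapy drug compartment.  Treatments
    (chemotherapy, IL-2, adoptive CD8+ and CD4+ T-cell transfer) enter as
    continuous or pulsed dose schedules.  Integration uses a fixed-step
    Adams-Bashforth/Adams-Moulton predictor-corrector of configurable order
    (1-12) with exact rational coefficients, a self-starting refined ramp-up
    and restarts at dose discontinuities.  The package enumerates the
    equilibria of the untreated system along its three branches (tumor-free,
    zero-cytokine, nonzero-cytokine), classifies their stability from
    Jacobian eigenvalues, evaluates the closed-form tumor-recurrence
    threshold, and sweeps single parameters to locate bifurcation points.  A
    scenario workbench reproduces a panel of published no-treatment,
    continuous-therapy and pulsed-therapy experiments for two reference
    patients and reports eradication outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
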