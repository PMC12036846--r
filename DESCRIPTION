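Package: tdcontagion
Title: Temporal Discounting, Preference Uncertainty, and Social Contagion
    of Intertemporal Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian analysis of delegated
    intertemporal choice sessions in which participants first reveal their own
    delay-discounting preferences, then learn the preferences of two simulated
    others (one more impulsive, one more patient) and choose on their behalf.
    Implements hyperbolic discounting with softmax choice (KT model), the
    preference-uncertainty (KU) model in which the log discount rate is drawn
    per trial from a subject-specific normal distribution, generative and
    adaptive Bayesian choice-pair design, hierarchical Bayesian estimation of
    KU parameters per block via MCMC with Gelman-Rubin diagnostics, signed
    base-10 Kullback-Leibler divergence as the measure of preference shift
    under social influence, and parameter-recovery and posterior-predictive
    validation harnesses, together with a synthetic-cohort generator that
    emulates the full five-block session structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rjags,
    coda
Config/testthat/edition: 3
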