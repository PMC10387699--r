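# Fixture builders, constructed in code.

toy_dmt <- function(name, moa = name, irr = 1, rr = 1, c1 = 0, c2 = c1,
                    ae = 0, lines = c("1a", "1b", "2", "3", "4"), ...) {
  dmt_definition(name, moa, lines,
                 efficacy_estimate(irr, measure = "IRR_ARR"),
                 efficacy_estimate(rr, measure = "RR_CDP"),
                 c1, c2, ae_discontinuation_prob = ae, ...)
}

# Degenerate 3-state world: no events, flat utility 0.782, forced death at a
# given age. Reproduces the textbook 10 years * 0.782 = 7.82 QALY example.
flat_params <- function(death_age = 39, utility = 0.782,
                        discount_costs = 0, discount_effects = 0) {
  states <- 0:2
  lt <- data.frame(age = 0:100,
                   hazard = ifelse(0:100 < death_age, 1e-12, 1e9))
  nh <- natural_history_params(states, diag(3), rep(0, 3), rep(1, 3), lt)
  ec <- economic_params(rep(utility, 3), 0, rep(0, 3), rep(0, 3), 0, 50000,
                        discount_costs, discount_effects)
  dmts <- list(X = toy_dmt("X"), Y = toy_dmt("Y"))
  model_parameters(dmts, nh, ec,
                   grammar_rules(first_line_escalation_set = c("X", "Y")),
                   cohort = list(n_patients = 10L, start_age = 29L,
                                 baseline_edss_range = c(0L, 2L)))
}

# Small 3-state world with real dynamics, used against the Markov-cohort
# oracle (natural history only, no treatment).
toy_markov_params <- function() {
  states <- 0:2
  tm <- rbind(c(0.88, 0.09, 0.03),
              c(0.02, 0.88, 0.10),
              c(0.00, 0.03, 0.97))
  lt <- data.frame(age = 0:100, hazard = 2.5e-5 * exp(0.085 * (0:100)))
  nh <- natural_history_params(states, tm, c(0.5, 0.4, 0.3), c(1, 1.3, 1.8), lt)
  ec <- economic_params(c(0.85, 0.70, 0.50), 0.07,
                        c(2000, 6000, 15000), c(1000, 4000, 9000),
                        2600, 50000, 0.04, 0.015)
  dmts <- list(X = toy_dmt("X"), Y = toy_dmt("Y"))
  model_parameters(dmts, nh, ec,
                   grammar_rules(first_line_escalation_set = c("X", "Y")),
                   cohort = list(n_patients = 1000L, start_age = 29L,
                                 baseline_edss_range = c(0L, 2L)))
}

# Synthetic default parameters, generated once per test session.
synth_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_synthetic_params(scenario_spec())
    cache
  }
})

ocr_first_line <- function() sequence_spec(c("OCR", "CLA", "NAT", "ALE"))
ofa_first_line <- function() sequence_spec(c("OFA", "CLA", "NAT", "ALE"))

# Clone a DMT under a new name (same class unless overridden).
clone_dmt <- function(d, name, moa = d$moa_class) {
  d$name <- name
  d$moa_class <- moa
  d
}
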