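# Fixtures built in code: a degenerate "all-off" Markov config for
# pencil-and-paper traces, and a direct psa_result builder for synthetic
# INB surfaces.

zero_markov_config <- function(...) {
  markov_config(
    rates = list(local_recurrence = 0, metastatic = 0, lr_to_met = 0,
                 met_mortality = 0),
    background_mortality = list(rate0 = 0, slope = 0),
    treatment_effects = list(intensity = 1, modality = 1, duration = 0),
    utilities = list(well = 1, local_recurrence = 1, met_decrement = 0,
                     age_slope = 0),
    costs = list(well = 0, well_first = 0, lr_first = 0, lr_later = 0,
                 met = 0,
                 intervention = list(A = list(sessions = 0, per_session = 0),
                                     B = list(sessions = 0, per_session = 0))),
    adverse_events = list(
      prob = rbind(A = c(c0 = 1, c2a = 0, c2b = 0, c3 = 0),
                   B = c(c0 = 1, c2a = 0, c2b = 0, c3 = 0)),
      cost = c(c0 = 0, c2a = 0, c2b = 0, c3 = 0),
      disutility = c(c0 = 0, c2a = 0, c2b = 0, c3 = 0),
      concentration = 150),
    horizon = 10,
    discount = list(costs = 0, qalys = 0),
    ...
  )
}

# psa_result with an arbitrary INB surface: comparator all zero, intervention
# QALYs equal to inb, costs zero.
make_synthetic_psa <- function(draws, inb, k = 13000, population = 0) {
  n <- nrow(draws)
  psa_result(
    draws = draws,
    outcomes = list(
      strategy_outcomes("A", qalys = numeric(n), costs = numeric(n)),
      strategy_outcomes("B", qalys = inb, costs = numeric(n))
    ),
    k = k, incident_population = population
  )
}
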