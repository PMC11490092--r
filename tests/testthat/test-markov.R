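# markov_case_study: rate conversion, cohort traces, PSA sampling, toy model.

test_that("rates_to_cycle_probabilities matches competing-risks arithmetic", {
  # no rates: identity
  expect_equal(rates_to_cycle_probabilities(matrix(0, 3, 3)), diag(3))
  # single exit at rate ln 2 over one year: probability one half
  q <- matrix(0, 2, 2); q[1, 2] <- log(2)
  P <- rates_to_cycle_probabilities(q, 1)
  expect_equal(P[1, 2], 0.5)
  expect_equal(rowSums(P), c(1, 1))
  # two equal exits r1 = r2 = 1: total 1 - e^-2 split evenly
  q <- matrix(0, 3, 3); q[1, 2] <- 1; q[1, 3] <- 1
  P <- rates_to_cycle_probabilities(q, 1)
  expect_equal(P[1, 2], (1 - exp(-2)) / 2)
  expect_equal(P[1, 3], (1 - exp(-2)) / 2)
  expect_error(rates_to_cycle_probabilities(matrix(-1, 2, 2)), "negative")
  expect_error(rates_to_cycle_probabilities(matrix(0, 2, 2), 0), "cycle_length")
})

test_that("run_cohort reproduces hand-computed traces", {
  # frozen cohort, utility 1, no discounting: one QALY per cycle
  tr <- run_cohort(zero_markov_config(), "A")
  expect_equal(tr$discounted_qalys, 10)
  expect_equal(tr$discounted_costs, 0)
  # 3.5%/yr discounting, first cycle undiscounted: geometric series
  tr <- run_cohort(zero_markov_config(discount = list(costs = 0.035,
                                                      qalys = 0.035)), "A")
  expect_equal(tr$discounted_qalys, sum(1.035^-(0:9)))
  expect_equal(round(tr$discounted_qalys, 4), 8.6077)
  # two-cycle, two-state pencil-and-paper check: well -> dead at 0.1/yr, u = 0.8
  cfg <- zero_markov_config(
    background_mortality = list(rate0 = 0.1, slope = 0),
    utilities = list(well = 0.8, local_recurrence = 0.8, met_decrement = 0,
                     age_slope = 0),
    horizon = 2
  )
  tr <- run_cohort(cfg, "A")
  expect_equal(tr$discounted_qalys, 0.8 * (1 + exp(-0.1)))
  expect_equal(tr$occupancy[, "dead"], c(0, 1 - exp(-0.1), 1 - exp(-0.2)))
})

test_that("cohort conservation and monotone death hold across random configs", {
  set.seed(7)
  for (i in 1:15) {
    cfg <- markov_config(
      rates = list(local_recurrence = runif(1, 0, 0.3),
                   metastatic = runif(1, 0, 0.2),
                   lr_to_met = runif(1, 0, 0.5),
                   met_mortality = runif(1, 0, 1)),
      horizon = sample(5:40, 1)
    )
    for (arm in c("A", "B")) {
      tr <- run_cohort(cfg, arm)
      expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-12)
      expect_true(all(diff(tr$occupancy[, "dead"]) >= -1e-15))
    }
  }
})

test_that("weaker treatment effects weakly reduce the QALY gain", {
  gain <- function(rr) {
    cfg <- markov_config()
    cfg$treatment_effects$intensity <- rr
    cfg$treatment_effects$modality <- rr
    r <- markov_inb(cfg)
    r$delta_qalys
  }
  g <- vapply(c(0.6, 0.8, 0.95, 1), gain, numeric(1))
  expect_true(all(diff(g) <= 1e-12))
  # at the null, only the one-off adverse-event disutility difference remains
  ae <- markov_config()$adverse_events
  expect_equal(g[4], sum((ae$prob["A", ] - ae$prob["B", ]) * ae$disutility))
})

test_that("discounted outcomes are non-increasing in the discount rate", {
  q <- vapply(c(0, 0.015, 0.035, 0.06), function(r) {
    run_cohort(markov_config(discount = list(costs = r, qalys = r)),
               "B")$discounted_qalys
  }, numeric(1))
  expect_true(all(diff(q) < 0))
})

test_that("sample_psa is reproducible and respects determinism contracts", {
  cfg <- markov_config()
  p1 <- sample_psa(cfg, n_draws = 10, seed = 11)
  p2 <- sample_psa(cfg, n_draws = 10, seed = 11)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$outcomes[[2]]$costs, p2$outcomes[[2]]$costs)
  expect_equal(ncol(p1$draws), 21)  # the 21 probabilistic inputs
  expect_named(p1$correlation_groups, "ae_probabilities")
  # all parameters deterministic: zero-width draw matrix, zero INB variance
  pd <- sample_psa(cfg, specs = list(), n_draws = 5, seed = 1)
  expect_equal(ncol(pd$draws), 0)
  expect_equal(stats::sd(compute_inb(pd)), 0)
  # invalid hyperparameters -> domain error (zero-probability AE class)
  bad <- markov_config()
  bad$adverse_events$prob["A", ] <- c(1, 0, 0, 0)
  expect_error(sample_psa(bad, n_draws = 2, seed = 1), "Dirichlet")
})

test_that("AE probabilities stay on the simplex and correlate across arms", {
  psa <- sample_psa(markov_config(), n_draws = 300, seed = 5)
  ae_b <- psa$draws[, c("p_ae0_B", "p_ae2a_B", "p_ae2b_B", "p_ae3_B")]
  expect_true(all(ae_b >= 0 & ae_b <= 1))
  expect_true(all(rowSums(ae_b) <= 1 + 1e-9))
  ae_a <- psa$draws[, c("p_ae2a_A", "p_ae2b_A", "p_ae3_A")]
  expect_true(all(rowSums(ae_a) <= 1 + 1e-9))
  # shared underlying draws induce positive cross-arm correlation
  expect_gt(cor(psa$draws[, "p_ae2a_A"], psa$draws[, "p_ae2a_B"]), 0.5)
})

test_that("set_config_param validates domains", {
  cfg <- markov_config()
  expect_error(set_config_param(cfg, "nonsense", 1), "unknown parameter")
  expect_error(set_config_param(cfg, "u_well", 1.2), "above 1")
  expect_error(set_config_param(cfg, "rate_lr", -0.1), "negative")
  expect_error(set_config_param(cfg, "p_ae2a_B", 1.5), "probability")
  cfg2 <- set_config_param(cfg, "rate_lr", 0.05)
  expect_equal(get_config_param(cfg2, "rate_lr"), 0.05)
})

test_that("linear_gaussian_toy matches its analytic moments", {
  psa <- linear_gaussian_toy(c(0.2, -0.1, 0.05), c(0.5, 0.3, 0.1),
                             n_draws = 2e4, seed = 8)
  inb <- compute_inb(psa)
  mu <- 0.2 - 0.1 + 0.05
  sigma <- sqrt(0.5^2 + 0.3^2 + 0.1^2)
  expect_lt(abs(mean(inb) - mu), 3 * sigma / sqrt(2e4))
  # closed forms: certain decision has zero EVPI; sd-0 parameter none either
  expect_equal(toy_true_evpi(1, 0), 0)
  expect_equal(toy_true_evpi(c(0, 0), c(1, 0), subset = 2), 0)
  expect_equal(toy_true_evpi(c(0, 0), c(1, 0)), dnorm(0))
  expect_error(linear_gaussian_toy(0, -1, 10), "sds")
})
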