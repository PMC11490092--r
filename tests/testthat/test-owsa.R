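# owsa: percent-rescaled OLS semielasticities, adaptation metric, manual OWSA.

test_that("semielasticity follows the chain rule exactly on a noiseless model", {
  set.seed(3)
  x <- rnorm(200)
  x <- 2 + (x - mean(x)) / sd(x)          # sample mean exactly 2
  psa <- make_synthetic_psa(cbind(x = x, z = runif(200, 1, 3) ),
                            0.5 * x)
  tab <- fit_semielasticity_metamodel(psa)
  # d INB / d(1% of x) = 0.5 * 2 / 100
  expect_equal(tab$semielasticity[tab$parameter == "x"], 0.01,
               tolerance = 1e-10)
  expect_equal(attr(tab, "r_squared"), 1, tolerance = 1e-10)
  expect_equal(tab$parameter[1], "x")
})

test_that("OLS recovers known coefficients within 3 SE under noise", {
  set.seed(14)
  n <- 10000
  draws <- cbind(a = rgamma(n, 20, 4), b = rnorm(n, 10, 2),
                 c = runif(n, 0.5, 1.5))
  beta <- c(a = 0.03, b = -0.01, c = 0.002)
  inb <- as.numeric(draws %*% beta) + rnorm(n, 0, 0.2)
  psa <- make_synthetic_psa(draws, inb)
  tab <- suppressWarnings(fit_semielasticity_metamodel(psa))
  for (p in names(beta)) {
    truth <- beta[[p]] * mean(draws[, p]) / 100
    row <- tab[tab$parameter == p, ]
    expect_lt(abs(row$semielasticity - truth), 3 * row$std_error)
  }
  expect_equal(sum(tab$proportion), 1, tolerance = 1e-9)
  expect_true(all(diff(tab$adaptation_metric) >= -1e-9))
  expect_equal(utils::tail(tab$adaptation_metric, 1), 100, tolerance = 1e-9)
  expect_true(all(diff(abs(tab$semielasticity)) <= 1e-15))
})

test_that("scaling INB rescales coefficients but not ranks or metrics", {
  set.seed(15)
  n <- 2000
  draws <- cbind(a = rgamma(n, 9, 3), b = rnorm(n, 5, 1))
  inb <- 0.02 * draws[, "a"] - 0.01 * draws[, "b"] + rnorm(n, 0, 0.05)
  t1 <- suppressWarnings(fit_semielasticity_metamodel(
    make_synthetic_psa(draws, inb)))
  t2 <- suppressWarnings(fit_semielasticity_metamodel(
    make_synthetic_psa(draws, 7 * inb)))
  expect_identical(t1$parameter, t2$parameter)
  expect_equal(t2$semielasticity, 7 * t1$semielasticity, tolerance = 1e-8)
  expect_equal(t2$proportion, t1$proportion, tolerance = 1e-8)
  expect_equal(t2$adaptation_metric, t1$adaptation_metric, tolerance = 1e-6)
})

test_that("degenerate designs are surfaced, not silently fitted", {
  set.seed(16)
  # constant INB
  draws <- cbind(a = rnorm(100, 5), b = rnorm(100, 3))
  expect_warning(tab <- fit_semielasticity_metamodel(
    make_synthetic_psa(draws, rep(0.5, 100))), "constant")
  expect_true(all(tab$semielasticity == 0))
  expect_true(is.na(attr(tab, "r_squared")))
  # near-zero-mean column excluded with warning
  draws2 <- cbind(ok = rnorm(300, 5), centred = rnorm(300, 0, 1))
  expect_warning(tab2 <- fit_semielasticity_metamodel(
    make_synthetic_psa(draws2, draws2[, "ok"] + rnorm(300, 0, 0.1))),
    "mean ~ 0")
  expect_false("centred" %in% tab2$parameter)
  expect_true("centred" %in% attr(tab2, "excluded"))
  # exact collinearity is an error naming the columns
  x <- rnorm(300, 4)
  draws3 <- cbind(p = x, q = 2 * x)
  expect_error(suppressWarnings(fit_semielasticity_metamodel(
    make_synthetic_psa(draws3, x + rnorm(300, 0, 0.1)))), "collinear")
  # more parameters than draws
  expect_error(fit_semielasticity_metamodel(
    make_synthetic_psa(matrix(rnorm(12), 3, 4,
                              dimnames = list(NULL, letters[1:4])),
                       rnorm(3))), "more draws")
})

test_that("adaptation_metric sums top-ranked proportions", {
  tab <- structure(
    data.frame(parameter = c("a", "b"), rank = 1:2,
               semielasticity = c(3, 1), std_error = c(0, 0),
               proportion = c(0.75, 0.25),
               adaptation_metric = c(75, 100)),
    r_squared = 1, excluded = character(0),
    class = c("semielasticity_table", "data.frame"))
  expect_equal(adaptation_metric(tab, 1), 75)
  expect_equal(adaptation_metric(tab, 2), 100)
  expect_equal(adaptation_metric(tab, 0), 0)
  expect_error(adaptation_metric(tab, 3), "between 0 and 2")
})

test_that("manual OWSA equals the metamodel on an exactly linear model", {
  set.seed(17)
  n <- 500
  draws <- cbind(a = rnorm(n, 2, 0.3), b = rgamma(n, 16, 4))
  beta <- c(a = 0.5, b = 1.5)
  psa <- make_synthetic_psa(draws, as.numeric(draws %*% beta))
  tab <- fit_semielasticity_metamodel(psa)
  runner <- function(cfg) 0.5 * cfg$a + 1.5 * cfg$b
  cfg <- list(a = mean(draws[, "a"]), b = mean(draws[, "b"]))
  for (p in c("a", "b")) {
    d <- manual_owsa(runner, cfg, p, delta_pct = 1)
    m <- tab$semielasticity[tab$parameter == p]
    expect_lt(abs(d - m) / abs(m), 1e-8)
  }
  expect_equal(manual_owsa(runner, cfg, "a", delta_pct = 0), 0)
  expect_error(manual_owsa(runner, cfg, "zzz"), "unknown parameter")
})

test_that("manual OWSA on the Markov model respects signs and domains", {
  cfg <- markov_config()
  # pure cost parameter of the intervention-favoured state: raising the cost
  # of metastatic care helps the arm that prevents metastases
  d_cmet <- manual_owsa(NULL, cfg, "c_met")
  expect_gt(d_cmet, 0)
  # raising comparator-only AE burden favours the intervention
  expect_gt(manual_owsa(NULL, cfg, "p_ae3_A"), 0)
  expect_lt(manual_owsa(NULL, cfg, "p_ae3_B"), 0)
  # perturbation leaving the valid domain errors
  cfg2 <- cfg
  cfg2$adverse_events$prob["B", ] <- c(c0 = 0, c2a = 0.995, c2b = 0,
                                       c3 = 0.005)
  expect_error(manual_owsa(NULL, cfg2, "p_ae2a_B"),
               "out of \\[0, 1\\]|exceed")
})
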