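# Four-state oncology Markov cohort model: well, local recurrence, metastasis,
# dead. All survival functions exponential; background mortality is an
# additive age-indexed rate from every alive state. The local-recurrence
# state is split internally into a first-year tunnel (lr1) and subsequent
# years (lr2) so that first-year vs later recurrence costs can differ.

.markov_internal_states <- c("well", "lr1", "lr2", "met", "dead")
.ae_classes <- c("c0", "c2a", "c2b", "c3")

#' Markov case-study model configuration
#'
#' Builds the bundled configuration of a 4-state breast-cancer cohort model
#' (well, local recurrence, metastasis, dead) comparing current practice (A)
#' with a higher-intensity treatment using a new modality (B). Both relative
#' effects act multiplicatively on the local-recurrence rate of arm B for the
#' stated effect duration. All entries can be overridden; values are yearly
#' rates, GBP costs, and utilities on the 0-1 scale.
#'
#' The default values are plausible stand-ins chosen so that the qualitative
#' behaviour of a typical adjuvant-therapy evaluation holds (B dominates with
#' little decision uncertainty); they are not fitted to any data set and every
#' one of them can be replaced via `...` or by editing the returned list.
#'
#' @param ... Named overrides replacing entries of the default list; nested
#'   entries are replaced wholesale (e.g. `rates = list(...)` must be a full
#'   rates list) or individually via [set_config_param()].
#' @return An object of class `markov_config`.
#' @examples
#' cfg <- markov_config()
#' tr <- run_cohort(cfg, "B")
#' tr$discounted_qalys
#' @export
markov_config <- function(...) {
  cfg <- list(
    states = c("well", "local_recurrence", "metastasis", "dead"),
    rates = list(
      local_recurrence = 0.04,  # well -> local recurrence, per year
      metastatic = 0.015,       # well -> metastasis
      lr_to_met = 0.12,         # local recurrence -> metastasis
      met_mortality = 0.35      # metastasis -> dead (disease-specific)
    ),
    # background mortality rate(age) = rate0 * exp(slope * age), all alive states
    background_mortality = list(rate0 = exp(-10), slope = 0.09),
    treatment_effects = list(
      intensity = 0.78,  # hazard ratio on local recurrence, arm B
      modality = 0.88,   # hazard ratio on local recurrence, arm B
      duration = 10      # years over which both effects apply (from cycle 0)
    ),
    utilities = list(
      well = 0.85,
      local_recurrence = 0.70,
      met_decrement = 0.25,     # utility with metastasis = well - decrement
      age_slope = 0.002         # utility loss per year of age from start_age
    ),
    costs = list(
      well = 150,               # yearly, well state
      well_first = 500,         # additional, first year in well state
      lr_first = 4000,          # first year after local recurrence
      lr_later = 1000,          # second and subsequent years
      met = 12000,              # yearly with metastatic disease
      intervention = list(
        A = list(sessions = 15, per_session = 130),
        B = list(sessions = 20, per_session = 140)
      )
    ),
    adverse_events = list(
      # short-term AE classes: none, 2a, 2b, 3; one-off cost/disutility at
      # cycle 0. Rows sum to < 1: the remainder is unclassified events, so
      # the named class probabilities are not exactly collinear in a PSA.
      prob = rbind(A = c(c0 = 0.78, c2a = 0.10, c2b = 0.06, c3 = 0.04),
                   B = c(c0 = 0.83, c2a = 0.07, c2b = 0.05, c3 = 0.03)),
      cost = c(c0 = 0, c2a = 200, c2b = 500, c3 = 2000),
      disutility = c(c0 = 0, c2a = 0.005, c2b = 0.01, c3 = 0.03),
      concentration = 150       # Dirichlet concentration for PSA sampling
    ),
    start_age = 55,
    horizon = 45,               # cycles
    cycle_length = 1,           # years
    discount = list(costs = 0.035, qalys = 0.035),
    k = 13000,                  # GBP per QALY
    incident_population = 24799 # patients per year
  )
  dots <- list(...)
  for (i in seq_along(dots)) {   # by index: later duplicates win
    nm <- names(dots)[i]
    if (!nm %in% names(cfg)) stop("unknown config entry: ", nm, call. = FALSE)
    cfg[[nm]] <- dots[[i]]
  }
  structure(cfg, class = "markov_config")
}

#' @export
print.markov_config <- function(x, ...) {
  cat("Markov case-study config: states",
      paste(x$states, collapse = ", "), "\n")
  cat("  horizon", x$horizon, "cycles of", x$cycle_length,
      "year(s), start age", x$start_age, "\n")
  cat("  k =", x$k, "GBP/QALY; incident population",
      x$incident_population, "/year\n")
  invisible(x)
}

# name -> (Table-style label, config location) for the 21 probabilistic inputs
.case_study_params <- list(
  rate_lr        = list(label = "Baseline rate of local recurrence",
                        path = c("rates", "local_recurrence")),
  rate_met       = list(label = "Baseline rate of metastatic disease",
                        path = c("rates", "metastatic")),
  rate_lr_met    = list(label = "Rate of metastatic disease following local recurrence",
                        path = c("rates", "lr_to_met")),
  rate_met_death = list(label = "Mortality rate with metastatic disease",
                        path = c("rates", "met_mortality")),
  rr_intensity   = list(label = "Relative effect for treatment intensity",
                        path = c("treatment_effects", "intensity")),
  rr_modality    = list(label = "Relative effect for the new modality",
                        path = c("treatment_effects", "modality")),
  u_well         = list(label = "Utility in well state",
                        path = c("utilities", "well")),
  u_lr           = list(label = "Utility with local recurrence",
                        path = c("utilities", "local_recurrence")),
  u_met_dec      = list(label = "Utility decrement from metastatic disease",
                        path = c("utilities", "met_decrement")),
  c_well         = list(label = "Yearly costs in well state",
                        path = c("costs", "well")),
  c_well_first   = list(label = "Additional costs in first year in well state",
                        path = c("costs", "well_first")),
  c_lr_first     = list(label = "Costs in first year after local recurrence",
                        path = c("costs", "lr_first")),
  c_lr_later     = list(label = "Yearly costs from second year after local recurrence",
                        path = c("costs", "lr_later")),
  c_met          = list(label = "Yearly costs with metastatic disease",
                        path = c("costs", "met")),
  p_ae2a_A       = list(label = "Probability of class 2a AE with A", ae = c("A", "c2a")),
  p_ae2b_A       = list(label = "Probability of class 2b AE with A", ae = c("A", "c2b")),
  p_ae3_A        = list(label = "Probability of class 3 AE with A",  ae = c("A", "c3")),
  p_ae0_B        = list(label = "Probability of class 0 AE with B",  ae = c("B", "c0")),
  p_ae2a_B       = list(label = "Probability of class 2a AE with B", ae = c("B", "c2a")),
  p_ae2b_B       = list(label = "Probability of class 2b AE with B", ae = c("B", "c2b")),
  p_ae3_B        = list(label = "Probability of class 3 AE with B",  ae = c("B", "c3"))
)

#' Look up or set a probabilistic parameter in a config
#'
#' Parameters are addressed by the short names used as PSA column names (see
#' [case_study_param_specs()] for the mapping to descriptive labels).
#' Adverse-event class probabilities are set verbatim; each must lie in
#' `[0, 1]` and the named classes of an arm must sum to at most 1 (any
#' remainder is unclassified events with zero cost and disutility).
#'
#' @param config A [markov_config()].
#' @param name Parameter short name, e.g. `"rate_lr"` or `"p_ae2a_B"`.
#' @param value Replacement value (scalar).
#' @return For `set_config_param`, the modified config; for
#'   `get_config_param`, the current value.
#' @export
set_config_param <- function(config, name, value) {
  info <- .case_study_params[[name]]
  if (is.null(info)) stop("unknown parameter: ", name, call. = FALSE)
  if (!is.null(info$ae)) {
    p <- config$adverse_events$prob
    if (value < 0 || value > 1) {
      stop("probability out of [0, 1] for ", name, call. = FALSE)
    }
    p[info$ae[1], info$ae[2]] <- value
    if (sum(p[info$ae[1], ]) > 1 + 1e-9) {
      stop("adverse-event probabilities of arm ", info$ae[1],
           " exceed 1 after setting ", name, call. = FALSE)
    }
    config$adverse_events$prob <- p
  } else {
    if (value < 0) stop("negative value for ", name, call. = FALSE)
    if (startsWith(name, "u_") && value > 1) {
      stop("utility parameter ", name, " above 1", call. = FALSE)
    }
    config[[info$path[1]]][[info$path[2]]] <- value
  }
  config
}

#' @rdname set_config_param
#' @export
get_config_param <- function(config, name) {
  info <- .case_study_params[[name]]
  if (is.null(info)) stop("unknown parameter: ", name, call. = FALSE)
  if (!is.null(info$ae)) {
    config$adverse_events$prob[info$ae[1], info$ae[2]]
  } else {
    config[[info$path[1]]][[info$path[2]]]
  }
}

#' Sampling specification for one model input
#'
#' @param name Short parameter name (PSA column name).
#' @param label Human-readable label.
#' @param kind `"probabilistic"` or `"deterministic"`.
#' @param distribution For probabilistic specs, a list with `family`
#'   (`"gamma"`, `"beta"`, `"lognormal"` or `"dirichlet_group"`) and its
#'   hyperparameters.
#' @param correlation_group Optional tag; specs sharing a tag are sampled
#'   jointly (used for the adverse-event probabilities).
#' @return An object of class `param_spec`.
#' @export
param_spec <- function(name, label = name,
                       kind = c("probabilistic", "deterministic"),
                       distribution = NULL, correlation_group = NULL) {
  kind <- match.arg(kind)
  if (kind == "probabilistic") {
    if (is.null(distribution$family)) {
      stop("probabilistic spec '", name, "' needs a distribution family",
           call. = FALSE)
    }
    fam <- distribution$family
    ok <- switch(fam,
      gamma = is.numeric(distribution$mean) && distribution$mean > 0 &&
        is.numeric(distribution$cv) && distribution$cv > 0,
      beta = is.numeric(distribution$mean) && distribution$mean > 0 &&
        distribution$mean < 1 && is.numeric(distribution$nu) && distribution$nu > 0,
      lognormal = is.numeric(distribution$median) && distribution$median > 0 &&
        is.numeric(distribution$sdlog) && distribution$sdlog >= 0,
      dirichlet_group = TRUE,
      stop("unknown distribution family: ", fam, call. = FALSE))
    if (!isTRUE(ok)) {
      stop("invalid hyperparameters for '", name, "' (", fam, ")", call. = FALSE)
    }
  }
  structure(list(name = name, label = label, kind = kind,
                 distribution = distribution,
                 correlation_group = correlation_group),
            class = "param_spec")
}

#' Default sampling specs for the case-study model
#'
#' The 21 probabilistic inputs: gamma distributions for rates and costs
#' (mean = the config value), beta for utilities, lognormal for the two
#' relative effects, and a correlated Dirichlet group for the adverse-event
#' class probabilities of both arms (classes within an arm live on the
#' simplex; the two arms are coupled through shared underlying draws).
#' Deterministic inputs (start age, discount rates, background mortality,
#' effect duration, utility-age slope, intervention cost components) are held
#' fixed during PSA.
#'
#' @param config A [markov_config()] supplying the means.
#' @param cv Default coefficient of variation for gamma-distributed inputs.
#' @param nu_utility Beta "effective sample size" for utilities.
#' @param sdlog_rr Log-scale SD of the two relative effects.
#' @return Named list of [param_spec()]s (probabilistic only).
#' @export
case_study_param_specs <- function(config = markov_config(), cv = 0.2,
                                   nu_utility = 150, sdlog_rr = 0.12) {
  g <- function(name) {
    param_spec(name, .case_study_params[[name]]$label, "probabilistic",
               list(family = "gamma", mean = get_config_param(config, name), cv = cv))
  }
  b <- function(name) {
    param_spec(name, .case_study_params[[name]]$label, "probabilistic",
               list(family = "beta", mean = get_config_param(config, name),
                    nu = nu_utility))
  }
  ln <- function(name) {
    param_spec(name, .case_study_params[[name]]$label, "probabilistic",
               list(family = "lognormal",
                    median = get_config_param(config, name), sdlog = sdlog_rr))
  }
  ae <- function(name) {
    param_spec(name, .case_study_params[[name]]$label, "probabilistic",
               list(family = "dirichlet_group"), correlation_group = "ae")
  }
  specs <- c(
    lapply(c("rate_lr", "rate_met", "rate_lr_met", "rate_met_death",
             "c_well", "c_well_first", "c_lr_first", "c_lr_later", "c_met"), g),
    lapply(c("u_well", "u_lr", "u_met_dec"), b),
    lapply(c("rr_intensity", "rr_modality"), ln),
    lapply(c("p_ae2a_A", "p_ae2b_A", "p_ae3_A",
             "p_ae0_B", "p_ae2a_B", "p_ae2b_B", "p_ae3_B"), ae)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Convert competing exponential rates to per-cycle transition probabilities
#'
#' Given a square matrix of yearly transition rates (off-diagonal entries;
#' the diagonal is ignored), the total exit probability from a state over one
#' cycle is `1 - exp(-sum(rates) * cycle_length)`, apportioned across
#' destinations proportionally to their rates (the standard competing-risks
#' conversion for constant hazards). Rows with zero total rate stay put.
#'
#' @param rates Square numeric matrix of rates per year, `rates[i, j]` the
#'   hazard of moving from state `i` to state `j`; all entries `>= 0`.
#' @param cycle_length Cycle length in years, `> 0`.
#' @return A stochastic matrix of the same dimension (rows sum to 1).
#' @examples
#' q <- matrix(0, 2, 2); q[1, 2] <- log(2)
#' rates_to_cycle_probabilities(q, 1)[1, 2]  # 0.5
#' @export
rates_to_cycle_probabilities <- function(rates, cycle_length = 1) {
  rates <- as.matrix(rates)
  if (nrow(rates) != ncol(rates)) stop("rates must be square", call. = FALSE)
  if (cycle_length <= 0) stop("cycle_length must be > 0", call. = FALSE)
  diag(rates) <- 0
  if (any(rates < 0)) stop("negative transition rate", call. = FALSE)
  n <- nrow(rates)
  P <- matrix(0, n, n, dimnames = dimnames(rates))
  tot <- rowSums(rates)
  for (i in seq_len(n)) {
    if (tot[i] == 0) {
      P[i, i] <- 1
    } else {
      exit <- 1 - exp(-tot[i] * cycle_length)
      P[i, ] <- exit * rates[i, ] / tot[i]
      P[i, i] <- 1 - exit
    }
  }
  P
}

# Internal 5-state rate matrix for cycle t (age-dependent via background
# mortality); rr is the multiplicative effect on the local-recurrence rate.
.cycle_rate_matrix <- function(config, age, rr) {
  bg <- config$background_mortality$rate0 *
    exp(config$background_mortality$slope * age)
  r <- config$rates
  q <- matrix(0, 5, 5, dimnames = list(.markov_internal_states,
                                       .markov_internal_states))
  q["well", "lr1"] <- r$local_recurrence * rr
  q["well", "met"] <- r$metastatic
  q["well", "dead"] <- bg
  q["lr1", "met"] <- r$lr_to_met
  q["lr1", "dead"] <- bg
  q["lr2", "met"] <- r$lr_to_met
  q["lr2", "dead"] <- bg
  q["met", "dead"] <- r$met_mortality + bg
  q
}

#' Run the cohort model for one treatment arm
#'
#' Simulates the cohort over the configured horizon with annual-style cycles
#' and no half-cycle correction: state membership at the start of each cycle
#' earns that cycle's utility and state costs, discounted at
#' `(1 + rate)^-t` with cycle 0 undiscounted. One-off quantities at cycle 0:
#' the additional first-year well-state cost, the intervention cost
#' (sessions x cost per session), and the expected adverse-event cost and
#' QALY loss for the arm. Treatment B's two relative effects multiply the
#' local-recurrence rate from cycle 0 until the effect duration expires.
#'
#' @param config A [markov_config()].
#' @param treatment `"A"` (comparator, current practice) or `"B"`.
#' @return An object of class `cohort_trace`: list with `occupancy`
#'   (`horizon + 1` rows, one per cycle start, over the four reported states
#'   with the two internal local-recurrence tunnel states collapsed),
#'   `discounted_qalys` and `discounted_costs` (per patient).
#' @export
run_cohort <- function(config, treatment = c("A", "B")) {
  stopifnot(inherits(config, "markov_config"))
  treatment <- match.arg(treatment)
  H <- config$horizon
  if (H < 1) stop("horizon must be >= 1", call. = FALSE)
  dt <- config$cycle_length
  u <- config$utilities
  cs <- config$costs
  rr_b <- config$treatment_effects$intensity * config$treatment_effects$modality
  dur <- config$treatment_effects$duration
  disc_q <- 1 / (1 + config$discount$qalys)
  disc_c <- 1 / (1 + config$discount$costs)

  occ <- matrix(0, H + 1L, 5L,
                dimnames = list(NULL, .markov_internal_states))
  occ[1L, "well"] <- 1
  qalys <- 0
  costs <- 0
  u_met <- u$well - u$met_decrement
  state_u <- c(well = u$well, lr1 = u$local_recurrence,
               lr2 = u$local_recurrence, met = u_met, dead = 0)
  state_c <- c(well = cs$well, lr1 = cs$lr_first, lr2 = cs$lr_later,
               met = cs$met, dead = 0)
  alive <- c(1, 1, 1, 1, 0)

  for (t in 0:(H - 1L)) {
    age <- config$start_age + t * dt
    x <- occ[t + 1L, ]
    # rewards for cycle t from state membership at its start
    u_t <- pmax(state_u - u$age_slope * (age - config$start_age), 0) * alive
    qalys <- qalys + sum(x * u_t) * dt * disc_q^t
    costs <- costs + sum(x * state_c) * dt * disc_c^t
    if (t == 0L) {
      costs <- costs + x[["well"]] * cs$well_first
      iv <- cs$intervention[[treatment]]
      costs <- costs + iv$sessions * iv$per_session
      aep <- config$adverse_events$prob[treatment, ]
      costs <- costs + sum(aep * config$adverse_events$cost)
      qalys <- qalys - sum(aep * config$adverse_events$disutility)
    }
    rr <- if (treatment == "B" && t * dt < dur) rr_b else 1
    P <- rates_to_cycle_probabilities(.cycle_rate_matrix(config, age, rr), dt)
    # first-year recurrence tunnel: survivors of lr1 age into lr2
    P["lr1", "lr2"] <- P["lr1", "lr2"] + P["lr1", "lr1"]
    P["lr1", "lr1"] <- 0
    occ[t + 2L, ] <- as.numeric(x %*% P)
  }
  reported <- cbind(well = occ[, "well"],
                    local_recurrence = occ[, "lr1"] + occ[, "lr2"],
                    metastasis = occ[, "met"],
                    dead = occ[, "dead"])
  structure(list(occupancy = reported, occupancy_internal = occ,
                 discounted_qalys = qalys, discounted_costs = costs,
                 treatment = treatment),
            class = "cohort_trace")
}

#' Deterministic incremental results at the configured parameter values
#'
#' Runs both arms of the cohort model and returns incremental QALYs, costs
#' and net benefit (QALY units) at the threshold in the config.
#'
#' @param config A [markov_config()].
#' @return List with `delta_qalys`, `delta_costs`, `inb`.
#' @export
markov_inb <- function(config) {
  a <- run_cohort(config, "A")
  b <- run_cohort(config, "B")
  dq <- b$discounted_qalys - a$discounted_qalys
  dc <- b$discounted_costs - a$discounted_costs
  list(delta_qalys = dq, delta_costs = dc, inb = dq - dc / config$k)
}

# Apply one PSA draw (named vector) to a config. Adverse-event cells are
# written jointly and validated once, so the order of assignment cannot
# trip the per-arm sum constraint mid-update.
.apply_draw <- function(config, values) {
  nms <- names(values)
  is_ae <- vapply(nms, function(nm) !is.null(.case_study_params[[nm]]$ae),
                  logical(1))
  for (nm in nms[!is_ae]) {
    config <- set_config_param(config, nm, values[[nm]])
  }
  if (any(is_ae)) {
    p <- config$adverse_events$prob
    set_cells <- character(0)
    for (nm in nms[is_ae]) {
      cell <- .case_study_params[[nm]]$ae
      p[cell[1], cell[2]] <- values[[nm]]
      set_cells <- c(set_cells, paste(cell, collapse = "."))
    }
    # a class-0 cell that is not itself a sampled column absorbs the arm's
    # slack (class 0 carries zero cost and disutility, so outcomes are
    # unaffected by its exact value)
    for (arm in rownames(p)) {
      if (!paste(arm, "c0", sep = ".") %in% set_cells) {
        others <- sum(p[arm, setdiff(.ae_classes, "c0")])
        p[arm, "c0"] <- max(0, min(p[arm, "c0"], 1 - others))
      }
    }
    if (any(p < 0) || any(rowSums(p) > 1 + 1e-9)) {
      stop("adverse-event probabilities invalid after applying draw",
           call. = FALSE)
    }
    config$adverse_events$prob <- p
  }
  config
}

# Sample one matrix of probabilistic parameter values (n x 21). The AE group
# uses per-arm Dirichlet draws built from gamma variates that share uniforms
# across arms (a comonotone copula), inducing the stated positive correlation
# between the arms' class probabilities while keeping each arm on the simplex.
.sample_param_matrix <- function(config, specs, n) {
  indep <- Filter(function(s) is.null(s$correlation_group), specs)
  cols <- list()
  for (s in indep) {
    d <- s$distribution
    cols[[s$name]] <- switch(d$family,
      gamma = {
        shape <- 1 / d$cv^2
        stats::rgamma(n, shape = shape, rate = shape / d$mean)
      },
      beta = stats::rbeta(n, d$mean * d$nu, (1 - d$mean) * d$nu),
      lognormal = stats::rlnorm(n, meanlog = log(d$median), sdlog = d$sdlog),
      stop("unsupported family for independent sampling: ", d$family,
           call. = FALSE))
  }
  ae_specs <- Filter(function(s) identical(s$correlation_group, "ae"), specs)
  if (length(ae_specs) > 0) {
    conc <- config$adverse_events$concentration
    # Dirichlet over the named classes plus an unclassified remainder so the
    # named probabilities sum to < 1 (and are not exactly collinear)
    pr <- config$adverse_events$prob
    rest <- 1 - rowSums(pr)
    if (any(rest < 0)) stop("AE class probabilities sum above 1", call. = FALSE)
    alpha <- cbind(pr, rest = pmax(rest, 1e-6)) * conc
    if (any(alpha <= 0)) stop("invalid Dirichlet hyperparameters", call. = FALSE)
    nc <- ncol(alpha)
    u <- matrix(stats::runif(n * nc), n, nc)
    gA <- sapply(seq_len(nc), function(j) stats::qgamma(u[, j], shape = alpha["A", j]))
    gB <- sapply(seq_len(nc), function(j) stats::qgamma(u[, j], shape = alpha["B", j]))
    pA <- (gA / rowSums(gA))[, seq_len(4)]
    pB <- (gB / rowSums(gB))[, seq_len(4)]
    colnames(pA) <- colnames(pB) <- .ae_classes
    ae_cols <- list(p_ae2a_A = pA[, "c2a"], p_ae2b_A = pA[, "c2b"],
                    p_ae3_A = pA[, "c3"], p_ae0_B = pB[, "c0"],
                    p_ae2a_B = pB[, "c2a"], p_ae2b_B = pB[, "c2b"],
                    p_ae3_B = pB[, "c3"])
    cols <- c(cols, ae_cols[intersect(names(ae_cols),
                                      vapply(ae_specs, `[[`, character(1), "name"))])
  }
  do.call(cbind, cols[intersect(names(specs), names(cols))])
}

#' Probabilistic sensitivity analysis of the case-study model
#'
#' Jointly samples every probabilistic parameter from its spec, runs both
#' treatment arms of the cohort model per draw and assembles a
#' [psa_result()]. Deterministic inputs stay at their config values.
#' Reproducible: the same `seed` yields a bitwise-identical result.
#'
#' @param config A [markov_config()].
#' @param specs Sampling specs, default [case_study_param_specs()].
#' @param n_draws Number of PSA draws, `>= 1`.
#' @param seed Optional integer seed (local to this call).
#' @return A [psa_result()] whose `correlation_groups` tags the seven
#'   adverse-event probability columns.
#' @export
sample_psa <- function(config = markov_config(),
                       specs = case_study_param_specs(config),
                       n_draws = 1000, seed = NULL) {
  stopifnot(inherits(config, "markov_config"), n_draws >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  draws <- .sample_param_matrix(config, specs, n_draws)
  if (is.null(draws)) draws <- matrix(numeric(0), n_draws, 0L)
  qa <- qb <- ca <- cb <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    cfg_i <- .apply_draw(config, draws[i, ])
    ta <- run_cohort(cfg_i, "A")
    tb <- run_cohort(cfg_i, "B")
    qa[i] <- ta$discounted_qalys; ca[i] <- ta$discounted_costs
    qb[i] <- tb$discounted_qalys; cb[i] <- tb$discounted_costs
  }
  groups <- NULL
  ae_names <- names(Filter(function(s) identical(s$correlation_group, "ae"), specs))
  if (length(ae_names)) groups <- list(ae_probabilities = ae_names)
  psa_result(
    draws = draws,
    outcomes = list(strategy_outcomes("A", qa, ca),
                    strategy_outcomes("B", qb, cb)),
    k = config$k,
    incident_population = config$incident_population,
    correlation_groups = groups
  )
}
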