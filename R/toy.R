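#' Linear-Gaussian toy decision model
#'
#' An analytic oracle for value-of-information estimators. The incremental net
#' benefit is the sum of independent normal parameters,
#' `INB = sum_j theta_j`, `theta_j ~ N(mean_j, sd_j^2)`, so EVPI and every
#' subset EVPPI have closed forms via the normal partial expectation (see
#' [toy_true_evpi()]).
#'
#' The returned [psa_result()] encodes the toy as a "cost-free" comparison:
#' the comparator has zero QALYs and costs, the intervention has per-draw
#' QALYs equal to the INB, so [compute_inb()] recovers it exactly for any `k`.
#'
#' @param means,sds Numeric vectors (recycled to common length) of parameter
#'   means and standard deviations; `sds >= 0`.
#' @param n_draws Number of PSA draws.
#' @param seed Optional integer seed (local to this call).
#' @param k Threshold carried in the result (irrelevant to the toy's INB).
#' @param incident_population Population scaling carried in the result.
#' @return A [psa_result()] with parameters named `theta1, theta2, ...`.
#' @examples
#' psa <- linear_gaussian_toy(means = c(0, 0), sds = c(1, 1),
#'                            n_draws = 1000, seed = 42)
#' toy_true_evpi(c(0, 0), c(1, 1))            # EVPI = sqrt(2) * dnorm(0)
#' toy_true_evpi(c(0, 0), c(1, 1), subset = 1) # EVPPI(theta1) = dnorm(0)
#' @export
linear_gaussian_toy <- function(means, sds, n_draws, seed = NULL,
                                k = 13000, incident_population = 0) {
  p <- max(length(means), length(sds))
  means <- rep_len(as.numeric(means), p)
  sds <- rep_len(as.numeric(sds), p)
  if (any(sds < 0)) stop("sds must be >= 0", call. = FALSE)
  if (n_draws < 1L) stop("n_draws must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  draws <- matrix(stats::rnorm(n_draws * p, mean = rep(means, each = n_draws),
                               sd = rep(sds, each = n_draws)),
                  nrow = n_draws, ncol = p,
                  dimnames = list(NULL, paste0("theta", seq_len(p))))
  inb <- rowSums(draws)
  psa_result(
    draws = draws,
    outcomes = list(
      strategy_outcomes("A", qalys = numeric(n_draws), costs = numeric(n_draws)),
      strategy_outcomes("B", qalys = inb, costs = numeric(n_draws))
    ),
    k = k, incident_population = incident_population
  )
}

#' Closed-form EVPI / EVPPI of the linear-Gaussian toy
#'
#' For `INB ~ N(mu, sigma^2)` the per-person EVPI is
#' `sigma * dnorm(mu/sigma) - mu * pnorm(-mu/sigma)` for `mu >= 0` (and
#' symmetric for `mu < 0`: `E[max(0, INB)] - max(0, mu)` in general). EVPPI of
#' a subset S replaces `sigma^2` by `sum_{j in S} sd_j^2`, because the
#' conditional expectation of INB given theta_S is normal with that variance
#' around `mu`.
#'
#' @param means,sds Toy parameter means and standard deviations.
#' @param subset Indices (or names `thetaJ`) of the known subset; `NULL` means
#'   all parameters, i.e. the EVPI.
#' @return Per-person value in QALYs.
#' @export
toy_true_evpi <- function(means, sds, subset = NULL) {
  p <- max(length(means), length(sds))
  means <- rep_len(as.numeric(means), p)
  sds <- rep_len(as.numeric(sds), p)
  mu <- sum(means)
  if (is.null(subset)) subset <- seq_len(p)
  if (is.character(subset)) subset <- match(subset, paste0("theta", seq_len(p)))
  sigma <- sqrt(sum(sds[subset]^2))
  if (sigma == 0) return(0)
  # E[max(0, X)] - max(0, mu), X ~ N(mu, sigma^2)
  emax <- mu * stats::pnorm(mu / sigma) + sigma * stats::dnorm(mu / sigma)
  emax - max(0, mu)
}
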