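# EVPI from PSA draws and regression-based EVPPI for parameter subsets.
#
# With two strategies and INB oriented intervention-vs-comparator,
#   EVPI  = E[max(0, INB)] - max(0, E[INB])
#   EVPPI(S) = E[max(0, E[INB | theta_S])] - max(0, E[INB]),
# the inner conditional expectation estimated by a penalized spline
# regression of per-draw INB on the subset's draws (GAM metamodel).

.new_voi_estimate <- function(per_person, raw, se, subset, n_draws,
                              population, kind) {
  structure(list(
    per_person = per_person,
    population_scaled = per_person * population,
    standard_error = se,
    subset = subset,
    n_draws = n_draws,
    incident_population = population,
    raw = raw,            # unclipped estimate, kept for audit
    kind = kind
  ), class = "voi_estimate")
}

#' @export
print.voi_estimate <- function(x, ...) {
  lab <- if (x$kind == "evpi") "EVPI" else
    paste0("EVPPI(", paste(x$subset, collapse = ", "), ")")
  cat(sprintf("%s: %.6g QALYs/person (SE %.2g)", lab, x$per_person,
              x$standard_error))
  if (x$incident_population > 0) {
    cat(sprintf("; %.6g population QALYs (x %g/year)",
                x$population_scaled, x$incident_population))
  }
  cat("\n")
  invisible(x)
}

#' Expected value of perfect information
#'
#' Per-person EVPI from PSA output: the expected gain from resolving all
#' parameter uncertainty before choosing between the two strategies. The
#' Monte-Carlo standard error comes from the delta method: when the optimal
#' strategy under current information is the intervention the estimator is a
#' mean of `max(0, INB_i) - INB_i`, otherwise of `max(0, INB_i)`.
#'
#' @param x A [psa_result()] or an INB vector from [compute_inb()].
#' @param ... Unused.
#' @return A `voi_estimate` with per-person and population-scaled values.
#' @examples
#' evpi(c(-1, 1))  # 0.5
#' @export
evpi <- function(x, ...) UseMethod("evpi")

#' @export
evpi.psa_result <- function(x, ...) evpi(compute_inb(x), ...)

#' @export
evpi.default <- function(x, ...) {
  inb <- as.numeric(x)
  n <- length(inb)
  if (n < 2L) stop("EVPI needs at least 2 draws", call. = FALSE)
  if (anyNA(inb)) stop("missing values in INB", call. = FALSE)
  pop <- attr(x, "incident_population")
  if (is.null(pop)) pop <- 0
  gains <- if (mean(inb) > 0) pmax(0, inb) - inb else pmax(0, inb)
  est <- mean(pmax(0, inb)) - max(0, mean(inb))
  se <- stats::sd(gains) / sqrt(n)
  .new_voi_estimate(est, raw = est, se = se, subset = character(0),
                    n_draws = n, population = pop, kind = "evpi")
}

# basis dimension heuristic: 4 * ceiling(n^0.2), capped by distinct values
.evppi_basis_dim <- function(n, x) {
  k <- 4L * as.integer(ceiling(n^0.2))
  min(k, max(3L, length(unique(x)) - 1L), 30L)
}

.evppi_fit <- function(inb, X, basis_dim = NULL) {
  n <- length(inb)
  d <- ncol(X)
  df <- data.frame(..y = inb, X, check.names = FALSE)
  engine <- if (n > 20000L) function(f) {
    mgcv::bam(f, data = df, discrete = TRUE)
  } else function(f) mgcv::gam(f, data = df)
  q <- function(v) paste0("`", v, "`")
  if (d == 1L) {
    k <- if (is.null(basis_dim)) .evppi_basis_dim(n, X[, 1]) else basis_dim
    f <- stats::as.formula(paste0("..y ~ s(", q(colnames(X)), ", k = ", k, ")"))
  } else if (d == 2L) {
    # low-rank tensor product captures interactions between the pair
    kt <- if (is.null(basis_dim)) 5L else basis_dim
    f <- stats::as.formula(paste0("..y ~ te(", q(colnames(X)[1]), ", ",
                                  q(colnames(X)[2]),
                                  ", k = c(", kt, ", ", kt, "))"))
  } else {
    # additive spline basis; interactions beyond pairs are not modelled
    k <- if (is.null(basis_dim)) max(5L, min(10L, .evppi_basis_dim(n, X[, 1])))
         else basis_dim
    terms <- paste0("s(", q(colnames(X)), ", k = ", k, ")", collapse = " + ")
    f <- stats::as.formula(paste0("..y ~ ", terms))
  }
  as.numeric(stats::fitted(engine(f)))
}

#' Expected value of partial perfect information for a parameter subset
#'
#' Regresses per-draw INB on the subset's parameter draws with a penalized
#' spline smoother (thin-plate spline for one parameter, a low-rank tensor
#' product for two, an additive spline basis beyond that), then evaluates
#' `mean(max(0, fitted)) - max(0, mean(INB))`. Negative raw estimates are
#' clipped to zero in `per_person` (pure estimation noise; the raw value is
#' kept in the `raw` field). The standard error is a nonparametric bootstrap
#' over draws of `(fitted, INB)` pairs; it reflects Monte-Carlo error but not
#' smoother-refit uncertainty.
#'
#' Estimates carry an upward bias that grows with subset size and shrinks
#' with `n_draws`; cumulative rankings can therefore exceed the EVPI (and an
#' update metric can exceed 100%).
#'
#' @param psa A [psa_result()].
#' @param subset Character vector of parameter names, `1 <= length <=
#'   max_subset`.
#' @param max_subset Safety cap on subset size (default 5); nonparametric
#'   regression in many dimensions is unreliable — raise explicitly if you
#'   accept that.
#' @param basis_dim Optional basis dimension override (per smooth; per margin
#'   for the two-parameter tensor product). Default `4 * ceiling(n^0.2)`
#'   capped by the data.
#' @param n_boot Bootstrap replicates for the SE (0 to skip).
#' @return A `voi_estimate`.
#' @examples
#' psa <- linear_gaussian_toy(c(0, 0), c(1, 1), n_draws = 2000, seed = 7)
#' evppi(psa, "theta1")
#' @export
evppi <- function(psa, subset, max_subset = 5L, basis_dim = NULL,
                  n_boot = 200L) {
  stopifnot(inherits(psa, "psa_result"))
  subset <- as.character(subset)
  if (length(subset) < 1L) stop("empty parameter subset", call. = FALSE)
  unknown <- setdiff(subset, psa$param_names)
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(subset) > max_subset) {
    stop("subset has ", length(subset), " parameters, above the cap of ",
         max_subset, "; raise max_subset explicitly if intended",
         call. = FALSE)
  }
  inb <- as.numeric(compute_inb(psa))
  n <- length(inb)
  if (n < 100L) stop("EVPPI regression needs at least 100 draws", call. = FALSE)
  X <- psa$draws[, subset, drop = FALSE]
  const <- apply(X, 2L, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("constant (deterministic) parameter(s) in subset: ",
            paste(subset[const], collapse = ", "),
            if (all(const)) "; EVPPI is 0" else "; dropped from regression",
            call. = FALSE)
    if (all(const)) {
      return(.new_voi_estimate(0, raw = 0, se = 0, subset = subset,
                               n_draws = n,
                               population = psa$incident_population,
                               kind = "evppi"))
    }
    X <- X[, !const, drop = FALSE]
  }
  g <- .evppi_fit(inb, X, basis_dim)
  base <- max(0, mean(inb))
  raw <- mean(pmax(0, g)) - base
  se <- 0
  if (n_boot > 0L) {
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      mean(pmax(0, g[idx])) - max(0, mean(inb[idx]))
    }, numeric(1))
    se <- stats::sd(reps)
  }
  .new_voi_estimate(max(0, raw), raw = raw, se = se, subset = subset,
                    n_draws = n, population = psa$incident_population,
                    kind = "evppi")
}
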