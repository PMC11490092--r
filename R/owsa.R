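# Percent-rescaled OLS semielasticities, the adaptation metric, and a direct
# one-at-a-time OWSA for cross-checking the metamodel on (near-)linear models.

#' Fit the percent-rescaled semielasticity metamodel
#'
#' Rescales every usable PSA parameter column to percentage differences from
#' its mean, `z = 100 * (x - mean(x)) / mean(x)`, and fits ordinary least
#' squares of per-draw INB on all rescaled inputs plus an intercept. Each
#' coefficient is then the change in INB per 1% increase in that input
#' (a 1% semielasticity). Rows are ranked by absolute semielasticity; the
#' cumulative adaptation metric is the running sum of the normalized
#' absolute semielasticities, computed from unrounded values.
#'
#' Constant (deterministic) columns are excluded silently — they carry no
#' variation for OLS. Columns whose sample mean is numerically zero are
#' excluded with a warning: "percent of mean" is undefined there.
#'
#' @param psa A [psa_result()].
#' @param r_squared_warn Warn when the metamodel R-squared falls below this
#'   linearity threshold (default 0.8).
#' @return A `semielasticity_table`: data frame with columns `parameter`,
#'   `rank`, `semielasticity`, `std_error`, `proportion` and
#'   `adaptation_metric` (%), with attributes `r_squared` and `excluded`.
#' @examples
#' psa <- linear_gaussian_toy(c(0.1, 0.2), c(0.05, 0.05), 500, seed = 3)
#' fit_semielasticity_metamodel(psa)
#' @export
fit_semielasticity_metamodel <- function(psa, r_squared_warn = 0.8) {
  stopifnot(inherits(psa, "psa_result"))
  inb <- as.numeric(compute_inb(psa))
  X <- psa$draws
  n <- nrow(X)
  if (n <= ncol(X) + 1L) {
    stop("need more draws than parameters for OLS (", n, " draws, ",
         ncol(X), " parameters)", call. = FALSE)
  }
  sds <- apply(X, 2L, stats::sd)
  mns <- colMeans(X)
  const <- sds == 0
  # a mean statistically indistinguishable from zero makes percent-of-mean
  # rescaling explosive and sign-unstable
  zero_mean <- !const & abs(mns) < 2.5 * sds / sqrt(n)
  if (any(zero_mean)) {
    warning("excluded parameter(s) with sample mean ~ 0 (percent rescaling ",
            "undefined): ", paste(colnames(X)[zero_mean], collapse = ", "),
            call. = FALSE)
  }
  keep <- !const & !zero_mean
  excluded <- colnames(X)[!keep]
  if (!any(keep)) stop("no usable parameter columns", call. = FALSE)
  Xk <- X[, keep, drop = FALSE]
  Z <- sweep(sweep(Xk, 2L, colMeans(Xk)), 2L, colMeans(Xk), "/") * 100

  if (stats::sd(inb) == 0) {
    warning("INB is constant across draws; all semielasticities are 0 and ",
            "R-squared is undefined", call. = FALSE)
    out <- data.frame(parameter = colnames(Z), rank = seq_len(ncol(Z)),
                      semielasticity = 0, std_error = 0,
                      proportion = 0, adaptation_metric = 0,
                      row.names = NULL)
    return(structure(out, r_squared = NA_real_, excluded = excluded,
                     class = c("semielasticity_table", "data.frame")))
  }

  fit <- stats::lm(inb ~ Z)
  cf <- stats::coef(fit)[-1L]
  if (anyNA(cf)) {
    bad <- sub("^Z", "", names(cf)[is.na(cf)])
    stop("rank-deficient metamodel design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ses <- sm$coefficients[-1L, "Std. Error"]
  r2 <- sm$r.squared
  if (r2 < r_squared_warn) {
    warning(sprintf(paste0("metamodel R-squared %.3f is below %.2f; the ",
                           "model may be too nonlinear for OLS ",
                           "semielasticities"), r2, r_squared_warn),
            call. = FALSE)
  }
  pars <- colnames(Z)
  ord <- order(-abs(cf), pars)
  cf <- cf[ord]; ses <- ses[ord]; pars <- pars[ord]
  prop <- if (sum(abs(cf)) > 0) abs(cf) / sum(abs(cf)) else rep(0, length(cf))
  out <- data.frame(
    parameter = pars,
    rank = seq_along(pars),
    semielasticity = unname(cf),
    std_error = unname(ses),
    proportion = unname(prop),
    adaptation_metric = 100 * cumsum(unname(prop)),
    row.names = NULL
  )
  structure(out, r_squared = r2, excluded = excluded,
            class = c("semielasticity_table", "data.frame"))
}

#' @export
print.semielasticity_table <- function(x, ...) {
  cat("Semielasticity ranking (adaptation prioritization)\n")
  r2 <- attr(x, "r_squared")
  cat("Metamodel R-squared:",
      if (is.na(r2)) "undefined (constant INB)" else sprintf("%.3f", r2), "\n\n")
  df <- as.data.frame(x)
  df$semielasticity <- round(df$semielasticity, 4)
  df$std_error <- round(df$std_error, 4)
  df$proportion <- round(df$proportion, 4)
  df$adaptation_metric <- round(df$adaptation_metric, 1)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Adaptation metric for the top-ranked parameters
#'
#' `100 * sum` of the normalized absolute-semielasticity proportions of the
#' `top_r` highest-ranked parameters: the share of total one-way sensitivity
#' captured if exactly those parameters are adapted. Equals 100% at the full
#' set by construction.
#'
#' @param table A `semielasticity_table` from
#'   [fit_semielasticity_metamodel()].
#' @param top_r Number of top-ranked parameters adapted, `0 <= top_r <=
#'   nrow(table)`.
#' @return Percentage.
#' @export
adaptation_metric <- function(table, top_r) {
  stopifnot(inherits(table, "semielasticity_table"))
  top_r <- as.integer(top_r)
  if (length(top_r) != 1L || is.na(top_r) || top_r < 0L ||
      top_r > nrow(table)) {
    stop("top_r must be between 0 and ", nrow(table), call. = FALSE)
  }
  100 * sum(table$proportion[seq_len(top_r)])
}

#' Direct one-at-a-time OWSA perturbation
#'
#' Evaluates the change in deterministic INB when one parameter is moved
#' `delta_pct` percent above its expected value with every other input held
#' at its expected value. On an exactly linear model this equals the
#' metamodel semielasticity (for `delta_pct = 1`) to numerical precision.
#'
#' @param model_runner Function `config -> scalar INB`. `NULL` with a
#'   [markov_config()] uses the bundled cohort model ([markov_inb()]).
#' @param config A [markov_config()] or a plain named list of expected
#'   parameter values.
#' @param parameter Name of the parameter to perturb.
#' @param delta_pct Percent perturbation (default 1).
#' @return The change in INB (QALYs).
#' @export
manual_owsa <- function(model_runner, config, parameter, delta_pct = 1) {
  if (is.null(model_runner)) {
    if (!inherits(config, "markov_config")) {
      stop("model_runner is required unless config is a markov_config",
           call. = FALSE)
    }
    model_runner <- function(cfg) markov_inb(cfg)$inb
  }
  if (inherits(config, "markov_config")) {
    base_val <- get_config_param(config, parameter)
    perturbed <- set_config_param(config, parameter,
                                  base_val * (1 + delta_pct / 100))
  } else {
    if (!parameter %in% names(config)) {
      stop("unknown parameter: ", parameter, call. = FALSE)
    }
    perturbed <- config
    perturbed[[parameter]] <- config[[parameter]] * (1 + delta_pct / 100)
  }
  model_runner(perturbed) - model_runner(config)
}
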