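#' Per-strategy PSA outcomes
#'
#' Bundle the per-draw discounted outcomes of one strategy.
#'
#' @param label Strategy label (e.g. `"A"`).
#' @param qalys Numeric vector of discounted QALYs, one entry per PSA draw.
#' @param costs Numeric vector of discounted costs (GBP), same length.
#' @return An object of class `strategy_outcomes`.
#' @export
strategy_outcomes <- function(label, qalys, costs) {
  stopifnot(is.character(label), length(label) == 1L)
  qalys <- as.numeric(qalys)
  costs <- as.numeric(costs)
  if (length(qalys) < 1L || length(qalys) != length(costs)) {
    stop("qalys and costs must have identical length >= 1", call. = FALSE)
  }
  if (anyNA(qalys) || anyNA(costs)) {
    stop("missing values in strategy outcomes are not allowed: PSA rows are ",
         "jointly sampled and cannot be partially dropped", call. = FALSE)
  }
  structure(list(label = label, qalys = qalys, costs = costs),
            class = "strategy_outcomes")
}

#' Probabilistic sensitivity analysis result
#'
#' The universal exchange object: a matrix of jointly sampled parameter values
#' aligned row-by-row with per-draw strategy outcomes, plus the
#' cost-effectiveness threshold and the incident population used for
#' population scaling.
#'
#' @param draws Numeric matrix, `n_draws x n_params`, of sampled parameter
#'   values. Column names (or `param_names`) label the parameters.
#' @param outcomes List of exactly two [strategy_outcomes()]: comparator first,
#'   intervention second. More than two strategies is an error (the
#'   one-way-sensitivity machinery is defined for two alternatives only).
#' @param k Cost-effectiveness threshold in GBP per QALY; must be positive.
#' @param incident_population Patients per year used to scale per-person
#'   value-of-information estimates; non-negative.
#' @param param_names Optional character vector overriding column names.
#' @param correlation_groups Optional named list tagging groups of parameter
#'   names that were sampled jointly (e.g. adverse-event probabilities); used
#'   by [conditional_evppi_ranking()] when grouping is requested.
#' @return An object of class `psa_result`.
#' @seealso [compute_inb()], [evpi()], [evppi()]
#' @export
psa_result <- function(draws, outcomes, k, incident_population = 0,
                       param_names = NULL, correlation_groups = NULL) {
  draws <- as.matrix(draws)
  storage.mode(draws) <- "double"
  if (!is.null(param_names)) colnames(draws) <- param_names
  if (is.null(colnames(draws)) && ncol(draws) > 0L) {
    colnames(draws) <- paste0("param", seq_len(ncol(draws)))
  }
  if (anyDuplicated(colnames(draws))) {
    stop("parameter names must be unique", call. = FALSE)
  }
  if (anyNA(draws)) {
    stop("missing values in PSA draws are not allowed", call. = FALSE)
  }
  if (!is.list(outcomes) || length(outcomes) != 2L ||
      !all(vapply(outcomes, inherits, logical(1), "strategy_outcomes"))) {
    stop("outcomes must be a list of exactly 2 strategy_outcomes ",
         "(comparator, intervention); >2 strategies is not supported",
         call. = FALSE)
  }
  n <- nrow(draws)
  if (any(vapply(outcomes, function(o) length(o$qalys), integer(1)) != n)) {
    stop("draw count mismatch between parameter draws and strategy outcomes",
         call. = FALSE)
  }
  k <- as.numeric(k)
  if (length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("threshold k must be a single positive number (GBP per QALY)",
         call. = FALSE)
  }
  incident_population <- as.numeric(incident_population)
  if (incident_population < 0) stop("incident_population must be >= 0", call. = FALSE)
  structure(list(
    draws = draws,
    param_names = colnames(draws),
    outcomes = outcomes,
    k = k,
    incident_population = incident_population,
    correlation_groups = correlation_groups
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("PSA result: ", nrow(x$draws), " draws x ", ncol(x$draws),
      " parameters\n", sep = "")
  cat("  strategies: ", x$outcomes[[1]]$label, " (comparator) vs ",
      x$outcomes[[2]]$label, " (intervention)\n", sep = "")
  cat("  k = ", format(x$k), " GBP/QALY; incident population = ",
      format(x$incident_population), "/year\n", sep = "")
  invisible(x)
}

#' Incremental net benefit per PSA draw
#'
#' INB in health (QALY) units: `(QALY_B - QALY_A) - (Cost_B - Cost_A)/k`,
#' intervention minus comparator. Positive values favour the intervention.
#'
#' @param psa A [psa_result()].
#' @param monetary If `TRUE` the vector is additionally returned on the net
#'   monetary benefit scale (`INB * k`) in the `"nmb"` attribute; the primary
#'   values are always in QALYs.
#' @return Numeric vector of class `inb` with attributes `k`,
#'   `incident_population` and `orientation` (`"<intervention> vs <comparator>"`).
#' @examples
#' psa <- linear_gaussian_toy(means = c(0.1, 0), sds = c(0.05, 0.02),
#'                            n_draws = 100, seed = 1)
#' inb <- compute_inb(psa)
#' mean(inb)
#' @export
compute_inb <- function(psa, monetary = FALSE) {
  stopifnot(inherits(psa, "psa_result"))
  a <- psa$outcomes[[1]]
  b <- psa$outcomes[[2]]
  values <- (b$qalys - a$qalys) - (b$costs - a$costs) / psa$k
  out <- structure(values, class = "inb", k = psa$k,
                   incident_population = psa$incident_population,
                   orientation = paste(b$label, "vs", a$label))
  if (monetary) attr(out, "nmb") <- values * psa$k
  out
}

#' Probability the intervention is cost-effective
#'
#' Fraction of PSA draws with strictly positive incremental net benefit.
#' Draws at exactly zero count as not cost-effective (a deterministic tie
#' rule; a zero-measure event under continuous PSA distributions).
#'
#' @param inb Numeric vector of per-draw INB (e.g. from [compute_inb()]).
#' @return A proportion in `[0, 1]`.
#' @export
probability_cost_effective <- function(inb) {
  inb <- as.numeric(inb)
  if (length(inb) < 1L) stop("empty INB vector", call. = FALSE)
  if (anyNA(inb)) stop("missing values in INB vector", call. = FALSE)
  mean(inb > 0)
}

# ---- PSA CSV schema ---------------------------------------------------------
# header: draw,<param columns...>,cost_A,qaly_A,cost_B,qaly_B
# Numbers are written with 17 significant digits so a write/read round trip is
# bit-exact.

.psa_outcome_cols <- c("cost_A", "qaly_A", "cost_B", "qaly_B")

#' Write a PSA result to CSV
#'
#' Schema: a `draw` index column, one column per parameter, then
#' `cost_A,qaly_A,cost_B,qaly_B`. Values are serialized with 17 significant
#' digits so that reading the file back reproduces the doubles bit-exactly.
#' The threshold, population and strategy labels are not stored in the CSV;
#' supply them to [read_psa_csv()] (typically from an analysis config).
#'
#' @param psa A [psa_result()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psa_csv <- function(psa, path) {
  stopifnot(inherits(psa, "psa_result"))
  n <- nrow(psa$draws)
  mat <- cbind(psa$draws,
               cost_A = psa$outcomes[[1]]$costs,
               qaly_A = psa$outcomes[[1]]$qalys,
               cost_B = psa$outcomes[[2]]$costs,
               qaly_B = psa$outcomes[[2]]$qalys)
  cols <- c("draw", colnames(mat))
  body <- cbind(as.character(seq_len(n)),
                matrix(sprintf("%.17g", mat), nrow = n))
  lines <- c(paste(cols, collapse = ","),
             apply(body, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PSA result from CSV
#'
#' Inverse of [write_psa_csv()]. Column order must be: `draw`, parameter
#' columns, `cost_A,qaly_A,cost_B,qaly_B`.
#'
#' @param path CSV file path.
#' @param k Cost-effectiveness threshold (GBP/QALY).
#' @param incident_population Patients per year (default 0: per-person only).
#' @param comparator,intervention Strategy labels.
#' @return A [psa_result()].
#' @export
read_psa_csv <- function(path, k, incident_population = 0,
                         comparator = "A", intervention = "B") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "draw" || !all(.psa_outcome_cols %in% names(df))) {
    stop("not a PSA CSV: expected columns 'draw', parameters, then '",
         paste(.psa_outcome_cols, collapse = ","), "' (file: ", path, ")",
         call. = FALSE)
  }
  pcols <- setdiff(names(df), c("draw", .psa_outcome_cols))
  if (length(pcols) == 0L) stop("PSA CSV has no parameter columns", call. = FALSE)
  psa_result(
    draws = as.matrix(df[pcols]),
    outcomes = list(
      strategy_outcomes(comparator, df$qaly_A, df$cost_A),
      strategy_outcomes(intervention, df$qaly_B, df$cost_B)
    ),
    k = k, incident_population = incident_population
  )
}
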