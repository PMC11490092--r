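# Greedy conditional-EVPPI ranking and the update metric.
#
# Forward selection over candidate parameters (or pre-grouped sets): rank 1
# is the arg-max of independent EVPPI; at each later step the candidate that
# maximizes the joint EVPPI with the already-ranked set is appended. All
# steps reuse the one fixed PSA sample — no re-simulation.

#' Update metric
#'
#' Share of total decision uncertainty addressed by updating a parameter
#' set: `100 * cumulative_evppi / evpi`. Values above 100% are possible
#' because regression EVPPI carries an upward estimation bias; they are
#' flagged with a warning, never altered.
#'
#' @param cumulative_evppi EVPPI of the updated set (any consistent unit).
#' @param evpi The reference EVPI in the same unit; must be positive.
#' @return Percentage (vectorized over `cumulative_evppi`).
#' @examples
#' update_metric(2.41, 3.37)  # 71.5%
#' @export
update_metric <- function(cumulative_evppi, evpi) {
  evpi <- as.numeric(evpi)
  if (length(evpi) != 1L || !is.finite(evpi) || evpi <= 0) {
    stop("evpi must be a single positive value: the model has no decision ",
         "uncertainty to apportion", call. = FALSE)
  }
  m <- 100 * as.numeric(cumulative_evppi) / evpi
  if (any(m > 100 + 1e-9)) {
    warning("update metric exceeds 100% (EVPPI estimation bias)", call. = FALSE)
  }
  m
}

# normalize candidates into a named list of parameter-name vectors
.ranking_candidates <- function(psa, candidates, group_correlated) {
  if (is.null(candidates)) {
    nonconst <- psa$param_names[apply(psa$draws, 2L, function(v) stats::sd(v) > 0)]
    cand <- as.list(nonconst)
    names(cand) <- nonconst
    if (group_correlated && !is.null(psa$correlation_groups)) {
      for (g in names(psa$correlation_groups)) {
        members <- intersect(psa$correlation_groups[[g]], nonconst)
        if (length(members) > 1L) {
          cand <- cand[!names(cand) %in% members]
          cand[[g]] <- members
        }
      }
    }
  } else if (is.list(candidates)) {
    cand <- candidates
    if (is.null(names(cand)) || any(names(cand) == "")) {
      names(cand) <- vapply(cand, paste, character(1), collapse = "+")
    }
  } else {
    cand <- as.list(as.character(candidates))
    names(cand) <- as.character(candidates)
  }
  unknown <- setdiff(unlist(cand), psa$param_names)
  if (length(unknown)) {
    stop("unknown candidate parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(cand) == 0L) stop("empty candidate set", call. = FALSE)
  cand[order(names(cand))]  # input order must never influence the result
}

#' Greedy conditional-EVPPI ranking of model parameters
#'
#' Implements forward selection for model updating: compute independent
#' EVPPI for every candidate, rank the largest first, then repeatedly add
#' the candidate that maximizes the EVPPI of the joint set, until candidates
#' are exhausted or the best marginal gain drops to (or below) the stopping
#' tolerance. Correlated parameter groups recorded on the PSA (e.g. the
#' adverse-event probabilities) are offered as a single candidate by default.
#'
#' Ties in the arg-max are broken by the larger independent EVPPI, then
#' lexicographically by name, so the result is deterministic and invariant
#' to candidate input order.
#'
#' @param psa A [psa_result()].
#' @param candidates Candidate parameters: character vector, named list of
#'   name vectors (groups), or `NULL` for all non-constant parameters.
#' @param tol Stopping tolerance in per-person QALYs, or `"auto"` for
#'   `max(2 * SE(EVPI), 0.001 * EVPI)` — "marginal gain gone to zero" is
#'   unattainable verbatim under Monte-Carlo noise.
#' @param max_steps Cap on the number of ranked entries (default all).
#' @param n_boot Bootstrap replicates for the SE of each step's chosen
#'   EVPPI (0 to skip).
#' @param verbose Narrate each greedy step's candidate EVPPIs.
#' @param group_correlated Offer correlated parameter groups recorded on the
#'   PSA as single candidates (default `TRUE`); ignored when `candidates`
#'   is supplied.
#' @return A `ranking_table`: data frame with columns `parameter`, `rank`,
#'   `cumulative_evppi`, `marginal_evppi` (per person), `se`,
#'   `cumulative_evppi_pop`, `marginal_evppi_pop` (population-scaled) and
#'   `update_metric` (%), with attributes `evpi` (a `voi_estimate`), `tol`,
#'   `stopped_early` and `members`.
#' @export
conditional_evppi_ranking <- function(psa, candidates = NULL, tol = "auto",
                                      max_steps = Inf, n_boot = 100L,
                                      verbose = FALSE,
                                      group_correlated = TRUE) {
  stopifnot(inherits(psa, "psa_result"))
  cand <- .ranking_candidates(psa, candidates, group_correlated)
  ev <- evpi(compute_inb(psa))
  if (identical(tol, "auto")) {
    tol <- max(2 * ev$standard_error, 0.001 * ev$per_person)
  }
  tol <- as.numeric(tol)
  if (length(tol) != 1L || is.na(tol) || tol < 0) {
    stop("tol must be a single non-negative number or \"auto\"", call. = FALSE)
  }

  ee <- function(members) {
    est <- evppi(psa, members, max_subset = Inf, n_boot = 0L)
    est$raw  # unclipped: greedy comparisons should see the noise as-is
  }
  indep <- vapply(cand, ee, numeric(1))

  ranked <- character(0)   # candidate labels in rank order
  members <- list()
  cumulative <- numeric(0)
  se <- numeric(0)
  stopped_early <- FALSE
  current_set <- character(0)
  prev <- 0
  remaining <- names(cand)

  while (length(remaining) > 0L && length(ranked) < max_steps) {
    vals <- if (length(ranked) == 0L) {
      indep[remaining]
    } else {
      vapply(remaining, function(nm) ee(c(current_set, cand[[nm]])),
             numeric(1))
    }
    if (verbose) {
      message("step ", length(ranked) + 1L, ": ",
              paste(sprintf("%s=%.4g", remaining, vals), collapse = ", "))
    }
    ord <- order(-vals, -indep[remaining], remaining)
    best <- remaining[ord[1L]]
    gain <- vals[ord[1L]] - prev
    if (length(ranked) > 0L && gain <= tol) {
      stopped_early <- TRUE
      break
    }
    ranked <- c(ranked, best)
    members[[best]] <- cand[[best]]
    current_set <- c(current_set, cand[[best]])
    cumulative <- c(cumulative, vals[ord[1L]])
    se_step <- if (n_boot > 0L) {
      evppi(psa, current_set, max_subset = Inf, n_boot = n_boot)$standard_error
    } else NA_real_
    se <- c(se, se_step)
    prev <- vals[ord[1L]]
    remaining <- setdiff(remaining, best)
  }
  if (length(ranked) == 0L) {
    stop("no candidate achieved positive EVPPI above tolerance", call. = FALSE)
  }
  cum_clip <- pmax(0, cumulative)
  marginal <- diff(c(0, cum_clip))
  metric <- suppressWarnings(update_metric(cum_clip, ev$per_person))
  pop <- psa$incident_population
  out <- data.frame(
    parameter = ranked,
    rank = seq_along(ranked),
    cumulative_evppi = cum_clip,
    marginal_evppi = marginal,
    se = se,
    cumulative_evppi_pop = cum_clip * pop,
    marginal_evppi_pop = marginal * pop,
    update_metric = metric,
    row.names = NULL
  )
  structure(out, evpi = ev, tol = tol, stopped_early = stopped_early,
            members = members, raw_cumulative = cumulative,
            class = c("ranking_table", "data.frame"))
}

#' @export
print.ranking_table <- function(x, digits = 4, ...) {
  ev <- attr(x, "evpi")
  cat("Conditional EVPPI ranking (update prioritization)\n")
  cat(sprintf("EVPI: %.*g QALYs/person", digits, ev$per_person))
  if (ev$incident_population > 0) {
    cat(sprintf(" (%.*g population QALYs)", digits, ev$population_scaled))
  }
  cat(sprintf("; stopping tol %.3g; stopped early: %s\n\n",
              attr(x, "tol"), attr(x, "stopped_early")))
  df <- as.data.frame(x)
  df$cumulative_evppi <- signif(df$cumulative_evppi, digits)
  df$marginal_evppi <- signif(df$marginal_evppi, digits)
  df$update_metric <- round(df$update_metric, 1)
  print(df, row.names = FALSE)
  if (any(x$update_metric > 100)) {
    cat("\nNote: metric above 100% reflects upward EVPPI estimation bias.\n")
  }
  invisible(x)
}
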