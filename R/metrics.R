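#' Classify a completed protocol trace
#'
#' A trace is a *hit* when the protocol terminated by the 15-mm rule. A
#' trace that exhausted its potential modeling sites is an *early
#' termination* when its final-round estimated error was still strictly
#' improving on the previous round (the error reduction was interrupted by
#' running out of sites); otherwise it is a *miss*. Single-round exhausted
#' traces have no previous round and count as misses.
#'
#' @param trace A `protocol_trace` from [run_protocol].
#' @return `"hit"`, `"miss"` or `"early_termination"`.
#' @export
classify_outcome <- function(trace) {
  stopifnot(inherits(trace, "protocol_trace"))
  if (trace$termination == "hit") return("hit")
  err <- trace$rounds$estimated_error
  n <- length(err)
  if (n >= 2L && err[n] < err[n - 1L]) "early_termination" else "miss"
}

#' Summarize outcomes over a set of traces
#'
#' Counts hits, misses and early terminations per model and builds the
#' accumulation series of hits/misses against the number of modeling sites
#' at termination.
#'
#' @param traces List of `protocol_trace` objects (any mix of models).
#' @return List with `counts` (data frame: model, n_traces, hits, misses,
#'   early_terminations) and `accumulation` (data frame: model, n_sites,
#'   cum_hits, cum_misses).
#' @export
outcome_summary <- function(traces) {
  model <- vapply(traces, function(tr) tr$model_name, character(1))
  outcome <- vapply(traces, classify_outcome, character(1))
  n_final <- vapply(traces, function(tr) {
    tr$rounds$n_sites[nrow(tr$rounds)]
  }, numeric(1))
  counts <- do.call(rbind, lapply(unique(model), function(m) {
    o <- outcome[model == m]
    data.frame(model = m, n_traces = length(o),
               hits = sum(o == "hit"), misses = sum(o == "miss"),
               early_terminations = sum(o == "early_termination"),
               stringsAsFactors = FALSE)
  }))
  acc <- do.call(rbind, lapply(unique(model), function(m) {
    sel <- model == m
    ns <- sort(unique(n_final[sel]))
    do.call(rbind, lapply(ns, function(k) {
      data.frame(model = m, n_sites = k,
                 cum_hits = sum(outcome[sel] == "hit" & n_final[sel] <= k),
                 cum_misses = sum(outcome[sel] != "hit" & n_final[sel] <= k),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(counts = counts, accumulation = acc)
}

# Internal: per-trace running-minimum error series, padded to max_rounds by
# holding the minimum (the estimated error remains unchanged after
# minimization).
held_errors <- function(trace, max_rounds) {
  err <- cummin(trace$rounds$estimated_error)
  if (length(err) < max_rounds) {
    err <- c(err, rep(err[length(err)], max_rounds - length(err)))
  }
  err[seq_len(max_rounds)]
}

#' Estimated-error curves with hold-at-minimum
#'
#' For each trace, the estimated error per round is replaced by its running
#' minimum and held constant once the trace's own minimum is reached (and
#' beyond its last round, up to `max_rounds`).
#'
#' @param traces List of `protocol_trace` objects.
#' @param max_rounds Number of rounds in the output series (default: the
#'   longest trace).
#' @return Data frame with columns `model`, `target_id`, `round`, `n_sites`
#'   (modeling sites in that round, extrapolated past exhaustion) and
#'   `error` (held estimated error, mm).
#' @export
error_curve <- function(traces, max_rounds = NULL) {
  if (is.null(max_rounds)) {
    max_rounds <- max(vapply(traces, function(tr) nrow(tr$rounds),
                             numeric(1)))
  }
  do.call(rbind, lapply(traces, function(tr) {
    n0 <- tr$rounds$n_sites[1L]
    data.frame(model = tr$model_name, target_id = tr$target_id,
               round = seq_len(max_rounds),
               n_sites = n0 + seq_len(max_rounds) - 1L,
               error = held_errors(tr, max_rounds),
               stringsAsFactors = FALSE)
  }))
}

#' Reduced distance of a protocol round
#'
#' The minimum distance between the current modeling sites and the target
#' minus that round's estimated error; positive values mean the unknown
#' region around the target shrank. Rounds after the trace's minimum
#' estimated error has been reached are excluded (`NA`), matching the
#' convention that minimized samples are not counted.
#'
#' @param trace A `protocol_trace`.
#' @param round Round number (1-based).
#' @return Reduced distance in mm, or `NA` if the round is excluded.
#' @export
reduced_distance <- function(trace, round) {
  err <- trace$rounds$estimated_error
  stopifnot(round >= 1L, round <= length(err))
  r_min <- which.min(err)
  if (round > r_min) return(NA_real_)
  trace$rounds$min_modeling_distance[round] - err[round]
}

# Guarded paired two-sided t-test p-value; identical vectors give 1.
paired_p <- function(x, y) {
  d <- x - y
  if (length(d) < 2L || stats::sd(d) == 0) return(1)
  stats::t.test(x, y, paired = TRUE)$p.value
}

#' Target-range summary table across models
#'
#' For range-scheme traces run on identical targets under each model,
#' summarizes (mean, std, median) the initial target radius (maximum
#' potential-site distance), the final estimated error (minimum over
#' rounds) and the number of modeling sites in use when that minimum was
#' first reached, and computes pairwise two-sided paired t-tests between
#' models on final errors and on site counts. Medians are labeled `Mid`.
#'
#' @param traces_by_model Named list: one list of `protocol_trace` objects
#'   per model, all covering the same targets in the same order.
#' @return List with `summary` (data frame: model, quantity, Mean, Std,
#'   Mid) and `t_tests` (data frame: model_a, model_b, quantity, p_value).
#' @export
range_table <- function(traces_by_model) {
  models <- names(traces_by_model)
  stopifnot(length(models) >= 1L)
  tgt <- lapply(traces_by_model, function(trs) {
    vapply(trs, function(tr) tr$target_id, character(1))
  })
  for (m in models) {
    if (!identical(tgt[[m]], tgt[[1L]])) {
      stop("traces must cover identical targets in identical order")
    }
  }
  per_model <- lapply(traces_by_model, function(trs) {
    list(
      radius = vapply(trs, function(tr) tr$initial_radius, numeric(1)),
      final_error = vapply(trs, function(tr) {
        min(tr$rounds$estimated_error)
      }, numeric(1)),
      n_sites = vapply(trs, function(tr) {
        tr$rounds$n_sites[which.min(tr$rounds$estimated_error)]
      }, numeric(1))
    )
  })
  qty_names <- c(radius = "initial_radius_mm",
                 final_error = "final_estimated_error_mm",
                 n_sites = "n_modeling_sites_used")
  summary <- do.call(rbind, lapply(models, function(m) {
    do.call(rbind, lapply(names(qty_names), function(q) {
      v <- per_model[[m]][[q]]
      data.frame(model = m, quantity = qty_names[[q]],
                 Mean = mean(v), Std = stats::sd(v), Mid = stats::median(v),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summary) <- NULL
  t_tests <- NULL
  if (length(models) >= 2L) {
    cmb <- utils::combn(models, 2)
    t_tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      a <- cmb[1, i]; b <- cmb[2, i]
      data.frame(
        model_a = a, model_b = b,
        quantity = c("final_estimated_error_mm", "n_modeling_sites_used"),
        p_value = c(
          paired_p(per_model[[a]]$final_error, per_model[[b]]$final_error),
          paired_p(per_model[[a]]$n_sites, per_model[[b]]$n_sites)),
        stringsAsFactors = FALSE)
    }))
  }
  list(summary = summary, t_tests = t_tests)
}
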