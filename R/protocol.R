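#' Geometric center of a set of positions
#'
#' Arithmetic mean of the coordinates; used by the protocol's
#' spatial-information step when choosing the next modeling site.
#'
#' @param positions Numeric n x 3 matrix (or a single 3-vector).
#' @return Numeric 3-vector.
#' @export
geometric_center <- function(positions) {
  if (is.null(dim(positions))) positions <- matrix(positions, nrow = 1)
  if (nrow(positions) < 1L) stop("geometric center of an empty set")
  colMeans(positions)
}

#' Select target cases from a patient dataset
#'
#' Applies one of the two target-selection schemes. Under `"hitrate"` a site
#' qualifies as a target when at least 5 other sites lie strictly between
#' 15 and 35 mm from it; under `"range"` when at least 5 other sites lie
#' within 35 mm (inclusive). The qualifying neighbors become the target's
#' potential modeling sites.
#'
#' @param dataset A [patient_dataset].
#' @param scheme `"hitrate"` or `"range"`.
#' @param min_neighbors Minimum qualifying neighbors (default 5).
#' @return List of `target_case` objects, each with fields `target`
#'   ([pacing_site]), `potential_modeling` (list of [pacing_site]),
#'   `scheme` and `initial_radius` (max potential-site distance, mm).
#'   May be empty.
#' @export
select_targets <- function(dataset, scheme = c("hitrate", "range"),
                           min_neighbors = 5L) {
  scheme <- match.arg(scheme)
  sites <- dataset$sites
  out <- list()
  for (i in seq_along(sites)) {
    d <- vapply(sites, function(s) {
      point_distance(sites[[i]]$position, s$position)
    }, numeric(1))
    ok <- if (scheme == "hitrate") {
      d > 15 & d < 35
    } else {
      d <= 35 & seq_along(sites) != i
    }
    ok[i] <- FALSE
    if (sum(ok) >= min_neighbors) {
      out[[length(out) + 1L]] <- structure(
        list(target = sites[[i]],
             potential_modeling = sites[ok],
             scheme = scheme,
             initial_radius = max(d[ok])),
        class = "target_case"
      )
    }
  }
  out
}

# Deterministic ordering helpers: ties broken by lexicographic site id.
order_by_value <- function(values, ids, decreasing) {
  ord <- order(values, ids, decreasing = c(decreasing, FALSE),
               method = "radix")
  ord
}

pick_extreme <- function(sites, ref_point, decreasing) {
  d <- vapply(sites, function(s) point_distance(s$position, ref_point),
              numeric(1))
  ids <- vapply(sites, function(s) s$site_id, character(1))
  order_by_value(d, ids, decreasing)[1L]
}

#' Run the iterative modeling/prediction protocol on one target case
#'
#' Emulates the six-step clinical loop for a single target under one model.
#' Round 1 starts from the potential modeling sites farthest from the
#' target (5 for QIM, 3 otherwise); each subsequent round adds one unused
#' potential site:
#'
#' 1. fit the model on the current modeling sites and predict the target;
#' 2. terminate if the prediction is within `hit_mm` of the target (hit) or
#'    no unused potential sites remain (exhausted);
#' 3. if the prediction lies more than `discard_mm` from the target it is
#'    not credible: add the unused site farthest from the geometric center
#'    of the current modeling sites;
#' 4. otherwise add the unused site nearest the prediction if it lies
#'    within `hit_mm` of the prediction; failing that, fall back to the
#'    farthest-from-center choice.
#'
#' The `"fixed"` variant replaces the adaptive choice with the unused site
#' farthest from the target in every round, making the modeling-site
#' sequence independent of the model. Distance checks against the target
#' use the target's true pacing coordinate: this is a retrospective
#' emulation with known ground truth, recorded as such in the trace.
#'
#' @param case A `target_case` from [select_targets].
#' @param model `"QIM"`, `"DEM"`, `"DCM"`, `"DDM"` or a predictor function
#'   (see [predict_origin]).
#' @param variant `"adaptive"` (default) or `"fixed"`.
#' @param hit_mm Hit radius, mm (default 15, inclusive).
#' @param discard_mm Credibility radius, mm (default 35; exceeding it is
#'   exclusive).
#' @return Object of class `protocol_trace`: `target_id`, `model_name`,
#'   `variant`, `scheme`, `initial_radius`, `termination` (`"hit"` or
#'   `"exhausted"`) and `rounds`, a data frame with one row per round
#'   (`round`, `n_sites`, `added_ids`, `modeling_ids`, `pred_x/y/z`,
#'   `estimated_error`, `min_modeling_distance`).
#' @export
run_protocol <- function(case, model, variant = c("adaptive", "fixed"),
                         hit_mm = 15, discard_mm = 35) {
  variant <- match.arg(variant)
  stopifnot(inherits(case, "target_case"))
  target <- case$target
  pot <- case$potential_modeling
  n_init <- model_n_init(model)
  if (length(pot) < n_init) {
    stop(sprintf("model needs %d initial sites but only %d potential sites",
                 n_init, length(pot)))
  }
  ids <- vapply(pot, function(s) s$site_id, character(1))
  d_target <- vapply(pot, function(s) {
    point_distance(s$position, target$position)
  }, numeric(1))
  ord <- order_by_value(d_target, ids, decreasing = TRUE)
  used <- pot[ord[seq_len(n_init)]]
  unused <- pot[ord[-seq_len(n_init)]]
  added <- paste(sort(vapply(used, function(s) s$site_id, character(1))),
                 collapse = ",")

  model_name <- if (is.function(model)) "custom" else model
  rounds <- list()
  termination <- NULL
  repeat {
    pred <- predict_origin(model, used, target)
    err <- point_distance(pred$position, target$position)
    min_d <- min(vapply(used, function(s) {
      point_distance(s$position, target$position)
    }, numeric(1)))
    rounds[[length(rounds) + 1L]] <- data.frame(
      round = length(rounds) + 1L,
      n_sites = length(used),
      added_ids = added,
      modeling_ids = paste(vapply(used, function(s) s$site_id, character(1)),
                           collapse = ","),
      pred_x = pred$position[1], pred_y = pred$position[2],
      pred_z = pred$position[3],
      estimated_error = err,
      min_modeling_distance = min_d,
      stringsAsFactors = FALSE
    )
    if (err <= hit_mm) { termination <- "hit"; break }
    if (length(unused) == 0L) { termination <- "exhausted"; break }

    if (variant == "fixed") {
      pick <- pick_extreme(unused, target$position, decreasing = TRUE)
    } else if (err > discard_mm) {
      center <- geometric_center(site_positions(used))
      pick <- pick_extreme(unused, center, decreasing = TRUE)
    } else {
      near <- pick_extreme(unused, pred$position, decreasing = FALSE)
      if (point_distance(unused[[near]]$position, pred$position) <= hit_mm) {
        pick <- near
      } else {
        center <- geometric_center(site_positions(used))
        pick <- pick_extreme(unused, center, decreasing = TRUE)
      }
    }
    added <- unused[[pick]]$site_id
    used <- c(used, unused[pick])
    unused <- unused[-pick]
  }

  structure(
    list(target_id = target$site_id, model_name = model_name,
         variant = variant, scheme = case$scheme,
         initial_radius = case$initial_radius,
         termination = termination,
         rounds = do.call(rbind, rounds)),
    class = "protocol_trace"
  )
}

#' @export
print.protocol_trace <- function(x, ...) {
  cat(sprintf(
    "<protocol_trace> %s on target '%s': %d round(s), %s (final error %.2f mm)\n",
    x$model_name, x$target_id, nrow(x$rounds), x$termination,
    x$rounds$estimated_error[nrow(x$rounds)]))
  invisible(x)
}
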