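#' @title Least squares with pseudo-inverse and ridge fallback
#' @description Internal solver for all normal-equation systems. Uses the
#'   SVD-based minimum-norm least-squares solution; singular values below
#'   `tol * max(sv)` are dropped and a rank flag reported. If the SVD fails
#'   (pathological input) a small relative ridge is added instead.
#' @param X design matrix (n x p)
#' @param Y response matrix (n x q) or vector
#' @param tol relative singular-value tolerance
#' @return list(coef = p x q matrix, rank = numeric rank,
#'   rank_deficient = logical)
#' @keywords internal
lstsq <- function(X, Y, tol = 1e-8) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  sv <- tryCatch(svd(X), error = function(e) NULL)
  if (is.null(sv)) {
    # ridge fallback: (X'X + lambda I)^-1 X'Y with small relative lambda
    lambda <- tol * max(abs(X))^2
    coef <- solve(crossprod(X) + lambda * diag(ncol(X)), crossprod(X, Y))
    return(list(coef = coef, rank = NA_integer_, rank_deficient = TRUE))
  }
  keep <- sv$d > tol * max(sv$d, 0)
  r <- sum(keep)
  if (r == 0L) {
    return(list(coef = matrix(0, ncol(X), ncol(Y)), rank = 0L,
                rank_deficient = TRUE))
  }
  coef <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], Y)) / sv$d[keep])
  list(coef = coef, rank = r, rank_deficient = r < ncol(X))
}

#' Construct a localizer prediction
#'
#' @param position Numeric 3-vector (mm).
#' @param model_name Name of the predicting model.
#' @param diagnostics Optional list (residual norms, rank flags, cost).
#' @return Object of class `pvc_prediction`.
#' @export
pvc_prediction <- function(position, model_name, diagnostics = list()) {
  position <- as.numeric(position)
  if (length(position) != 3L || !all(is.finite(position))) {
    stop("prediction position must be a finite 3-vector")
  }
  structure(list(position = position, model_name = model_name,
                 diagnostics = diagnostics),
            class = "pvc_prediction")
}

#' @export
print.pvc_prediction <- function(x, ...) {
  cat(sprintf("<pvc_prediction> %s: (%.2f, %.2f, %.2f) mm\n",
              x$model_name, x$position[1], x$position[2], x$position[3]))
  invisible(x)
}

# Internal: QRS-integral triples for a list of sites (from representatives).
sites_integrals <- function(sites) {
  t(vapply(sites, function(s) {
    onset <- detect_qrs_onset(s$representative)
    as.numeric(qrs_integrals(s$representative, onset))
  }, numeric(3)))
}

#' Fit the QRS-integral regression model (QIM)
#'
#' Fits, by ordinary least squares, each spatial coordinate on an intercept
#' plus the initial 120-ms QRS integrals of leads III, V2 and V6 computed
#' from each site's representative beat. At least 5 sites are required to
#' avoid a singular 4-parameter system; a rank-deficient design falls back
#' to the pseudo-inverse solution and sets a flag.
#'
#' @param sites List of at least 5 [pacing_site] objects.
#' @return Object of class `qim_fit`: `coefficients` (3 x 4 matrix, rows x,
#'   y, z; columns intercept, III, V2, V6) and `rank_deficient` flag.
#' @export
fit_qim <- function(sites) {
  if (length(sites) < 5L) {
    stop("QIM requires at least 5 pacing sites to avoid matrix singularity")
  }
  I <- sites_integrals(sites)
  X <- cbind(1, I)
  Y <- site_positions(sites)
  fit <- lstsq(X, Y)
  structure(list(coefficients = t(fit$coef),
                 rank_deficient = fit$rank_deficient, rank = fit$rank),
            class = "qim_fit")
}

#' Predict a position from a QIM fit
#'
#' @param fit A `qim_fit` from [fit_qim].
#' @param integrals A `qrs_int_triple` (or numeric 3-vector) for the target.
#' @return A [pvc_prediction].
#' @export
predict_qim <- function(fit, integrals) {
  stopifnot(inherits(fit, "qim_fit"))
  x <- as.numeric(integrals)
  stopifnot(length(x) == 3L, all(is.finite(x)))
  pos <- as.numeric(fit$coefficients %*% c(1, x))
  pvc_prediction(pos, "QIM",
                 diagnostics = list(rank_deficient = fit$rank_deficient))
}

#' Fit a through-origin morphology-to-distance slope
#'
#' Origin-constrained least squares of inter-site distance on a scalar
#' morphology metric: `k = sum(dist * metric) / sum(metric^2)`, the
#' minimizer of `sum((dist - k * metric)^2)`.
#'
#' @param metric Numeric vector of morphology metric values (E12 or
#'   1 - Corr), at least one strictly positive.
#' @param dist Numeric vector of matching Euclidean distances (mm).
#' @param metric_kind `"E12"` or `"one-minus-Corr"` (bookkeeping only).
#' @return Object of class `scalar_distance_fit` with slope `k`
#'   (mm per metric unit) and `metric_kind`.
#' @export
fit_scalar_distance <- function(metric, dist, metric_kind = "E12") {
  metric <- as.numeric(metric)
  dist <- as.numeric(dist)
  stopifnot(length(metric) == length(dist), length(metric) >= 1L)
  if (all(metric == 0)) {
    stop("all metric values are zero: distance slope undefined")
  }
  k <- sum(dist * metric) / sum(metric^2)
  structure(list(k = k, metric_kind = metric_kind),
            class = "scalar_distance_fit")
}

# Internal: multilateration cost J and its gradient.
multilat_cost <- function(x, anchors, d) {
  r <- sqrt(rowSums((anchors - matrix(x, nrow(anchors), 3, byrow = TRUE))^2))
  sum((r - d)^2)
}

multilat_grad <- function(x, anchors, d) {
  diff <- matrix(x, nrow(anchors), 3, byrow = TRUE) - anchors
  r <- sqrt(rowSums(diff^2))
  r <- pmax(r, 1e-12)
  as.numeric(2 * colSums((1 - d / r) * diff))
}

#' Multilateration of a point from distances to anchors
#'
#' Estimates a position by minimizing the cost
#' `J = sum_i (||x - a_i|| - d_i)^2` over candidate positions x. J is
#' nonconvex (mirror minima for coplanar anchors), so the solver runs a
#' local minimization from several starts -- the inverse-distance-weighted
#' centroid of the anchors and each anchor itself -- and returns the lowest
#' cost solution. Each start is refined by Nelder--Mead followed by a
#' gradient (BFGS) polish.
#'
#' @param anchors Numeric m x 3 matrix of distinct anchor positions (mm),
#'   m >= 3.
#' @param distances Numeric m-vector of nonnegative estimated distances (mm).
#' @return A [pvc_prediction] with `diagnostics$cost` (J at the optimum)
#'   and `diagnostics$n_starts`.
#' @export
multilaterate <- function(anchors, distances) {
  anchors <- as.matrix(anchors)
  distances <- as.numeric(distances)
  if (nrow(anchors) < 3L) {
    stop("multilateration requires at least 3 anchors")
  }
  stopifnot(ncol(anchors) == 3L, length(distances) == nrow(anchors),
            all(distances >= 0))
  w <- 1 / (distances + 1e-6)
  starts <- rbind(colSums(anchors * w) / sum(w), anchors)
  # linearized trilateration start: subtracting the squared-distance
  # equation of anchor 1 from the others leaves a linear system in x,
  # exact when the distances are consistent and the anchors span 3-D
  if (nrow(anchors) >= 4L) {
    A <- 2 * sweep(anchors[-1L, , drop = FALSE], 2, anchors[1L, ], "-")
    b <- distances[1L]^2 - distances[-1L]^2 +
      rowSums(anchors[-1L, , drop = FALSE]^2) - sum(anchors[1L, ]^2)
    lin <- lstsq(A, b)$coef
    if (all(is.finite(lin))) starts <- rbind(as.numeric(lin), starts)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o1 <- stats::optim(starts[i, ], multilat_cost, anchors = anchors,
                       d = distances, method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 2000))
    o2 <- stats::optim(o1$par, multilat_cost, gr = multilat_grad,
                       anchors = anchors, d = distances, method = "BFGS",
                       control = list(reltol = 1e-14, maxit = 500))
    cand <- if (o2$value <= o1$value) o2 else o1
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  pvc_prediction(best$par, "multilateration",
                 diagnostics = list(cost = best$value,
                                    n_starts = nrow(starts)))
}

# Internal: scalar-distance prediction shared by DEM and DCM.
predict_scalar_model <- function(modeling, target_splice, metric_fun,
                                 metric_kind, model_name) {
  m <- length(modeling)
  if (m < 3L) stop(model_name, " requires at least 3 modeling sites")
  pairs <- utils::combn(m, 2)
  met <- numeric(ncol(pairs))
  dst <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    met[p] <- metric_fun(modeling[[i]]$splice, modeling[[j]]$splice)
    dst[p] <- point_distance(modeling[[i]]$position, modeling[[j]]$position)
  }
  fit <- fit_scalar_distance(met, dst, metric_kind)
  d_hat <- vapply(modeling, function(s) {
    fit$k * metric_fun(s$splice, target_splice)
  }, numeric(1))
  d_hat <- pmax(d_hat, 0)  # clamp implausible negatives
  pred <- multilaterate(site_positions(modeling), d_hat)
  pvc_prediction(pred$position, model_name,
                 diagnostics = c(pred$diagnostics,
                                 list(k = fit$k, d_hat = d_hat)))
}

#' Predict with the dis-E12 model (DEM)
#'
#' Fits the through-origin slope between E12 and Euclidean distance on all
#' modeling-site pairs, converts target E12 values into estimated distances
#' and multilaterates.
#'
#' @param modeling List of at least 3 [pacing_site] objects.
#' @param target_splice [splice_vector] of the target beat.
#' @return A [pvc_prediction].
#' @export
predict_dem <- function(modeling, target_splice) {
  predict_scalar_model(modeling, target_splice, e12, "E12", "DEM")
}

#' Predict with the dis-Corr model (DCM)
#'
#' As [predict_dem] but with the morphology metric `1 - Corr`, where Corr is
#' the mean 12-lead Pearson correlation; estimated distance is
#' `k2 * (1 - Corr)` so that it is nonnegative.
#'
#' @inheritParams predict_dem
#' @return A [pvc_prediction].
#' @export
predict_dcm <- function(modeling, target_splice) {
  metric <- function(a, b) 1 - corr12(a, b)
  predict_scalar_model(modeling, target_splice, metric, "one-minus-Corr",
                       "DCM")
}

#' Predict with the dp-dw transfer-matrix model (DDM)
#'
#' The morphological-domain waveform differences between modeling-site
#' pairs form a basis `[dW]`; the waveform differences from each modeling
#' site to the target form `[dW*]`. The transfer matrix `theta` expressing
#' `[dW*]` in the basis `[dW]` is found by least squares, then applied
#' unchanged in the spatial domain: `[dP*] = [dP] theta` estimates the
#' position difference from each modeling site to the target, and the
#' prediction is the mean over modeling sites of `P_i + dP*_i`.
#'
#' For m modeling sites all ordered pairs i < j are used as basis columns
#' (C(m, 2) columns); for affine position-to-waveform data this basis is
#' deliberately redundant and the minimum-norm least-squares solution keeps
#' the spatial reconstruction unique.
#'
#' @param modeling List of at least 3 [pacing_site] objects with equal-length
#'   splice vectors.
#' @param target_splice [splice_vector] of the target beat.
#' @return A [pvc_prediction] with `diagnostics$rank_deficient` and
#'   `diagnostics$residual` (Frobenius norm of the waveform-domain residual).
#' @export
predict_ddm <- function(modeling, target_splice) {
  m <- length(modeling)
  if (m < 3L) stop("DDM requires at least 3 modeling sites")
  for (s in modeling) check_splice_pair(s$splice, target_splice)
  W <- vapply(modeling, function(s) s$splice$values,
              numeric(length(target_splice$values)))
  P <- t(site_positions(modeling))          # 3 x m
  pairs <- utils::combn(m, 2)
  dW <- W[, pairs[2, ], drop = FALSE] - W[, pairs[1, ], drop = FALSE]
  dP <- P[, pairs[2, ], drop = FALSE] - P[, pairs[1, ], drop = FALSE]
  dWs <- matrix(target_splice$values, nrow(W), m) - W  # W_iO columns
  sol <- lstsq(dW, dWs)
  dPs <- dP %*% sol$coef                    # 3 x m estimated dp vectors
  pos <- rowMeans(P + dPs)
  resid <- sqrt(sum((dW %*% sol$coef - dWs)^2))
  pvc_prediction(pos, "DDM",
                 diagnostics = list(rank_deficient = sol$rank_deficient,
                                    rank = sol$rank, residual = resid))
}

#' Dispatch a localizer by name
#'
#' Convenience wrapper used by the protocol emulation: runs one of the four
#' localizers (or a custom function) on a modeling set and a target site.
#' Custom functions must accept `(modeling, target_site)` and return a
#' [pvc_prediction]; they may carry an `n_init` attribute giving the number
#' of initial modeling sites they need (default 3).
#'
#' @param model `"QIM"`, `"DEM"`, `"DCM"`, `"DDM"`, or a function.
#' @param modeling List of [pacing_site] objects.
#' @param target_site [pacing_site] whose position is treated as unknown
#'   (only its ECG-derived features are used for prediction).
#' @return A [pvc_prediction].
#' @export
predict_origin <- function(model, modeling, target_site) {
  if (is.function(model)) return(model(modeling, target_site))
  switch(model,
    QIM = {
      fit <- fit_qim(modeling)
      onset <- detect_qrs_onset(target_site$representative)
      predict_qim(fit, qrs_integrals(target_site$representative, onset))
    },
    DEM = predict_dem(modeling, target_site$splice),
    DCM = predict_dcm(modeling, target_site$splice),
    DDM = predict_ddm(modeling, target_site$splice),
    stop("unknown model: ", model)
  )
}

# Number of initial modeling sites a model needs (5 for QIM, else 3).
model_n_init <- function(model) {
  if (is.function(model)) {
    n <- attr(model, "n_init")
    if (is.null(n)) 3L else as.integer(n)
  } else if (identical(model, "QIM")) 5L else 3L
}
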