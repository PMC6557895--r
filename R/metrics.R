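#' Face-space metric context
#'
#' Bundles everything a face-space metric needs beyond the two vectors:
#' standardization constants (coordinate means and standard deviations), a
#' coordinate covariance (or correlation) matrix, and an optional principal
#' component truncation rank `k`.  Available metrics:
#'
#' * `euclidean` — Euclidean distance per coordinate, `||u - v||_2 / sqrt(D)`
#'   in physical (facial-length) units; needs no context.
#' * `mahalanobis` — `sqrt((u - v)' C^+ (u - v))` with the pseudo-inverse of
#'   the covariance restricted to its top-`k` eigenspace (default rank 7,
#'   the number of principal components found to sharpen discrimination).
#' * `angle` — the angle subtended between the standardized fluctuation
#'   vectors `y(u)` and `y(v)`, optionally truncated to the top-`k`
#'   principal components of the covariance.
#' * `byatt_rhodes` — angle computed in the whitened (Mahalanobis) frame;
#'   a norm-based-coding style metric.
#'
#' @param metric one of `"euclidean"`, `"mahalanobis"`, `"angle"`,
#'   `"byatt_rhodes"`.
#' @param center,scale coordinate means and standard deviations used to
#'   standardize (required for the angle metrics).
#' @param cov coordinate covariance matrix (required for `mahalanobis` and
#'   `byatt_rhodes`; also used for PC truncation of `angle`).
#' @param k principal-component truncation rank, `NULL` for no truncation.
#' @param norm per-coordinate normalization of the Euclidean metric:
#'   `"rms"` divides the 2-norm by `sqrt(D)` (default), `"mean"` divides by
#'   `D`.
#' @return An object of class `metric_context`.
#' @export
metric_context <- function(metric = c("euclidean", "mahalanobis", "angle",
                                      "byatt_rhodes"),
                           center = NULL, scale = NULL, cov = NULL,
                           k = NULL, norm = c("rms", "mean")) {
  metric <- match.arg(metric)
  norm <- match.arg(norm)
  if (metric %in% c("mahalanobis", "byatt_rhodes") && is.null(cov))
    stop("metric '", metric, "' requires a covariance matrix")
  if (metric %in% c("angle", "byatt_rhodes") &&
      (is.null(center) || is.null(scale)))
    stop("metric '", metric, "' requires standardization constants")
  if (!is.null(cov)) {
    cov <- as.matrix(cov)
    if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
      stop("covariance matrix must be symmetric")
    if (!is.null(k) && k > ncol(cov))
      stop("'k' cannot exceed the face-space dimension")
  }
  eig <- if (!is.null(cov)) eigen((cov + t(cov)) / 2, symmetric = TRUE)
  structure(list(metric = metric, center = center, scale = scale,
                 cov = cov, eig = eig, k = k, norm = norm),
            class = "metric_context")
}

#' Metric context fitted to a dataset
#'
#' Convenience wrapper computing the standardization constants and the
#' covariance of the standardized coordinates from a set of records.
#'
#' @param x a `standardized_dataset` or a records `data.frame`.
#' @inheritParams metric_context
#' @return A `metric_context`.
#' @export
metric_context_from_dataset <- function(x, metric = "euclidean", k = NULL,
                                        norm = "rms") {
  ds <- if (inherits(x, "standardized_dataset")) x else standardize(x)
  metric_context(metric, center = ds$center, scale = ds$scale,
                 cov = stats::cov(ds$y[ds$reference, , drop = FALSE]),
                 k = k, norm = norm)
}

.standardized <- function(u, ctx) (u - ctx$center) / ctx$scale

.pc_truncate <- function(y, ctx) {
  if (is.null(ctx$k) || is.null(ctx$eig)) return(y)
  V <- ctx$eig$vectors[, seq_len(ctx$k), drop = FALSE]  # top-k (descending)
  as.numeric(crossprod(V, y))
}

#' Distance between two facial vectors
#'
#' @param u,v facial vectors.
#' @param ctx a [metric_context()].
#' @return Non-negative scalar distance; zero iff the arguments are equal
#'   (Euclidean/Mahalanobis) or their standardized vectors colinear (angle
#'   variants).
#' @export
#' @examples
#' d1 <- default_schema()$reference
#' face_distance(d1, d1 + 0.01, metric_context("euclidean"))  # 0.01
face_distance <- function(u, v, ctx = metric_context("euclidean")) {
  diff <- as.numeric(u) - as.numeric(v)
  switch(ctx$metric,
    euclidean = {
      n <- sqrt(sum(diff^2))
      if (ctx$norm == "rms") n / sqrt(length(diff)) else n / length(diff)
    },
    mahalanobis = {
      ev <- ctx$eig
      k <- if (is.null(ctx$k)) sum(ev$values > 1e-12 * max(ev$values)) else ctx$k
      V <- ev$vectors[, seq_len(k), drop = FALSE]
      lam <- ev$values[seq_len(k)]
      if (any(lam <= 0)) stop("covariance has non-positive leading eigenvalues")
      z <- as.numeric(crossprod(V, diff))
      sqrt(sum(z^2 / lam))
    },
    angle = {
      yu <- .pc_truncate(.standardized(as.numeric(u), ctx), ctx)
      yv <- .pc_truncate(.standardized(as.numeric(v), ctx), ctx)
      .angle_between(yu, yv)
    },
    byatt_rhodes = {
      ev <- ctx$eig
      k <- if (is.null(ctx$k)) sum(ev$values > 1e-12 * max(ev$values)) else ctx$k
      V <- ev$vectors[, seq_len(k), drop = FALSE]
      lam <- ev$values[seq_len(k)]
      yu <- as.numeric(crossprod(V, .standardized(as.numeric(u), ctx))) / sqrt(lam)
      yv <- as.numeric(crossprod(V, .standardized(as.numeric(v), ctx))) / sqrt(lam)
      .angle_between(yu, yv)
    })
}

.angle_between <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("angle metric undefined for a zero-norm standardized vector")
  acos(max(-1, min(1, sum(a * b) / (na * nb))))
}

# All pairwise distances between the rows of A and the rows of B.
cross_distances <- function(A, B, ctx) {
  A <- as.matrix(A); B <- as.matrix(B)
  out <- matrix(NA_real_, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      out[i, j] <- face_distance(A[i, ], B[j, ], ctx)
  out
}

#' Intra-population distance
#'
#' Mean face-space distance over all `N (N - 1) / 2` unordered member pairs
#' of a population: the clustering measure tracked across generations of a
#' sculpting run.
#'
#' @param P population matrix (one facial vector per row, at least 2 rows).
#' @param ctx a [metric_context()].
#' @return Non-negative scalar.
#' @export
intra_population_distance <- function(P, ctx = metric_context("euclidean")) {
  P <- as.matrix(P)
  N <- nrow(P)
  if (N < 2L) stop("intra-population distance needs at least 2 members")
  if (ctx$metric == "euclidean") {
    D <- as.matrix(stats::dist(P))
    denom <- if (ctx$norm == "rms") sqrt(ncol(P)) else ncol(P)
    return(mean(D[upper.tri(D)]) / denom)
  }
  M <- cross_distances(P, P, ctx)
  mean(M[upper.tri(M)])
}

#' Pseudo-distance between two populations
#'
#' Mean face-space distance over all cross pairs (one member from each
#' population).  It is symmetric in its arguments and, being a mean over
#' cross pairs, a population has nonzero pseudo-distance to itself whenever
#' it has spread -- hence "pseudo".
#'
#' @param P,Q population matrices (at least one row each).
#' @param ctx a [metric_context()].
#' @return Non-negative scalar.
#' @export
population_pseudo_distance <- function(P, Q,
                                       ctx = metric_context("euclidean")) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) < 1L || nrow(Q) < 1L)
    stop("pseudo-distance needs non-empty populations")
  if (ctx$metric == "euclidean") {
    D <- as.matrix(stats::dist(rbind(P, Q)))
    cross <- D[seq_len(nrow(P)), nrow(P) + seq_len(nrow(Q)), drop = FALSE]
    denom <- if (ctx$norm == "rms") sqrt(ncol(P)) else ncol(P)
    return(mean(cross) / denom)
  }
  mean(cross_distances(P, Q, ctx))
}

#' Intra-population distance per generation
#'
#' @param record a `sculpt_experiment`.
#' @param ctx a [metric_context()].
#' @return Numeric vector of length `T + 1` (generations `0 ... T`).
#' @export
convergence_curve <- function(record, ctx = metric_context("euclidean")) {
  vapply(record$populations, intra_population_distance, numeric(1L),
         ctx = ctx)
}

#' Serialize and restore a metric context
#'
#' Writes the context (metric name, standardization constants, covariance
#' and truncation rank) to JSON so analyses can be reproduced bit-exactly.
#'
#' @param ctx a `metric_context`.
#' @param path file path.
#' @export
write_metric_context <- function(ctx, path) {
  jsonlite::write_json(
    list(metric = ctx$metric, center = ctx$center, scale = ctx$scale,
         cov = ctx$cov, k = ctx$k, norm = ctx$norm),
    path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_metric_context
#' @export
read_metric_context <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  metric_context(x$metric,
                 center = if (length(x$center)) unlist(x$center),
                 scale = if (length(x$scale)) unlist(x$scale),
                 cov = if (length(x$cov)) as.matrix(x$cov),
                 k = x$k, norm = x$norm)
}
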