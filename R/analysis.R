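#' Separation statistic between two distance histograms
#'
#' Quantifies how distinguishable the inter-subject distances are from the
#' self-consistency distances via
#' `t = (mu_i - mu_sc) / sqrt(sigma_i^2 + sigma_sc^2)`, together with the
#' Gaussian overlap probability `p12 = pnorm(t)`: under a Gaussian
#' approximation of both histograms, the probability that a same-subject
#' pair of populations is closer than a different-subject pair.  Standard
#' deviations use denominator `n - 1`.
#'
#' @param inter_dists inter-subject distances (between populations sculpted
#'   by different subjects).
#' @param sc_dists self-consistency distances (between populations sculpted
#'   by the same subject in independent runs).
#' @return An object of class `separation_stats` with the means, standard
#'   deviations, counts, standard errors, `t` and `gaussian_p12`.
#' @export
#' @examples
#' s <- separation_stats(rnorm(200, 2), rnorm(200, 1))
#' s$t
separation_stats <- function(inter_dists, sc_dists) {
  if (length(inter_dists) < 2L || length(sc_dists) < 2L)
    stop("both distance sets need at least 2 values to estimate a spread")
  mu_i <- mean(inter_dists); sigma_i <- stats::sd(inter_dists)
  mu_sc <- mean(sc_dists); sigma_sc <- stats::sd(sc_dists)
  t <- (mu_i - mu_sc) / sqrt(sigma_i^2 + sigma_sc^2)
  structure(list(mu_i = mu_i, sigma_i = sigma_i, n_i = length(inter_dists),
                 mu_sc = mu_sc, sigma_sc = sigma_sc,
                 n_sc = length(sc_dists),
                 se_i = sigma_i / sqrt(length(inter_dists)),
                 se_sc = sigma_sc / sqrt(length(sc_dists)),
                 t = t, gaussian_p12 = gaussian_p12(t)),
            class = "separation_stats")
}

#' @export
print.separation_stats <- function(x, ...) {
  cat(sprintf("inter-subject:    mu = %.4g +/- %.2g (sd %.4g, n = %d)\n",
              x$mu_i, x$se_i, x$sigma_i, x$n_i))
  cat(sprintf("self-consistency: mu = %.4g +/- %.2g (sd %.4g, n = %d)\n",
              x$mu_sc, x$se_sc, x$sigma_sc, x$n_sc))
  cat(sprintf("separation t = %.3f, Gaussian p12 = %.3f\n",
              x$t, x$gaussian_p12))
  invisible(x)
}

#' Gaussian overlap probability
#'
#' `pnorm(t)`: the probability that a draw from the self-consistency
#' histogram falls below a draw from the inter-subject histogram when both
#' are Gaussian with separation statistic `t`.
#'
#' @param t separation statistic.
#' @return Probability in `(0, 1)`; strictly increasing in `t`, 0.5 at 0.
#' @export
gaussian_p12 <- function(t) stats::pnorm(t)

#' Empirical overlap probability
#'
#' Estimates `P(X_same < X_diff)` for a same-subject distance `X_same` and a
#' different-subject distance `X_diff` drawn independently from the two
#' empirical sets; ties count one half.  When the sets are small enough
#' (product of sizes at most `1e6`) the exhaustive double loop is used;
#' otherwise a Monte-Carlo estimate over `n_samples` independent draws.
#'
#' @param same_pair_dists,diff_pair_dists non-empty numeric vectors.
#' @param n_samples Monte-Carlo sample count for large sets.
#' @return Probability in `[0, 1]`.
#' @export
empirical_p12 <- function(same_pair_dists, diff_pair_dists,
                          n_samples = 1e5) {
  if (length(same_pair_dists) == 0L || length(diff_pair_dists) == 0L)
    stop("both distance sets must be non-empty")
  if (length(same_pair_dists) * length(diff_pair_dists) <= 1e6) {
    lt <- outer(same_pair_dists, diff_pair_dists, "<")
    eq <- outer(same_pair_dists, diff_pair_dists, "==")
    mean(lt + 0.5 * eq)
  } else {
    s <- sample(same_pair_dists, n_samples, replace = TRUE)
    d <- sample(diff_pair_dists, n_samples, replace = TRUE)
    mean((s < d) + 0.5 * (s == d))
  }
}

#' One-vector-per-subject bootstrap of the coordinate correlation matrix
#'
#' The correlation matrix `C_ij = <y_i y_j>` of standardized coordinate
#' fluctuations, averaged over subjects.  To subtract correlations internal
#' to a single subject's population, each bootstrap realization draws *one*
#' member uniformly at random from every subject's population, standardizes
#' the coordinates within the realization (population standard deviation,
#' so the diagonal is exactly 1 per realization), and computes
#' `C^(b)_ij = (1/S) sum_s y_i y_j`.  Element-wise mean and standard
#' deviation over the `B` realizations are reported together with two-sided
#' p-values from the normal approximation `z = mean / sd` and the empirical
#' sign-flip fraction.
#'
#' Two p-value matrices are returned.  `p` uses the bootstrap spread alone
#' (`z = mean / sd`): it asks whether the *realized cohort's* correlation is
#' nonzero, and will legitimately flag finite-sample correlations of order
#' `1/sqrt(S)` among the recruited subjects.  `p_cohort` adds the
#' subject-sampling variance (the across-subject spread of the products
#' `y_i y_j`, divided by `S`) to the denominator: it asks whether the
#' *population-level* correlation is nonzero and is calibrated at the
#' nominal false-positive rate against a cohort drawn with independent
#' coordinates.
#'
#' @param x population records (`data.frame`), a `standardized_dataset` or a
#'   `study_dataset`; subjects are identified by `subject_id`.
#' @param B number of bootstrap realizations (at least 100).
#' @param max_redraws cap on redraws of realizations rejected for a
#'   zero-variance coordinate.
#' @return An object of class `correlation_result` with matrices `C`
#'   (mean), `sd`, `p`, `sign_flip`, plus `B` and `n_subjects`.
#' @export
bootstrap_correlation <- function(x, B = 1000L, max_redraws = 10L * B) {
  records <- extract_records(x)
  if (B < 100L) stop("'B' must be at least 100")
  groups <- split(seq_len(nrow(records)), records$subject_id)
  S <- length(groups)
  if (S < 2L) stop("at least 2 subjects are required")
  F <- record_matrix(records)
  D <- ncol(F)
  sumC <- matrix(0, D, D); sumC2 <- matrix(0, D, D)
  pos <- matrix(0, D, D); neg <- matrix(0, D, D)
  sumVs <- matrix(0, D, D)  # subject-sampling variance of C per realization
  redraws <- 0L
  b <- 0L
  while (b < B) {
    idx <- vapply(groups, function(g)
      if (length(g) == 1L) g else g[sample.int(length(g), 1L)], integer(1L))
    Fb <- F[idx, , drop = FALSE]
    mu <- colMeans(Fb)
    sig <- sqrt(colMeans(sweep(Fb, 2L, mu)^2))  # population sd
    if (any(sig <= 0)) {
      redraws <- redraws + 1L
      if (redraws > max_redraws)
        stop("too many bootstrap realizations with a zero-variance coordinate")
      next
    }
    y <- sweep(sweep(Fb, 2L, mu), 2L, sig, "/")
    Cb <- crossprod(y) / S
    # across-subject variance of the products y_i y_j in this realization
    P2 <- crossprod(y^2) / S
    sumVs <- sumVs + (P2 - Cb^2) / S
    sumC <- sumC + Cb
    sumC2 <- sumC2 + Cb^2
    pos <- pos + (Cb > 0); neg <- neg + (Cb < 0)
    b <- b + 1L
  }
  Cm <- sumC / B
  Cs <- sqrt(pmax(sumC2 / B - Cm^2, 0) * B / (B - 1))
  z <- Cm / Cs
  p <- 2 * stats::pnorm(-abs(z))
  p[Cs == 0] <- ifelse(Cm[Cs == 0] == 0, 1, 0)
  # total uncertainty including the subject-sampling term: tests the
  # generative (cohort-level) correlation rather than the realized one
  Ct <- sqrt(Cs^2 + sumVs / B)
  p_cohort <- 2 * stats::pnorm(-abs(Cm / Ct))
  p_cohort[Ct == 0] <- ifelse(Cm[Ct == 0] == 0, 1, 0)
  sign_flip <- ifelse(Cm >= 0, neg, pos) / B
  dimnames(Cm) <- dimnames(Cs) <- dimnames(p) <- dimnames(Ct) <-
    dimnames(p_cohort) <- dimnames(sign_flip) <-
    list(FACE_COORDS, FACE_COORDS)
  structure(list(C = Cm, sd = Cs, p = p,
                 sd_cohort = Ct, p_cohort = p_cohort,
                 sign_flip = sign_flip,
                 B = B, n_subjects = S, redraws = redraws),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, alpha = 0.05, ...) {
  off <- upper.tri(x$C)
  cat(sprintf("Bootstrapped coordinate correlation matrix (%d subjects, B = %d)\n",
              x$n_subjects, x$B))
  cat(sprintf("%.0f%% of off-diagonal elements significant at p < %.3g\n",
              100 * mean(x$p[off] < alpha), alpha))
  print(round(x$C, 3))
  invisible(x)
}

extract_records <- function(x) {
  if (inherits(x, "study_dataset")) x$records
  else if (inherits(x, "standardized_dataset")) x$records
  else if (is.data.frame(x)) x
  else stop("cannot extract population records from an object of class ",
            paste(class(x), collapse = "/"))
}

#' Eigen-decomposition of a coordinate correlation matrix
#'
#' Principal components of the standardized facial coordinates: eigenvalues
#' are returned in *ascending* order `lambda_0 <= ... <= lambda_10` (so the
#' last axis is the most variant one), the eigenvector rows `e^(k)` form the
#' projection matrix `E` with `E C E' = diag(lambda)`, and each eigenvector
#' has its largest-magnitude entry made positive as a deterministic sign
#' convention.
#'
#' @param C symmetric correlation/covariance matrix.
#' @return An object of class `pca_result` with `values` (ascending),
#'   `E` (eigenvector rows, same order).
#' @export
pca_decompose <- function(C) {
  C <- as.matrix(C)
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    stop("'C' must be symmetric")
  eig <- eigen((C + t(C)) / 2, symmetric = TRUE)
  ord <- rev(seq_along(eig$values))  # ascending
  values <- eig$values[ord]
  E <- t(eig$vectors[, ord, drop = FALSE])
  for (k in seq_len(nrow(E))) {
    j <- which.max(abs(E[k, ]))
    if (E[k, j] < 0) E[k, ] <- -E[k, ]
  }
  rownames(E) <- paste0("e_", seq_len(nrow(E)) - 1L)
  if (!is.null(colnames(C))) colnames(E) <- colnames(C)
  structure(list(values = values, E = E), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("Principal axes of the coordinate correlation matrix\n")
  cat("eigenvalues (ascending):", paste(round(x$values, 3), collapse = " "),
      "\n")
  invisible(x)
}

#' Project standardized vectors on the principal axes
#'
#' Computes `y' = E y` for each row of a matrix of standardized vectors.
#'
#' @param pca a `pca_result`.
#' @param y matrix of standardized vectors (rows) or a single vector.
#' @return Matrix of projections, columns ordered like the eigenvalues
#'   (ascending variance).
#' @export
pca_project <- function(pca, y) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  out <- y %*% t(pca$E)
  colnames(out) <- rownames(pca$E)
  out
}

subject_mean_matrix <- function(records, center, scale) {
  F <- record_matrix(records)
  y <- sweep(sweep(F, 2L, center), 2L, scale, "/")
  ids <- records$subject_id
  agg <- rowsum(y, ids)
  sweep(agg, 1L, as.numeric(table(ids)[rownames(agg)]), "/")
}

#' Per-coordinate (or per-PC) group comparison
#'
#' Compares two groups of subjects coordinate by coordinate (or principal
#' component by principal component).  Coordinates are standardized with
#' the pooled dataset's mean and standard deviation, each subject is
#' reduced to their mean standardized vector, and a two-sample t test is
#' run per coordinate (Welch by default; set `var_equal = TRUE` for the
#' pooled-variance Student test).
#'
#' @param ds_A,ds_B population records of the two groups (each with at
#'   least 2 subjects).
#' @param per `"coordinate"` or `"pc"`.
#' @param pca a `pca_result` (required when `per = "pc"`).
#' @param var_equal use the pooled-variance Student test.
#' @param p_adjust optional multiple-testing correction passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); default `"none"`, matching raw
#'   per-coordinate thresholds.
#' @return An object of class `group_test_result`: a `data.frame` with the
#'   group means, `t`, `df`, `p` and group sizes.
#' @export
group_coordinate_test <- function(ds_A, ds_B,
                                  per = c("coordinate", "pc"),
                                  pca = NULL, var_equal = FALSE,
                                  p_adjust = "none") {
  per <- match.arg(per)
  ra <- extract_records(ds_A); rb <- extract_records(ds_B)
  pooled <- rbind(ra[, c("subject_id", FACE_COORDS)],
                  rb[, c("subject_id", FACE_COORDS)])
  F <- as.matrix(pooled[, FACE_COORDS])
  center <- colMeans(F); scale <- apply(F, 2L, stats::sd)
  if (any(scale <= 0)) stop("zero-variance coordinate in the pooled dataset")
  A <- subject_mean_matrix(ra, center, scale)
  Bm <- subject_mean_matrix(rb, center, scale)
  if (nrow(A) < 2L || nrow(Bm) < 2L)
    stop("both groups need at least 2 subjects")
  if (per == "pc") {
    if (is.null(pca)) stop("'pca' is required for per-PC tests")
    A <- pca_project(pca, A)
    Bm <- pca_project(pca, Bm)
  }
  out <- lapply(seq_len(ncol(A)), function(j) {
    tt <- stats::t.test(A[, j], Bm[, j], var.equal = var_equal)
    data.frame(coordinate = colnames(A)[j],
               mean_A = mean(A[, j]), mean_B = mean(Bm[, j]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$p <- stats::p.adjust(out$p, method = p_adjust)
  attr(out, "n_A") <- nrow(A)
  attr(out, "n_B") <- nrow(Bm)
  class(out) <- c("group_test_result", "data.frame")
  out
}

#' Cross-experiment coordinate offsets
#'
#' For each coordinate, the average difference between subject-mean
#' coordinates across all cross pairs of subjects from two experiments
#' (equivalently, the difference of the two experiment-wide subject means),
#' with its standard error.  Robust coordinates (those whose preferred
#' values do not depend on the reference portrait) show offsets compatible
#' with zero.
#'
#' @param ds_A,ds_B population records of the two experiments.
#' @return A `data.frame` with `coordinate`, `offset` (A minus B), `se` and
#'   the pair-difference standard deviation `sd_pair`.
#' @export
cross_experiment_offset <- function(ds_A, ds_B) {
  ra <- extract_records(ds_A); rb <- extract_records(ds_B)
  one <- rep(1, 11L)
  A <- subject_mean_matrix(ra, center = rep(0, 11L), scale = one)
  Bm <- subject_mean_matrix(rb, center = rep(0, 11L), scale = one)
  va <- apply(A, 2L, stats::var); vb <- apply(Bm, 2L, stats::var)
  data.frame(coordinate = FACE_COORDS,
             offset = colMeans(A) - colMeans(Bm),
             se = sqrt(va / nrow(A) + vb / nrow(Bm)),
             sd_pair = sqrt(va + vb),
             stringsAsFactors = FALSE)
}
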