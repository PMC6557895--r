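#' Build population records from a matrix of facial vectors
#'
#' Convenience constructor for the tabular record format used throughout
#' the analysis layer: one row per facial vector with identifying columns
#' `experiment_id`, `subject_id`, `replicate`, `generation`, `member` and
#' the 11 distance columns `d_0 ... d_10`.
#'
#' @param P numeric matrix with one facial vector per row (11 columns).
#' @param experiment_id,subject_id,replicate,generation identifying values
#'   recycled across rows.
#' @return A `data.frame` of population records.
#' @export
population_records <- function(P, experiment_id = "E1", subject_id = "s1",
                               replicate = 1L, generation = 0L) {
  P <- as.matrix(P)
  stopifnot(ncol(P) == 11L)
  colnames(P) <- FACE_COORDS
  cbind(data.frame(experiment_id = experiment_id,
                   subject_id = as.character(subject_id),
                   replicate = as.integer(replicate),
                   generation = as.integer(generation),
                   member = seq_len(nrow(P)),
                   stringsAsFactors = FALSE),
        as.data.frame(P))
}

record_matrix <- function(records) {
  as.matrix(records[, FACE_COORDS, drop = FALSE])
}

#' Standardize a dataset of facial vectors
#'
#' Computes the per-coordinate mean and standard deviation (denominator
#' `n - 1`) over a reference subset of the records and the standardized
#' fluctuations `y_i = (f_i - <f_i>) / sigma_i` for *all* records.  Over the
#' reference subset each `y` column then has mean 0 and standard deviation 1.
#'
#' @param records population records (see [population_records()]).
#' @param reference logical or integer index selecting the reference subset
#'   (default: all records).
#' @return An object of class `standardized_dataset` with elements
#'   `records`, `center` (the coordinate means), `scale` (the coordinate
#'   standard deviations), `y` (matrix of standardized values, one row per
#'   record) and `reference` (logical mask).
#' @export
standardize <- function(records, reference = NULL) {
  F <- record_matrix(records)
  n <- nrow(F)
  mask <- rep(TRUE, n)
  if (!is.null(reference)) {
    mask <- rep(FALSE, n)
    mask[reference] <- TRUE
  }
  if (sum(mask) < 2L)
    stop("the reference subset must contain at least 2 records")
  center <- colMeans(F[mask, , drop = FALSE])
  scale <- apply(F[mask, , drop = FALSE], 2L, stats::sd)
  if (any(scale <= 0) || any(!is.finite(scale)))
    stop("zero-variance coordinate in the reference subset: ",
         paste(FACE_COORDS[scale <= 0 | !is.finite(scale)], collapse = ", "))
  y <- sweep(sweep(F, 2L, center), 2L, scale, "/")
  structure(list(records = records, center = center, scale = scale,
                 y = y, reference = mask),
            class = "standardized_dataset")
}

#' @export
print.standardized_dataset <- function(x, ...) {
  cat("Standardized face-space dataset:", nrow(x$records), "records,",
      length(unique(x$records$subject_id)), "subjects\n")
  cat("Coordinate means (reference subset):\n")
  print(round(x$center, 4))
  cat("Coordinate standard deviations:\n")
  print(round(x$scale, 4))
  invisible(x)
}
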