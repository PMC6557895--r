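#' Read and write population record CSV files
#'
#' Populations of facial vectors are exchanged as CSV tables with the fixed
#' header `experiment_id,subject_id,replicate,generation,member,d_0,...,d_10`
#' (distances in facial-length units).  Floats are serialized at 17
#' significant digits, so a write/read round trip is lossless and row order
#' is preserved.
#'
#' @param records population records (see [population_records()]).
#' @param path file path.
#' @param strict if `TRUE`, a constraint violation beyond `tol` is an
#'   error; otherwise a warning.
#' @param tol tolerance on the `h = 1` constraint check.
#' @param schema a `face_schema` used for the constraint check.
#' @return `read_population_csv()` returns the records `data.frame`;
#'   `write_population_csv()` returns `path` invisibly.
#' @export
write_population_csv <- function(records, path) {
  need <- c("experiment_id", "subject_id", "replicate", "generation",
            "member", FACE_COORDS)
  if (!all(need %in% names(records)))
    stop("records are missing required columns: ",
         paste(setdiff(need, names(records)), collapse = ", "))
  out <- records[, need]
  for (cc in FACE_COORDS) out[[cc]] <- sprintf("%.17g", out[[cc]])
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path, strict = FALSE, tol = 1e-6,
                                schema = default_schema()) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(experiment_id = "character",
                                            subject_id = "character"))
  need <- c("experiment_id", "subject_id", "replicate", "generation",
            "member", FACE_COORDS)
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("population CSV is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (cc in FACE_COORDS) {
    if (!is.numeric(records[[cc]]))
      stop("non-numeric values in distance column ", cc)
  }
  ci <- match(schema$constraint_indices, schema$distance_defs$index)
  h <- rowSums(record_matrix(records)[, ci, drop = FALSE])
  bad <- abs(h - 1) > tol
  if (any(bad)) {
    msg <- sprintf("%d record(s) violate the h = 1 constraint beyond %g (max |h - 1| = %g)",
                   sum(bad), tol, max(abs(h - 1)))
    if (strict) stop(msg) else warning(msg)
  }
  records[, need]
}

#' Read and write landmark JSON files
#'
#' Landmarks are exchanged as JSON objects
#' `{"frame": "pixel"|"face", "landmarks": [{"id", "x", "y"}, ...]}`.
#' The `frame` field is mandatory; unknown landmark identifiers are
#' rejected against the schema.
#'
#' @param L a landmark set.
#' @param path file path.
#' @param schema a `face_schema` for identifier validation (`NULL` skips
#'   the check).
#' @return `read_landmarks_json()` returns a landmark set;
#'   `write_landmarks_json()` returns `path` invisibly.
#' @export
write_landmarks_json <- function(L, path) {
  frame <- attr(L, "frame")
  if (is.null(frame)) stop("landmark set has no 'frame' attribute")
  jsonlite::write_json(
    list(frame = frame,
         landmarks = lapply(seq_len(nrow(L)), function(k)
           list(id = L$id[k], x = L$x[k], y = L$y[k]))),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path, schema = default_schema()) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$frame) || !x$frame %in% c("pixel", "face"))
    stop("landmark JSON must declare frame 'pixel' or 'face'")
  L <- data.frame(id = vapply(x$landmarks, `[[`, "", "id"),
                  x = vapply(x$landmarks, function(l) as.numeric(l$x), 0),
                  y = vapply(x$landmarks, function(l) as.numeric(l$y), 0),
                  stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    unknown <- setdiff(L$id, schema$landmark_ids)
    if (length(unknown))
      stop("unknown landmark id(s): ", paste(unknown, collapse = ", "),
           "; valid ids are: ", paste(schema$landmark_ids, collapse = ", "))
  }
  attr(L, "frame") <- x$frame
  L
}

#' Read and write schema YAML files
#'
#' Serializes a `face_schema` to YAML (all fields mirrored) so alternative
#' landmark/distance pairings can be supplied as configuration.
#'
#' @param schema a `face_schema`.
#' @param path file path.
#' @return `read_schema_yaml()` returns a validated `face_schema`.
#' @export
write_schema_yaml <- function(schema, path) {
  x <- unclass(schema)
  x$distance_defs <- as.list(x$distance_defs)
  x$free_coordinates <- as.list(x$free_coordinates)
  x$default_positions <- as.list(x$default_positions)
  x$mirror <- as.list(x$mirror)
  x$y_anchor <- as.list(x$y_anchor)
  x$x_center <- as.list(x$x_center)
  x$height_pair <- as.list(x$height_pair)
  x$reference <- as.list(x$reference)
  x$bounds <- list(lo = as.list(x$bounds$lo), hi = as.list(x$bounds$hi))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_schema_yaml
#' @export
read_schema_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  schema <- structure(list(
    landmark_ids = unlist(x$landmark_ids),
    mirror = unlist(x$mirror),
    distance_defs = as.data.frame(x$distance_defs,
                                  stringsAsFactors = FALSE),
    constraint_indices = unlist(x$constraint_indices),
    free_landmarks = unlist(x$free_landmarks),
    free_coordinates = as.data.frame(x$free_coordinates,
                                     stringsAsFactors = FALSE),
    height_pair = unlist(x$height_pair),
    y_anchor = unlist(x$y_anchor),
    x_center = unlist(x$x_center),
    reference = unlist(x$reference),
    bounds = list(lo = unlist(x$bounds$lo), hi = unlist(x$bounds$hi)),
    default_positions = as.data.frame(x$default_positions,
                                      stringsAsFactors = FALSE)
  ), class = "face_schema")
  validate_schema(schema)
  schema
}

#' Serialize an experiment record
#'
#' Writes a `sculpt_experiment` as the population CSV (all generations),
#' a choices CSV and a JSON sidecar holding the engine configuration, seed
#' and chooser metadata.
#'
#' @param record a `sculpt_experiment`.
#' @param dir output directory (created if needed).
#' @param experiment_id,subject_id,replicate identifiers stamped into the
#'   records.
#' @return The directory path, invisibly.
#' @export
write_experiment <- function(record, dir, experiment_id = "E1",
                             subject_id = "s1", replicate = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- do.call(rbind, lapply(seq_along(record$populations), function(g)
    population_records(record$populations[[g]], experiment_id, subject_id,
                       replicate, g - 1L)))
  write_population_csv(recs, file.path(dir, "populations.csv"))
  utils::write.csv(record$choices, file.path(dir, "choices.csv"),
                   row.names = FALSE)
  cfg <- record$config
  jsonlite::write_json(
    list(N = cfg$N, T = cfg$T, mu = cfg$mu, rho = cfg$rho,
         seed = cfg$seed, randomize_sides = cfg$randomize_sides,
         chooser = record$chooser_info,
         experiment_id = experiment_id, subject_id = subject_id,
         replicate = replicate),
    file.path(dir, "run.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}
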