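#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm plogis rnorm runif sd t.test var cov lm coef
#' @importFrom utils read.csv write.csv head tail
NULL

# Coordinate names used throughout (CSV headers, matrix columns).
FACE_COORDS <- paste0("d_", 0:10)

#' Default face-space schema
#'
#' The face-space is spanned by `D = 11` vertical and horizontal
#' inter-landmark distances `d_0 ... d_10` between 18 standard facial
#' landmarks.  The four vertical distances `d_1 ... d_4` partition the total
#' face height (top of face to eye line, eye line to nose end, nose end to
#' mouth line, mouth line to chin) and are subject to the normalization
#' constraint `d_1 + d_2 + d_3 + d_4 = 1`, so that all distances are
#' proportions of the total facial length.  The remaining distances are:
#' `d_0` the vertical offset between the eye line and the zygomatic bones,
#' `d_5` the face (zygomatic) width, `d_6` the inter-eye distance, `d_7` the
#' mouth width, `d_8` the eye width, `d_9` the nose width and `d_10` the jaw
#' width.
#'
#' The schema is a plain data object: it records the landmark identifiers
#' with their bilateral-symmetry map, the 11 distance definitions (landmark
#' pair and axis), the constraint indices, per-coordinate bounds, a
#' reference vector of anatomically plausible proportions, and the placement
#' metadata needed to reconstruct Cartesian landmark positions from a
#' distance vector.  An alternative landmark/distance pairing is therefore a
#' configuration change, not a code change.
#'
#' The face frame has `x` increasing rightward from the facial midline and
#' `y` increasing *downward* from the top landmark (image convention), in
#' facial-length units: the top landmark sits at `y = 0` and the chin at
#' `y = 1`.  "Higher" facial features therefore have *smaller* `y`; keep
#' this in mind when interpreting the signs of coordinate correlations.
#'
#' @param bounds_factor half-width of the per-coordinate bounds, as a
#'   fraction of the reference value (default 0.5: bounds are 50%--150% of
#'   the reference proportions).
#' @return An object of class `face_schema`.
#' @export
#' @examples
#' sc <- default_schema()
#' nrow(sc$distance_defs)  # 11
default_schema <- function(bounds_factor = 0.5) {
  ids <- c("face_top", "chin", "nose_base", "mouth_center",
           "eye_center_l", "eye_center_r", "eye_inner_l", "eye_inner_r",
           "eye_outer_l", "eye_outer_r", "nose_wing_l", "nose_wing_r",
           "mouth_corner_l", "mouth_corner_r", "zygomatic_l", "zygomatic_r",
           "jaw_l", "jaw_r")
  lat <- grep("_l$", ids, value = TRUE)
  mirror <- stats::setNames(ids, ids)
  mirror[lat] <- sub("_l$", "_r", lat)
  mirror[sub("_l$", "_r", lat)] <- lat

  defs <- data.frame(
    index = 0:10,
    name  = FACE_COORDS,
    axis  = c("vertical", "vertical", "vertical", "vertical", "vertical",
              "horizontal", "horizontal", "horizontal", "horizontal",
              "horizontal", "horizontal"),
    a = c("eye_center_r", "face_top", "eye_center_r", "nose_base",
          "mouth_center", "zygomatic_l", "eye_center_l", "mouth_corner_l",
          "eye_inner_r", "nose_wing_l", "jaw_l"),
    b = c("zygomatic_r", "eye_center_r", "nose_base", "mouth_center",
          "chin", "zygomatic_r", "eye_center_r", "mouth_corner_r",
          "eye_outer_r", "nose_wing_r", "jaw_r"),
    stringsAsFactors = FALSE
  )

  reference <- c(0.12, 0.45, 0.25, 0.10, 0.20,
                 0.75, 0.30, 0.28, 0.12, 0.20, 0.60)
  names(reference) <- FACE_COORDS

  schema <- structure(list(
    landmark_ids = ids,
    mirror = mirror,
    distance_defs = defs,
    constraint_indices = 1:4,
    free_landmarks = c("eye_center_r", "eye_outer_r", "zygomatic_r",
                       "nose_base", "nose_wing_r", "mouth_corner_r",
                       "jaw_r"),
    free_coordinates = data.frame(
      landmark = c("eye_center_r", "eye_center_r", "eye_outer_r",
                   "zygomatic_r", "zygomatic_r", "nose_base",
                   "nose_wing_r", "mouth_corner_r", "mouth_corner_r",
                   "jaw_r"),
      axis = c("x", "y", "x", "x", "y", "y", "x", "x", "y", "x"),
      stringsAsFactors = FALSE
    ),
    height_pair = c(top = "face_top", bottom = "chin"),
    # y of these landmarks rides on the line defined by the anchor landmark
    y_anchor = c(eye_inner_l = "eye_center_l", eye_inner_r = "eye_center_r",
                 eye_outer_l = "eye_center_l", eye_outer_r = "eye_center_r",
                 nose_wing_l = "nose_base", nose_wing_r = "nose_base",
                 mouth_corner_l = "mouth_center",
                 mouth_corner_r = "mouth_center"),
    # horizontal defs between same-side landmarks are centered on this one
    x_center = c(d_8 = "eye_center_r"),
    reference = reference,
    bounds = list(lo = (1 - bounds_factor) * reference,
                  hi = (1 + bounds_factor) * reference),
    # fallback positions for coordinates no distance determines (jaw height)
    default_positions = NULL
  ), class = "face_schema")
  schema$default_positions <- .default_positions(schema)
  validate_schema(schema)
  schema
}

# Hand-placed default landmark positions for the shipped schema, used (a) to
# orient sign conventions during generic placement and (b) as fallback for
# coordinates not determined by any distance (the jaw height).
.default_positions <- function(schema) {
  r <- schema$reference
  ey <- r["d_1"]
  ny <- ey + r["d_2"]
  my <- ny + r["d_3"]
  zy <- ey + r["d_0"]
  jy <- 0.85  # jaw height: not fixed by any distance, anatomical default
  pos <- rbind(
    face_top       = c(0, 0),
    chin           = c(0, 1),
    nose_base      = c(0, ny),
    mouth_center   = c(0, my),
    eye_center_r   = c(r["d_6"] / 2, ey),
    eye_inner_r    = c(r["d_6"] / 2 - r["d_8"] / 2, ey),
    eye_outer_r    = c(r["d_6"] / 2 + r["d_8"] / 2, ey),
    nose_wing_r    = c(r["d_9"] / 2, ny),
    mouth_corner_r = c(r["d_7"] / 2, my),
    zygomatic_r    = c(r["d_5"] / 2, zy),
    jaw_r          = c(r["d_10"] / 2, jy)
  )
  left <- pos[grep("_r$", rownames(pos)), , drop = FALSE]
  left[, 1] <- -left[, 1]
  rownames(left) <- sub("_r$", "_l", rownames(left))
  pos <- rbind(pos, left)
  out <- data.frame(id = rownames(pos), x = unname(pos[, 1]),
                    y = unname(pos[, 2]), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[match(schema$landmark_ids, out$id), ]
}

#' Validate a face-space schema
#'
#' Checks the structural invariants: exactly 11 uniquely indexed distance
#' definitions, constraint indices referring to vertical definitions, all
#' referenced landmarks declared, and a symmetry map that is an involution.
#'
#' @param schema a `face_schema`.
#' @return The schema, invisibly; signals an error on violation.
#' @export
validate_schema <- function(schema) {
  defs <- schema$distance_defs
  if (nrow(defs) != 11L || anyDuplicated(defs$index))
    stop("schema must contain exactly 11 uniquely indexed distance definitions")
  if (!all(defs$axis[match(schema$constraint_indices, defs$index)] == "vertical"))
    stop("all constraint indices must refer to vertical distance definitions")
  refd <- unique(c(defs$a, defs$b))
  if (!all(refd %in% schema$landmark_ids))
    stop("distance definitions reference undeclared landmarks: ",
         paste(setdiff(refd, schema$landmark_ids), collapse = ", "))
  m <- schema$mirror
  if (!identical(unname(m[m[schema$landmark_ids]]), schema$landmark_ids))
    stop("symmetry map must be an involution")
  lo <- schema$bounds$lo; hi <- schema$bounds$hi
  if (any(lo < 0) || any(hi < lo))
    stop("bounds must satisfy 0 <= lo <= hi")
  invisible(schema)
}

#' @export
print.face_schema <- function(x, ...) {
  cat("Face-space schema:", length(x$landmark_ids), "landmarks,",
      nrow(x$distance_defs), "inter-landmark distances\n")
  cat("Constraint: sum of",
      paste(FACE_COORDS[x$constraint_indices + 1L], collapse = " + "),
      "= 1 (facial-length units)\n")
  print(x$distance_defs, row.names = FALSE)
  invisible(x)
}

#' Project a raw coordinate vector onto the valid face-space
#'
#' Rescales the constrained vertical distances so that their sum (the total
#' facial length) equals 1, then clamps every coordinate into its bounds,
#' iterating rescale and clamp to joint feasibility.  Already-valid vectors
#' are returned unchanged; the operation is idempotent.
#'
#' @param raw numeric vector of 11 finite values (facial-length units).
#' @param schema a `face_schema`.
#' @return A named numeric facial vector satisfying the `h = 1` constraint
#'   (within 1e-9) and the bounds.
#' @export
#' @examples
#' sc <- default_schema()
#' d <- project_to_constraint(sc$reference * 1.7, sc)
#' sum(d[2:5])  # 1
project_to_constraint <- function(raw, schema) {
  if (!is.numeric(raw) || length(raw) != 11L || !all(is.finite(raw)))
    stop("'raw' must be a numeric vector of 11 finite values")
  lo <- unname(schema$bounds$lo); hi <- unname(schema$bounds$hi)
  ci <- match(schema$constraint_indices, schema$distance_defs$index)
  d <- unname(raw)
  s <- sum(d[ci])
  if (s <= 0)
    stop("constraint coordinates sum to a non-positive value; cannot rescale to h = 1")
  if (sum(lo[ci]) > 1 + 1e-12 || sum(hi[ci]) < 1 - 1e-12)
    stop("bounds make the h = 1 constraint unreachable")
  d[ci] <- d[ci] / s
  d <- pmin(pmax(d, lo), hi)
  for (iter in seq_len(100L)) {
    h <- sum(d[ci])
    if (abs(h - 1) <= 1e-12) break
    free <- ci[d[ci] > lo[ci] + 1e-15 & d[ci] < hi[ci] - 1e-15]
    if (length(free) == 0L)
      stop("constraint projection infeasible: all constrained coordinates at bounds")
    target <- 1 - sum(d[setdiff(ci, free)])
    sf <- sum(d[free])
    if (target <= 0 || sf <= 0)
      stop("constraint projection infeasible under the given bounds")
    d[free] <- d[free] * (target / sf)
    d <- pmin(pmax(d, lo), hi)
  }
  if (abs(sum(d[ci]) - 1) > 1e-9)
    stop("constraint projection did not converge")
  names(d) <- FACE_COORDS
  d
}

#' Check a facial vector against the face-space invariants
#'
#' @param d numeric vector of 11 distances.
#' @param schema a `face_schema`.
#' @param tol tolerance on the constraint sum.
#' @return `TRUE` if `d` satisfies the constraint and the bounds.
#' @export
is_valid_face_vector <- function(d, schema, tol = 1e-9) {
  ci <- match(schema$constraint_indices, schema$distance_defs$index)
  is.numeric(d) && length(d) == 11L && all(is.finite(d)) &&
    abs(sum(d[ci]) - 1) <= tol &&
    all(d >= schema$bounds$lo - tol) && all(d <= schema$bounds$hi + tol)
}
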