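#' Reconstruct Cartesian landmark positions from a facial vector
#'
#' Places the 18 landmarks in the face frame (`x` rightward from the
#' midline, `y` downward from the top landmark, facial-length units).
#' Vertical positions accumulate the constrained distances from `y = 0`
#' (the chin therefore lands at `y = 1`), lateral landmarks are placed
#' symmetrically at `x = +/- width/2` about the midline, and coordinates not
#' determined by any distance (the jaw height in the default schema) keep
#' the schema's default positions.
#'
#' @param d a valid facial vector (see [project_to_constraint()]).
#' @param schema a `face_schema`.
#' @return A landmark set: `data.frame` with columns `id`, `x`, `y` and
#'   attribute `frame = "face"`.
#' @export
#' @examples
#' L <- distances_to_landmarks(default_schema()$reference, default_schema())
#' L[L$id == "chin", "y"]  # 1
distances_to_landmarks <- function(d, schema) {
  if (is.null(names(d))) names(d) <- FACE_COORDS
  defs <- schema$distance_defs
  ids <- schema$landmark_ids
  defaults <- schema$default_positions
  x <- stats::setNames(rep(NA_real_, length(ids)), ids)
  y <- x
  top <- schema$height_pair[["top"]]; bottom <- schema$height_pair[["bottom"]]
  x[top] <- 0; y[top] <- 0
  x[bottom] <- 0; y[bottom] <- 1

  defy <- stats::setNames(defaults$y, defaults$id)
  defx <- stats::setNames(defaults$x, defaults$id)

  set_y <- function(y, id, val) {
    y[id] <- val
    y[schema$mirror[[id]]] <- val
    y
  }

  # vertical propagation to a fixed point
  vdefs <- defs[defs$axis == "vertical", , drop = FALSE]
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(vdefs))) {
      a <- vdefs$a[k]; b <- vdefs$b[k]
      dv <- d[[vdefs$name[k]]]
      sgn <- sign(defy[b] - defy[a])
      if (!is.na(y[a]) && is.na(y[b])) {
        y <- set_y(y, b, y[a] + sgn * dv); changed <- TRUE
      } else if (!is.na(y[b]) && is.na(y[a])) {
        y <- set_y(y, a, y[b] - sgn * dv); changed <- TRUE
      }
    }
    if (!changed) break
  }
  # landmarks riding on an already-placed line
  for (id in names(schema$y_anchor)) {
    if (is.na(y[id])) y[id] <- y[schema$y_anchor[[id]]]
  }
  undetermined <- names(y)[is.na(y)]
  y[undetermined] <- defy[undetermined]

  # horizontal placement
  midline <- ids[schema$mirror[ids] == ids]
  x[midline] <- 0
  hdefs <- defs[defs$axis == "horizontal", , drop = FALSE]
  for (k in seq_len(nrow(hdefs))) {
    a <- hdefs$a[k]; b <- hdefs$b[k]
    dv <- d[[hdefs$name[k]]]
    if (identical(schema$mirror[[a]], b)) {
      # mirror pair: symmetric split about the midline
      ra <- if (defx[a] >= 0) a else b   # right-side member
      la <- if (identical(ra, a)) b else a
      x[ra] <- dv / 2; x[la] <- -dv / 2
    } else {
      # same-side pair centered on a third landmark (eye width)
      ctr <- schema$x_center[[hdefs$name[k]]]
      if (is.null(ctr))
        stop("horizontal definition '", hdefs$name[k],
             "' joins same-side landmarks but declares no center landmark")
      inner <- if (abs(defx[a]) <= abs(defx[b])) a else b
      outer <- if (identical(inner, a)) b else a
      sgn <- sign(defx[ctr])
      x[inner] <- x[ctr] - sgn * dv / 2
      x[outer] <- x[ctr] + sgn * dv / 2
      x[schema$mirror[[inner]]] <- -x[inner]
      x[schema$mirror[[outer]]] <- -x[outer]
    }
  }
  if (anyNA(x)) x[is.na(x)] <- defx[names(x)[is.na(x)]]
  if (anyNA(x) || anyNA(y))
    stop("schema leaves a landmark with no determining distance and no default")

  structure(data.frame(id = ids, x = unname(x[ids]), y = unname(y[ids]),
                       stringsAsFactors = FALSE),
            frame = "face")
}

#' Measure a facial vector from landmark positions
#'
#' Each distance is the absolute coordinate difference of its landmark pair
#' along the definition's axis, divided by the face height (top landmark to
#' chin), so the result is scale invariant and, because absolute values are
#' taken, mirror invariant.
#'
#' @param L a landmark set (`data.frame` with `id`, `x`, `y`) in either
#'   frame.
#' @param schema a `face_schema`.
#' @return A named facial vector in facial-length units.
#' @export
landmarks_to_distances <- function(L, schema) {
  defs <- schema$distance_defs
  need <- unique(c(defs$a, defs$b, schema$height_pair))
  if (!all(need %in% L$id))
    stop("landmark set is missing landmarks required by the schema: ",
         paste(setdiff(need, L$id), collapse = ", "))
  px <- stats::setNames(L$x, L$id)
  py <- stats::setNames(L$y, L$id)
  h <- py[[schema$height_pair[["bottom"]]]] - py[[schema$height_pair[["top"]]]]
  if (abs(h) <= .Machine$double.eps)
    stop("zero face height: top and chin landmarks coincide vertically")
  h <- abs(h)
  d <- numeric(11L)
  for (k in seq_len(nrow(defs))) {
    d[k] <- if (defs$axis[k] == "vertical")
      abs(py[[defs$b[k]]] - py[[defs$a[k]]]) / h
    else
      abs(px[[defs$b[k]]] - px[[defs$a[k]]]) / h
  }
  names(d) <- defs$name
  d
}

#' Non-redundant Cartesian coordinates of the free landmarks
#'
#' Reduces a facial vector to the 10 non-redundant Cartesian coordinates of
#' the 7 free landmarks (in the default schema: right eye center x and y,
#' right outer eye corner x, right zygomatic x and y, nose base y, right
#' nose wing x, right mouth corner x and y, right jaw x).  The midline-
#' landmark x's and the frame-fixing coordinates (top landmark at y = 0,
#' chin at y = 1) are omitted.  The mapping is invertible:
#' [cartesian_to_distances()] recovers the distance vector exactly.
#'
#' @param d a valid facial vector.
#' @param schema a `face_schema`.
#' @return Named numeric vector of length 10.
#' @export
cartesian_coordinates <- function(d, schema) {
  L <- distances_to_landmarks(d, schema)
  fc <- schema$free_coordinates
  px <- stats::setNames(L$x, L$id); py <- stats::setNames(L$y, L$id)
  out <- ifelse(fc$axis == "x", px[fc$landmark], py[fc$landmark])
  stats::setNames(as.numeric(out), paste0(fc$landmark, ".", fc$axis))
}

#' Recover a facial vector from the non-redundant Cartesian coordinates
#'
#' Inverse of [cartesian_coordinates()]: rebuilds the free landmark
#' positions (filling the omitted coordinates from the frame conventions,
#' the line anchors and the schema defaults, and mirroring to the left
#' side), then measures the distances.
#'
#' @param z named numeric vector of length 10 as returned by
#'   [cartesian_coordinates()].
#' @param schema a `face_schema`.
#' @return A named facial vector.
#' @export
cartesian_to_distances <- function(z, schema) {
  fc <- schema$free_coordinates
  if (length(z) != nrow(fc))
    stop("expected ", nrow(fc), " Cartesian coordinates, got ", length(z))
  ids <- schema$landmark_ids
  x <- stats::setNames(rep(NA_real_, length(ids)), ids)
  y <- x
  top <- schema$height_pair[["top"]]; bottom <- schema$height_pair[["bottom"]]
  x[top] <- 0; y[top] <- 0; x[bottom] <- 0; y[bottom] <- 1
  midline <- ids[schema$mirror[ids] == ids]
  x[midline] <- 0
  for (k in seq_len(nrow(fc))) {
    if (fc$axis[k] == "x") x[fc$landmark[k]] <- z[[k]]
    else y[fc$landmark[k]] <- z[[k]]
  }
  # omitted y's of free landmarks ride on their anchor line
  for (id in names(schema$y_anchor)) {
    anchor <- schema$y_anchor[[id]]
    if (is.na(y[id]) && !is.na(y[anchor])) y[id] <- y[anchor]
    if (!is.na(y[id]) && is.na(y[anchor])) y[anchor] <- y[id]
  }
  defaults <- schema$default_positions
  defy <- stats::setNames(defaults$y, defaults$id)
  defx <- stats::setNames(defaults$x, defaults$id)
  y[is.na(y)] <- defy[names(y)[is.na(y)]]
  # same-side pairs centered on a third landmark: reflect about the center
  for (nm in names(schema$x_center)) {
    def <- schema$distance_defs[schema$distance_defs$name == nm, ]
    ctr <- schema$x_center[[nm]]
    for (ep in c(def$a, def$b)) {
      other <- setdiff(c(def$a, def$b), ep)
      if (is.na(x[ep]) && !is.na(x[other]) && !is.na(x[ctr]))
        x[ep] <- 2 * x[ctr] - x[other]
    }
  }
  # mirror to the unset side
  for (id in ids) {
    mid <- schema$mirror[[id]]
    if (is.na(x[id]) && !is.na(x[mid])) x[id] <- -x[mid]
    if (is.na(y[id]) && !is.na(y[mid])) y[id] <- y[mid]
  }
  x[is.na(x)] <- defx[names(x)[is.na(x)]]
  L <- structure(data.frame(id = ids, x = unname(x[ids]), y = unname(y[ids]),
                            stringsAsFactors = FALSE),
                 frame = "face")
  landmarks_to_distances(L, schema)
}

#' Convert landmark positions between the face and pixel frames
#'
#' The pixel frame has its origin at the top-left corner of the image with
#' `x` along columns and `y` along rows; the face frame is anchored at the
#' top landmark with unit facial length.  `face_to_pixel()` maps face-frame
#' positions given the facial length in pixels and the pixel position of the
#' top landmark; `pixel_to_face()` derives both from the landmark set
#' itself.
#'
#' @param L a landmark set.
#' @param length_px facial length in pixels.
#' @param origin pixel position `c(x, y)` of the face-frame origin (the top
#'   landmark on the midline).
#' @param schema a `face_schema` (used by `pixel_to_face` to find the top
#'   and chin landmarks).
#' @return A landmark set in the requested frame.
#' @export
face_to_pixel <- function(L, length_px, origin) {
  stopifnot(identical(attr(L, "frame"), "face"), length_px > 0)
  out <- L
  out$x <- origin[1] + L$x * length_px
  out$y <- origin[2] + L$y * length_px
  attr(out, "frame") <- "pixel"
  attr(out, "length_px") <- length_px
  out
}

#' @rdname face_to_pixel
#' @export
pixel_to_face <- function(L, schema) {
  stopifnot(identical(attr(L, "frame"), "pixel"))
  top <- schema$height_pair[["top"]]; bottom <- schema$height_pair[["bottom"]]
  py <- stats::setNames(L$y, L$id); px <- stats::setNames(L$x, L$id)
  len <- py[[bottom]] - py[[top]]
  if (len <= 0) stop("zero or negative face height in pixel landmarks")
  out <- L
  out$x <- (L$x - px[[top]]) / len
  out$y <- (L$y - py[[top]]) / len
  attr(out, "frame") <- "face"
  attr(out, "length_px") <- len
  out
}
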