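#' Moving-least-squares similarity transform at a point
#'
#' Evaluates the point-dependent linear transformation of the
#' moving-least-squares deformation restricted to the *similarity class*
#' (rotation plus uniform scale plus translation).  With weights
#' `w_a = |p_a - v|^(-2*alpha)` and weighted centroids `p*`, `q*`, the map is
#' `f(v) = (v - p*) M + q*` where `M = [[a, -b], [b, a]]` is the similarity
#' matrix minimizing the weighted least-squares mismatch between the
#' centered control points:
#' `a = sum(w (phat . qhat)) / mu`, `b = sum(w (phat_perp . qhat)) / mu`,
#' `mu = sum(w |phat|^2)` and `phat_perp = (-phat_y, phat_x)`.
#' If `v` coincides with a control point its target is returned directly.
#' The map reproduces any global similarity of the control points exactly.
#'
#' @param v numeric length-2 point, or an n x 2 matrix of points.
#' @param p,q matrices of source and target control points (rows paired).
#' @param alpha positive weight exponent (default 1).
#' @return The mapped point(s), same shape as `v`.
#' @export
local_similarity <- function(v, p, q, alpha = 1) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (nrow(p) != nrow(q) || ncol(p) != 2L || ncol(q) != 2L)
    stop("'p' and 'q' must be matrices of paired 2D control points")
  if (nrow(p) < 3L) stop("at least 3 control points are required")
  if (alpha <= 0) stop("'alpha' must be positive")
  if (is.matrix(v)) {
    out <- t(apply(v, 1L, local_similarity, p = p, q = q, alpha = alpha))
    dimnames(out) <- dimnames(v)
    return(out)
  }
  d2 <- (p[, 1] - v[1])^2 + (p[, 2] - v[2])^2
  hit <- which(d2 < .Machine$double.eps)
  if (length(hit)) return(as.numeric(q[hit[1L], ]))
  w <- d2^(-alpha)
  sw <- sum(w)
  pstar <- c(sum(w * p[, 1]), sum(w * p[, 2])) / sw
  qstar <- c(sum(w * q[, 1]), sum(w * q[, 2])) / sw
  ph1 <- p[, 1] - pstar[1]; ph2 <- p[, 2] - pstar[2]
  qh1 <- q[, 1] - qstar[1]; qh2 <- q[, 2] - qstar[2]
  mu <- sum(w * (ph1^2 + ph2^2))
  if (mu <= 0) stop("degenerate control-point geometry (all sources coincide)")
  a <- sum(w * (ph1 * qh1 + ph2 * qh2)) / mu
  b <- sum(w * (-ph2 * qh1 + ph1 * qh2)) / mu
  vh1 <- v[1] - pstar[1]; vh2 <- v[2] - pstar[2]
  c(vh1 * a - vh2 * b + qstar[1],
    vh1 * b + vh2 * a + qstar[2])
}

# Bilinear sample of image `img` (matrix, rows = y, cols = x, 1-based pixel
# centers) at continuous positions (xs, ys); positions clamped to the grid.
bilinear_sample <- function(img, xs, ys) {
  H <- nrow(img); W <- ncol(img)
  xs <- pmin(pmax(xs, 1), W)
  ys <- pmin(pmax(ys, 1), H)
  x0 <- pmin(floor(xs), W - 1L); y0 <- pmin(floor(ys), H - 1L)
  fx <- xs - x0; fy <- ys - y0
  i00 <- (x0 - 1) * H + y0
  img[i00] * (1 - fx) * (1 - fy) +
    img[i00 + H] * fx * (1 - fy) +
    img[i00 + 1] * (1 - fx) * fy +
    img[i00 + H + 1] * fx * fy
}

#' Deform a grayscale raster image by grid-sampled MLS warping
#'
#' The similarity-class moving-least-squares map is evaluated only at the
#' vertices of a coarse sub-grid (spacing at most 15 pixels); each grid cell
#' is split into two triangles (diagonal from top-left to bottom-right) and
#' every destination triangle is filled by inverse-affine sampling of its
#' source triangle with bilinear interpolation.  Destination pixels covered
#' by no triangle are filled with the nearest covered value.
#'
#' @param img numeric matrix of grayscale intensities in `[0, 1]`, at least
#'   16 x 16, pixel frame origin top-left (rows = y, columns = x).
#' @param p,q source and target control points (n x 2 matrices of pixel
#'   `(x, y)` positions).
#' @param grid_px sub-grid spacing in pixels, between 2 and 15.
#' @param alpha MLS weight exponent.
#' @param max_inverted_frac maximal tolerated fraction of destination
#'   triangles with inverted (negative-area) orientation before the warp is
#'   rejected as geometrically invalid.
#' @return The deformed image, same dimensions as the input.
#' @export
deform_image <- function(img, p, q, grid_px = 15L, alpha = 1,
                         max_inverted_frac = 0.01) {
  if (!is.matrix(img) || nrow(img) < 16L || ncol(img) < 16L)
    stop("'img' must be a numeric matrix of at least 16 x 16 pixels")
  if (!all(is.finite(img))) stop("'img' contains non-finite intensities")
  if (grid_px < 2L || grid_px > 15L)
    stop("'grid_px' must lie in [2, 15]")
  H <- nrow(img); W <- ncol(img)
  xs <- unique(c(seq(1, W, by = grid_px), W))
  ys <- unique(c(seq(1, H, by = grid_px), H))
  nx <- length(xs); ny <- length(ys)
  verts <- cbind(rep(xs, each = ny), rep(ys, times = nx))
  # snap one lattice vertex onto each control point: the MLS map is exact at
  # control points, so landmarks sit on triangulation vertices and are
  # pinned to their targets instead of being interpolated across a cell.
  # Assignments are made closest-first so neighboring landmarks do not
  # steal each other's nearest vertex.
  inb <- p[, 1] >= 1 & p[, 1] <= W & p[, 2] >= 1 & p[, 2] <= H
  d2m <- outer(p[, 1], verts[, 1], "-")^2 + outer(p[, 2], verts[, 2], "-")^2
  d2m[!inb, ] <- Inf
  for (iter in seq_len(sum(inb))) {
    j <- arrayInd(which.min(d2m), dim(d2m))
    if (!is.finite(d2m[j[1], j[2]])) break
    verts[j[2], ] <- p[j[1], ]
    d2m[j[1], ] <- Inf
    d2m[, j[2]] <- Inf
  }
  mapped <- local_similarity(verts, p, q, alpha = alpha)

  out <- matrix(NA_real_, H, W)
  vid <- function(ix, iy) (ix - 1L) * ny + iy
  n_inv <- 0L; n_tri <- 0L
  for (ix in seq_len(nx - 1L)) {
    for (iy in seq_len(ny - 1L)) {
      i00 <- vid(ix, iy); i10 <- vid(ix + 1L, iy)
      i01 <- vid(ix, iy + 1L); i11 <- vid(ix + 1L, iy + 1L)
      # diagonal top-left -> bottom-right
      for (tri in list(c(i00, i10, i11), c(i00, i11, i01))) {
        n_tri <- n_tri + 1L
        S <- verts[tri, , drop = FALSE]
        D <- mapped[tri, , drop = FALSE]
        det_d <- (D[2, 1] - D[1, 1]) * (D[3, 2] - D[1, 2]) -
                 (D[3, 1] - D[1, 1]) * (D[2, 2] - D[1, 2])
        det_s <- (S[2, 1] - S[1, 1]) * (S[3, 2] - S[1, 2]) -
                 (S[3, 1] - S[1, 1]) * (S[2, 2] - S[1, 2])
        if (det_d * det_s < 0) n_inv <- n_inv + 1L
        if (abs(det_d) < .Machine$double.eps) next
        cx0 <- max(1L, floor(min(D[, 1]))); cx1 <- min(W, ceiling(max(D[, 1])))
        cy0 <- max(1L, floor(min(D[, 2]))); cy1 <- min(H, ceiling(max(D[, 2])))
        if (cx0 > cx1 || cy0 > cy1) next
        px <- rep(cx0:cx1, each = cy1 - cy0 + 1L)
        py <- rep(cy0:cy1, times = cx1 - cx0 + 1L)
        # barycentric coordinates w.r.t. destination triangle
        l1 <- ((D[2, 2] - D[3, 2]) * (px - D[3, 1]) +
               (D[3, 1] - D[2, 1]) * (py - D[3, 2])) / det_d
        l2 <- ((D[3, 2] - D[1, 2]) * (px - D[3, 1]) +
               (D[1, 1] - D[3, 1]) * (py - D[3, 2])) / det_d
        l3 <- 1 - l1 - l2
        tol <- 1e-9
        inside <- l1 >= -tol & l2 >= -tol & l3 >= -tol
        if (!any(inside)) next
        sx <- l1[inside] * S[1, 1] + l2[inside] * S[2, 1] + l3[inside] * S[3, 1]
        sy <- l1[inside] * S[1, 2] + l2[inside] * S[2, 2] + l3[inside] * S[3, 2]
        out[cbind(py[inside], px[inside])] <- bilinear_sample(img, sx, sy)
      }
    }
  }
  if (n_inv / n_tri > max_inverted_frac)
    stop(sprintf("deformation folds the image: %.1f%% of destination triangles are inverted",
                 100 * n_inv / n_tri))
  # fill uncovered destination pixels with the nearest covered value
  while (anyNA(out)) {
    na_idx <- which(is.na(out))
    r <- ((na_idx - 1L) %% H) + 1L
    cl <- ((na_idx - 1L) %/% H) + 1L
    filled <- FALSE
    for (off in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))) {
      rr <- pmin(pmax(r + off[1L], 1L), H)
      cc <- pmin(pmax(cl + off[2L], 1L), W)
      nb <- out[cbind(rr, cc)]
      take <- is.na(out[na_idx]) & !is.na(nb)
      if (any(take)) {
        out[na_idx[take]] <- nb[take]
        filled <- TRUE
      }
    }
    if (!filled) break
  }
  out
}

#' Render a facial vector on a reference portrait
#'
#' Builds the target pixel landmark positions implied by the facial vector
#' `d` (face frame mapped to pixels using the reference portrait's facial
#' length in pixels and the midline `x` of its top landmark; lateral
#' landmarks placed symmetrically), pairs them with the reference portrait's
#' own landmarks as warp control points, and deforms the portrait.
#' Landmarks present in `ref_landmarks` but absent from the schema are kept
#' fixed (target = source).  The result is deterministic for fixed inputs.
#'
#' @param reference grayscale image matrix (the reference portrait).
#' @param ref_landmarks pixel-frame landmark set of the reference portrait.
#' @param d a valid facial vector.
#' @param schema a `face_schema`.
#' @param grid_px warp sub-grid spacing (default 15 pixels).
#' @param alpha MLS weight exponent.
#' @return The deformed portrait (image matrix, same size as `reference`).
#' @export
#' @examples
#' fx <- make_fixture_image(120, 160)
#' d <- landmarks_to_distances(fx$landmarks, default_schema())
#' identity_render <- render_face(fx$image, fx$landmarks, d, default_schema())
render_face <- function(reference, ref_landmarks, d, schema,
                        grid_px = 15L, alpha = 1) {
  stopifnot(identical(attr(ref_landmarks, "frame"), "pixel"))
  top <- schema$height_pair[["top"]]; bottom <- schema$height_pair[["bottom"]]
  px <- stats::setNames(ref_landmarks$x, ref_landmarks$id)
  py <- stats::setNames(ref_landmarks$y, ref_landmarks$id)
  L_px <- py[[bottom]] - py[[top]]
  if (L_px <= 0) stop("reference landmarks have non-positive facial length")
  origin <- c(px[[top]], py[[top]])
  target_face <- distances_to_landmarks(d, schema)
  target <- face_to_pixel(target_face, L_px, origin)
  tx <- stats::setNames(target$x, target$id)
  ty <- stats::setNames(target$y, target$id)
  ids <- ref_landmarks$id
  qx <- px[ids]; qy <- py[ids]
  in_schema <- ids %in% schema$landmark_ids
  qx[in_schema] <- tx[ids[in_schema]]
  qy[in_schema] <- ty[ids[in_schema]]
  H <- nrow(reference); W <- ncol(reference)
  if (any(qx < 1 | qx > W | qy < 1 | qy > H))
    stop("target landmarks fall outside the image bounds")
  p <- cbind(px[ids], py[ids])
  q <- cbind(qx, qy)
  deform_image(reference, p, q, grid_px = grid_px, alpha = alpha)
}

#' Read and write grayscale face images
#'
#' Images are stored as numeric matrices with intensities in `[0, 1]`,
#' origin at the top-left pixel.  PNG files are read with the \pkg{png}
#' package; color images are converted to grayscale by the Rec. 601 luma
#' weights on load.
#'
#' @param path file path (PNG).
#' @param img image matrix to write.
#' @return `read_face_image()` returns an image matrix; `write_face_image()`
#'   returns `path` invisibly.
#' @export
read_face_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L)
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    else a <- a[, , 1]
  }
  a
}

#' @rdname read_face_image
#' @export
write_face_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Locate dark fiducial dots in an image
#'
#' Finds, for each approximate position, the darkness-weighted centroid in a
#' square search window: a simple detector for the fiducial dots burned into
#' the synthetic portrait fixture, used to verify that warps move landmarks
#' to their predicted pixel positions.
#'
#' @param img image matrix.
#' @param approx n x 2 matrix of approximate `(x, y)` pixel positions.
#' @param radius half-width of the search window in pixels.
#' @return n x 2 matrix of refined positions.
#' @export
locate_fiducials <- function(img, approx, radius = 4L) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(NA_real_, nrow(approx), 2L)
  for (k in seq_len(nrow(approx))) {
    cx <- round(approx[k, 1]); cy <- round(approx[k, 2])
    xr <- max(1L, cx - radius):min(W, cx + radius)
    yr <- max(1L, cy - radius):min(H, cy + radius)
    win <- img[yr, xr, drop = FALSE]
    # only pixels in the darkest band of the window count as dot evidence,
    # so nearby dark facial features do not drag the centroid
    thr <- min(win) + 0.3 * (max(win) - min(win))
    wgt <- pmax(thr - win, 0)^2
    if (sum(wgt) <= 0) next
    out[k, ] <- c(sum(wgt * rep(xr, each = length(yr))),
                  sum(wgt * rep(yr, times = length(xr)))) / sum(wgt)
  }
  out
}
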