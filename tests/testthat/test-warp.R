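test_that("MLS similarity map reproduces identity, translation and global similarity", {
  set.seed(10)
  p <- matrix(runif(36, 5, 95), 18, 2)
  vs <- matrix(runif(40, 1, 99), 20, 2)
  # identity
  expect_equal(local_similarity(vs, p, p), vs, tolerance = 1e-9)
  # pure translation
  tr <- matrix(c(7.5, -3.25), 18, 2, byrow = TRUE)
  expect_equal(local_similarity(vs, p, p + tr),
               vs + matrix(c(7.5, -3.25), 20, 2, byrow = TRUE),
               tolerance = 1e-9)
  # global similarity: rotation 30 degrees, scale 1.2, translation
  th <- 30 * pi / 180; s <- 1.2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- function(x) t(s * R %*% t(x)) + matrix(c(4, -2), nrow(x), 2,
                                              byrow = TRUE)
  expect_equal(local_similarity(vs, p, S(p)), S(vs), tolerance = 1e-9)
  # control points map exactly to their targets
  q <- p + matrix(rnorm(36, 0, 3), 18, 2)
  expect_equal(local_similarity(p, p, q), q, tolerance = 1e-12)
  # degenerate geometry signals
  p0 <- matrix(rep(c(5, 5), each = 3), 3, 2)
  expect_error(local_similarity(c(1, 1), p0, p0 + 1), "degenerate")
})

test_that("grid deformation is exact for identity and integer translation", {
  sc <- default_schema()
  fx <- make_fixture_image(120, 160, sc)
  p <- cbind(fx$landmarks$x, fx$landmarks$y)
  out <- deform_image(fx$image, p, p, grid_px = 13)
  expect_lt(max(abs(out - fx$image)), 1 / 255)
  # intensities stay within the input range (bilinear sampling)
  expect_gte(min(out), min(fx$image))
  expect_lte(max(out), max(fx$image))
  # integer-pixel translation equals the shifted input on the overlap
  tr <- deform_image(fx$image, p,
                     p + matrix(c(4, 3), nrow(p), 2, byrow = TRUE),
                     grid_px = 13)
  expect_lt(max(abs(tr[20:150, 20:110] - fx$image[17:147, 16:106])), 1e-9)
  # determinism: identical inputs give bit-identical output
  expect_identical(out, deform_image(fx$image, p, p, grid_px = 13))
  expect_error(deform_image(fx$image, p, p, grid_px = 30), "grid_px")
})

test_that("rendering a vector moves the fiducial landmarks to their targets", {
  sc <- default_schema()
  fx <- make_fixture_image(150, 200, sc, fiducials = TRUE)
  d0 <- landmarks_to_distances(fx$landmarks, sc)
  # identity warp reproduces the reference
  id <- render_face(fx$image, fx$landmarks, d0, sc)
  expect_lt(max(abs(id - fx$image)), 1 / 255)
  # a deformed vector lands every fiducial within 1 px of its prediction
  d1 <- d0
  d1["d_7"] <- d0["d_7"] * 1.5
  d1["d_6"] <- d0["d_6"] * 0.85
  d1 <- project_to_constraint(d1, sc)
  w <- render_face(fx$image, fx$landmarks, d1, sc, grid_px = 15)
  L_px <- attr(pixel_to_face(fx$landmarks, sc), "length_px")
  tgt <- face_to_pixel(distances_to_landmarks(d1, sc), L_px,
                       c(fx$landmarks$x[1], fx$landmarks$y[1]))
  det <- locate_fiducials(w, cbind(tgt$x, tgt$y), radius = 3)
  err <- sqrt(rowSums((det - cbind(tgt$x, tgt$y))^2))
  expect_lt(max(err), 1)
  # doubling the mouth width (clamped into bounds by the projection) moves
  # only the mouth-corner fiducials, each by the predicted pixel offset
  d2 <- d0; d2["d_7"] <- 2 * d0["d_7"]
  d2 <- project_to_constraint(d2, sc)
  w2 <- render_face(fx$image, fx$landmarks, d2, sc, grid_px = 15)
  src <- cbind(fx$landmarks$x, fx$landmarks$y)
  mouth <- fx$landmarks$id %in% c("mouth_corner_l", "mouth_corner_r")
  # non-mouth fiducials stay put
  det2 <- locate_fiducials(w2, src[!mouth, ], radius = 3)
  expect_true(all(sqrt(rowSums((det2 - src[!mouth, ])^2)) < 1))
  # mouth corners are found at their predicted targets, half the width
  # increase away from their sources
  predicted <- (d2[["d_7"]] - d0[["d_7"]]) / 2 * L_px
  expect_gt(predicted, 5)
  tgt2 <- face_to_pixel(distances_to_landmarks(d2, sc), L_px,
                        c(fx$landmarks$x[1], fx$landmarks$y[1]))
  det2m <- locate_fiducials(w2, cbind(tgt2$x, tgt2$y)[mouth, ], radius = 3)
  expect_lt(max(abs(det2m - cbind(tgt2$x, tgt2$y)[mouth, ])), 1)
  moved <- sqrt(rowSums((det2m - src[mouth, ])^2))
  expect_equal(unname(moved), rep(predicted, 2), tolerance = 0.1)
})

test_that("the same vector rendered on two reference portraits matches geometrically", {
  sc <- default_schema()
  fxA <- make_fixture_image(150, 200, sc, fiducials = TRUE)
  fxB <- make_fixture_image(120, 170, sc, fiducials = TRUE)
  d <- landmarks_to_distances(fxA$landmarks, sc)
  d["d_9"] <- d["d_9"] * 1.3
  d <- project_to_constraint(d, sc)
  for (fx in list(fxA, fxB)) {
    w <- render_face(fx$image, fx$landmarks, d, sc)
    L_px <- attr(pixel_to_face(fx$landmarks, sc), "length_px")
    tgt <- face_to_pixel(distances_to_landmarks(d, sc), L_px,
                         c(fx$landmarks$x[1], fx$landmarks$y[1]))
    det <- locate_fiducials(w, cbind(tgt$x, tgt$y), radius = 3)
    Ld <- fx$landmarks; Ld$x <- det[, 1]; Ld$y <- det[, 2]
    dm <- landmarks_to_distances(Ld, sc)
    # re-measured distances agree with the requested vector to ~1 px/L
    expect_lt(max(abs(dm - d)), 1.5 / L_px)
  }
})

test_that("face images survive a PNG write/read round trip", {
  fx <- make_fixture_image(80, 90)
  path <- tempfile(fileext = ".png")
  write_face_image(fx$image, path)
  back <- read_face_image(path)
  expect_equal(dim(back), dim(fx$image))
  expect_lt(max(abs(back - fx$image)), 1 / 255)
  unlink(path)
})
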