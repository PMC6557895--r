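test_that("default schema satisfies its structural invariants", {
  sc <- default_schema()
  expect_equal(nrow(sc$distance_defs), 11L)
  expect_false(anyDuplicated(sc$distance_defs$index) > 0)
  # constraint indices refer to vertical definitions
  ci_axis <- sc$distance_defs$axis[match(sc$constraint_indices,
                                         sc$distance_defs$index)]
  expect_true(all(ci_axis == "vertical"))
  expect_setequal(sc$constraint_indices, 1:4)
  # symmetry map is an involution
  expect_identical(unname(sc$mirror[sc$mirror[sc$landmark_ids]]),
                   sc$landmark_ids)
  expect_length(sc$free_landmarks, 7L)
  expect_equal(nrow(sc$free_coordinates), 10L)
  expect_silent(validate_schema(sc))
})

test_that("constraint projection rescales, clamps and is idempotent", {
  sc <- default_schema()
  # uniform rescale, isolated from the bounds by widening them
  sc_wide <- sc
  sc_wide$bounds$lo[] <- 0
  sc_wide$bounds$hi[] <- 2
  raw <- sc$reference
  raw[2:5] <- 0.5
  d <- project_to_constraint(raw, sc_wide)
  expect_equal(unname(d[2:5]), rep(0.25, 4))
  # with the default bounds the rescale is clamped into feasibility
  d2b <- project_to_constraint(raw, sc)
  expect_equal(sum(d2b[2:5]), 1, tolerance = 1e-12)
  expect_true(all(d2b >= sc$bounds$lo - 1e-12 & d2b <= sc$bounds$hi + 1e-12))
  # already-valid sums pass through unchanged
  raw2 <- sc$reference
  raw2[2:5] <- c(0.4, 0.3, 0.15, 0.15) * c(1, 1, 1, 1)
  raw2[2:5] <- c(0.45, 0.3, 0.1, 0.15)  # within bounds, sums to 1
  expect_equal(project_to_constraint(raw2, sc), raw2,
               ignore_attr = FALSE)
  # idempotence on random projected vectors
  set.seed(1)
  for (i in 1:20) {
    d <- random_face_vector(sc)
    expect_equal(project_to_constraint(d, sc), d)
    expect_true(abs(sum(d[2:5]) - 1) <= 1e-9)
  }
  # infeasible inputs signal
  bad <- sc$reference; bad[2:5] <- c(-1, 0.1, 0.1, 0.1)
  expect_error(project_to_constraint(bad, sc), "non-positive")
  expect_error(project_to_constraint(rep(NA_real_, 11), sc), "finite")
})

test_that("distances and landmarks are inverse, scale- and mirror-invariant", {
  sc <- default_schema()
  d <- sc$reference
  d[2:5] <- 0.25
  L <- distances_to_landmarks(d, sc)
  py <- setNames(L$y, L$id)
  expect_equal(unname(py["eye_center_r"]), 0.25)
  expect_equal(unname(py["eye_center_l"]), 0.25)
  expect_equal(unname(py["chin"]), 1.0)
  # symmetric split of the inter-eye distance
  d2 <- sc$reference; d2["d_6"] <- 0.3
  L2 <- distances_to_landmarks(d2, sc)
  px <- setNames(L2$x, L2$id)
  expect_equal(unname(px["eye_center_r"]), 0.15)
  expect_equal(unname(px["eye_center_l"]), -0.15)
  set.seed(2)
  for (i in 1:20) {
    dd <- random_face_vector(sc)
    LL <- distances_to_landmarks(dd, sc)
    # bilateral symmetry about x = 0
    xs <- setNames(LL$x, LL$id)
    expect_equal(unname(xs[sc$mirror[LL$id]]), -unname(xs[LL$id]),
                 tolerance = 1e-12)
    # round trip
    expect_equal(landmarks_to_distances(LL, sc), dd, tolerance = 1e-12)
    # scale invariance
    Ls <- LL; Ls$x <- 2 * Ls$x; Ls$y <- 2 * Ls$y
    expect_equal(landmarks_to_distances(Ls, sc), dd, tolerance = 1e-12)
    # mirror invariance
    Lm <- LL; Lm$x <- -Lm$x
    expect_equal(landmarks_to_distances(Lm, sc), dd, tolerance = 1e-12)
  }
  # zero face height signals
  L0 <- L; L0$y[] <- 0
  expect_error(landmarks_to_distances(L0, sc), "face height")
})

test_that("the 10 non-redundant Cartesian coordinates are a bijection", {
  sc <- default_schema()
  set.seed(3)
  for (i in 1:20) {
    d <- random_face_vector(sc)
    z <- cartesian_coordinates(d, sc)
    expect_length(z, 10L)
    expect_equal(cartesian_to_distances(z, sc), d, tolerance = 1e-12)
  }
  # a change in mouth width alone moves only the mouth-corner x coordinate
  d <- sc$reference
  d2 <- d; d2["d_7"] <- d["d_7"] + 0.05
  delta <- cartesian_coordinates(d2, sc) - cartesian_coordinates(d, sc)
  expect_equal(names(delta)[which(abs(delta) > 1e-12)],
               "mouth_corner_r.x")
})

test_that("standardization has unit moments on the reference subset", {
  set.seed(4)
  sc <- default_schema()
  recs <- population_records(random_population(30, sc))
  ds <- standardize(recs)
  expect_equal(unname(colMeans(ds$y)), rep(0, 11), tolerance = 1e-9)
  expect_equal(unname(apply(ds$y, 2, sd)), rep(1, 11), tolerance = 1e-9)
  # a record equal to the mean vector standardizes to zero
  recs2 <- rbind(recs, population_records(matrix(ds$center, 1),
                                          subject_id = "mean"))
  ds2 <- standardize(recs2, reference = seq_len(nrow(recs)))
  expect_equal(unname(ds2$y[nrow(recs2), ]), rep(0, 11), tolerance = 1e-9)
  # a coordinate that is constant across the reference subset must signal
  const <- random_population(3, sc)
  const[, 1] <- 0.12
  expect_error(standardize(population_records(const)), "zero-variance")
  # sd of a 3-record toy set against direct two-pass arithmetic
  set.seed(5)
  toy <- random_population(3, sc)
  ds3 <- standardize(population_records(toy))
  mu_hand <- unname((toy[1, 1] + toy[2, 1] + toy[3, 1]) / 3)
  sd_hand <- unname(sqrt(((toy[1, 1] - mu_hand)^2 + (toy[2, 1] - mu_hand)^2 +
                            (toy[3, 1] - mu_hand)^2) / 2))
  expect_equal(unname(ds3$center[["d_0"]]), mu_hand)
  expect_equal(unname(ds3$scale[["d_0"]]), sd_hand)
})
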