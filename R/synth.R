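#' Attractor covariance with planted correlations
#'
#' Builds the covariance matrix of the latent attractor distribution from a
#' per-coordinate standard deviation and an optional set of planted
#' pairwise correlations.
#'
#' @param sd scalar or length-11 vector of per-coordinate standard
#'   deviations, in facial-length units.  The default 0.018 matches the
#'   coordinate spread observed across sculpted facial vectors.
#' @param cor optional `data.frame` with columns `i`, `j` (0-based
#'   coordinate indices or `d_*` names) and `rho`, or a full 11 x 11
#'   correlation matrix.
#' @return An 11 x 11 covariance matrix.
#' @export
#' @examples
#' S <- attractor_covariance(0.018, data.frame(i = "d_6", j = "d_7",
#'                                             rho = 0.6))
attractor_covariance <- function(sd = 0.018, cor = NULL) {
  if (length(sd) == 1L) sd <- rep(sd, 11L)
  stopifnot(length(sd) == 11L, all(sd > 0))
  R <- diag(11L)
  if (!is.null(cor)) {
    if (is.matrix(cor)) {
      R <- cor
    } else {
      ix <- function(v) if (is.numeric(v)) v + 1L else match(v, FACE_COORDS)
      for (k in seq_len(nrow(cor))) {
        i <- ix(cor$i[k]); j <- ix(cor$j[k])
        R[i, j] <- R[j, i] <- cor$rho[k]
      }
    }
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-9)
    stop("planted correlation matrix is not positive semidefinite")
  S <- diag(sd) %*% R %*% diag(sd)
  dimnames(S) <- list(FACE_COORDS, FACE_COORDS)
  S
}

#' Configuration of a synthetic subject cohort
#'
#' Describes a cohort of simulated subjects: latent attractors drawn from a
#' multivariate Gaussian around a population-mean facial vector (projected
#' onto the constraint surface), optional group structure with an offset
#' applied to one group's attractor mean, and the logistic choice noise of
#' each simulated chooser.
#'
#' Defaults mirror the reference study conditions: 95 subjects with
#' gender-like group weights 54:39, per-coordinate attractor spread 0.018
#' facial lengths, and inverse choice temperature `beta = 6`.
#'
#' For parameter-recovery studies (does the analysis layer detect planted
#' structure?), `attractor_dist = "uniform"` draws each subject's attractor
#' coordinate-wise uniformly within the schema bounds -- attractors that are
#' distinct on the scale of the face space the engine explores -- instead of
#' the narrow Gaussian cohort.
#'
#' @param S number of subjects.
#' @param groups named numeric vector of group weights (proportions).
#' @param attractor_mean population-mean facial vector (projected onto the
#'   constraint before use).
#' @param attractor_cov 11 x 11 attractor covariance (see
#'   [attractor_covariance()]).
#' @param attractor_dist `"gaussian"` (default; cohort-emulating) or
#'   `"uniform"` (recovery studies; ignores `attractor_mean`/`attractor_cov`).
#' @param group_offset length-11 vector added to the attractor mean of the
#'   *second* group (zero by default).
#' @param beta inverse choice temperature of the simulated subjects.
#' @param metric metric name used by the simulated choosers.
#' @param m replicates (independent sculpting runs) per subject.
#' @param schema a `face_schema`.
#' @param seed optional integer seed.
#' @return An object of class `synth_cohort_config`.
#' @export
synth_cohort_config <- function(S = 95L,
                                groups = c(female = 54, male = 39),
                                attractor_mean = NULL,
                                attractor_cov = attractor_covariance(),
                                attractor_dist = c("gaussian", "uniform"),
                                group_offset = rep(0, 11L),
                                beta = 6, metric = "euclidean",
                                m = 1L, schema = default_schema(),
                                seed = NULL) {
  attractor_dist <- match.arg(attractor_dist)
  if (S < 1L) stop("'S' must be at least 1")
  if (is.null(attractor_mean)) attractor_mean <- schema$reference
  attractor_mean <- project_to_constraint(attractor_mean, schema)
  if (length(group_offset) != 11L) stop("'group_offset' must have length 11")
  groups <- groups / sum(groups)
  structure(list(S = as.integer(S), groups = groups,
                 attractor_mean = attractor_mean,
                 attractor_cov = attractor_cov,
                 attractor_dist = attractor_dist,
                 group_offset = group_offset,
                 beta = beta, metric = metric, m = as.integer(m),
                 schema = schema, seed = seed),
            class = "synth_cohort_config")
}

#' Sample a cohort of simulated subjects
#'
#' Draws each subject's latent attractor from the configured multivariate
#' Gaussian, applies the group offset to members of the second group,
#' projects onto the constraint surface and builds the logistic choosers.
#'
#' @param cfg a [synth_cohort_config()].
#' @return An object of class `synth_cohort` with `subjects` (a
#'   `data.frame` of ids and groups), `attractors` (matrix, one row per
#'   subject), `choosers` (list of [simulated_subject()] objects) and the
#'   config.
#' @export
sample_cohort <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  S <- cfg$S
  grp_names <- names(cfg$groups)
  n_per <- floor(S * cfg$groups)
  rem <- S - sum(n_per)
  if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1L
  group <- rep(grp_names, times = n_per)
  if (identical(cfg$attractor_dist, "uniform")) {
    lo <- cfg$schema$bounds$lo; hi <- cfg$schema$bounds$hi
    A <- t(replicate(S, runif(11L, lo, hi)))
  } else {
    A <- MASS::mvrnorm(S, mu = cfg$attractor_mean, Sigma = cfg$attractor_cov)
    if (S == 1L) A <- matrix(A, nrow = 1L)
  }
  if (length(grp_names) >= 2L) {
    in2 <- group == grp_names[2L]
    A[in2, ] <- sweep(A[in2, , drop = FALSE], 2L, cfg$group_offset, "+")
  }
  A <- t(apply(A, 1L, project_to_constraint, schema = cfg$schema))
  colnames(A) <- FACE_COORDS
  ctx <- metric_context(cfg$metric)
  choosers <- lapply(seq_len(S), function(s)
    simulated_subject(A[s, ], beta = cfg$beta, ctx = ctx,
                      group = group[s]))
  structure(list(subjects = data.frame(subject_id = sprintf("s%03d", seq_len(S)),
                                       group = group,
                                       stringsAsFactors = FALSE),
                 attractors = A, choosers = choosers, cfg = cfg),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$subjects), "simulated subjects (",
      paste(sprintf("%s: %d", names(table(x$subjects$group)),
                    as.integer(table(x$subjects$group))), collapse = ", "),
      "), beta =", x$cfg$beta, "\n")
  invisible(x)
}

#' Run a full synthetic sculpting study
#'
#' Executes one complete sculpting experiment per subject, replicate and
#' experiment tag, and collects the final sculpted populations in the
#' tabular record format.  A tag can carry a coordinate shift added to the
#' subjects' attractors for that tag, emulating a change of reference
#' portrait that displaces the preferred values of some coordinates while
#' leaving robust coordinates (those with zero shift) untouched.
#'
#' @param cohort a `synth_cohort`.
#' @param config an `engine_config` (its `seed` is ignored; seed the study
#'   through `seed`).
#' @param m replicates per subject (default: from the cohort config).
#' @param tags named list mapping experiment tags to length-11 shift
#'   vectors or `NULL` for no shift, e.g.
#'   `list(E1 = NULL, E3 = shift_vector)`.
#' @param seed optional integer seed for the whole study.
#' @param keep `"final"` (default) stores only the generation-`T`
#'   populations; `"all"` stores every generation.
#' @return An object of class `study_dataset` with `records`,
#'   `subjects`, `attractors` (ground truth per subject and tag) and the
#'   configurations.
#' @export
#' @examples
#' \donttest{
#' coh <- sample_cohort(synth_cohort_config(S = 4, seed = 1))
#' st <- run_synthetic_study(coh, engine_config(N = 8, T = 2), seed = 2)
#' }
run_synthetic_study <- function(cohort, config = engine_config(),
                                m = NULL, tags = list(E1 = NULL),
                                seed = NULL, keep = c("final", "all")) {
  keep <- match.arg(keep)
  if (is.null(m)) m <- cohort$cfg$m
  if (!is.null(seed)) set.seed(seed)
  config$seed <- NULL
  sc <- config$schema
  out <- list(); truth <- list()
  for (tag in names(tags)) {
    shift <- tags[[tag]]
    for (s in seq_len(nrow(cohort$subjects))) {
      base <- cohort$choosers[[s]]
      att <- cohort$attractors[s, ]
      if (!is.null(shift)) att <- project_to_constraint(att + shift, sc)
      chooser <- simulated_subject(att, beta = base$beta, ctx = base$ctx,
                                   group = base$group)
      truth[[length(truth) + 1L]] <- data.frame(
        experiment_id = tag, subject_id = cohort$subjects$subject_id[s],
        group = cohort$subjects$group[s], t(att),
        stringsAsFactors = FALSE)
      for (r in seq_len(m)) {
        rec <- run_experiment(config, chooser)
        gens <- if (keep == "all") seq_along(rec$populations) else
          length(rec$populations)
        for (g in gens) {
          out[[length(out) + 1L]] <- population_records(
            rec$populations[[g]], experiment_id = tag,
            subject_id = cohort$subjects$subject_id[s],
            replicate = r, generation = g - 1L)
        }
      }
    }
  }
  truth <- do.call(rbind, truth)
  names(truth)[4:14] <- FACE_COORDS
  structure(list(records = do.call(rbind, out),
                 subjects = cohort$subjects,
                 attractors = truth,
                 engine_config = config, cohort_config = cohort$cfg,
                 tags = tags, m = m),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("Synthetic sculpting study:", nrow(x$subjects), "subjects x",
      x$m, "replicates x", length(x$tags), "experiment tag(s);",
      nrow(x$records), "facial-vector records\n")
  invisible(x)
}

#' Deterministic synthetic portrait fixture
#'
#' Generates a cartoon-style grayscale portrait (smooth-shaded elliptical
#' head, eyes, nose, mouth and jaw shading over a gently textured
#' background) whose features are drawn at the pixel positions implied by
#' the schema's reference facial vector, together with those landmark
#' positions.  The image is smooth so that warps are both visually and
#' numerically detectable, and fully deterministic.  Optionally, dark
#' fiducial dots are burned in at the landmark positions for warp
#' round-trip verification.  It replaces a real reference portrait in all
#' tests and examples.
#'
#' @param width,height image dimensions in pixels (at least 64).
#' @param schema a `face_schema`.
#' @param fiducials burn fiducial dots at the landmarks.
#' @return A list with `image` (matrix in `[0, 1]`) and `landmarks`
#'   (pixel-frame landmark set).
#' @export
#' @examples
#' fx <- make_fixture_image(120, 160)
#' dim(fx$image)
make_fixture_image <- function(width = 300L, height = 400L,
                               schema = default_schema(),
                               fiducials = FALSE) {
  if (width < 64L || height < 64L) stop("fixture must be at least 64 x 64")
  L_px <- 0.75 * height
  origin <- c(width / 2, 0.10 * height)
  Lface <- distances_to_landmarks(schema$reference, schema)
  lm <- face_to_pixel(Lface, L_px, origin)
  px <- stats::setNames(lm$x, lm$id); py <- stats::setNames(lm$y, lm$id)

  X <- matrix(rep(seq_len(width), each = height), height, width)
  Y <- matrix(rep(seq_len(height), times = width), height, width)
  # textured background
  img <- 0.86 + 0.025 * sin(2 * pi * X / 23) * cos(2 * pi * Y / 29) +
    0.02 * sin(2 * pi * (X + Y) / 53)

  soft <- function(e, w) stats::plogis((1 - e) / w)  # smooth inside mask
  blob <- function(cx, cy, sx, sy) exp(-((X - cx)^2 / (2 * sx^2) +
                                           (Y - cy)^2 / (2 * sy^2)))
  # head: ellipse spanning the zygomatic width and full face height
  hx <- px[["face_top"]]
  hy <- (py[["face_top"]] + py[["chin"]]) / 2
  ha <- 1.12 * (px[["zygomatic_r"]] - px[["face_top"]])
  hb <- 0.56 * L_px * 1.08
  e_head <- ((X - hx) / ha)^2 + ((Y - hy) / hb)^2
  head_mask <- soft(e_head, 0.06)
  skin <- 0.72 - 0.10 * e_head  # center brighter, rim darker
  img <- img * (1 - head_mask) + skin * head_mask

  # eyes: dark horizontal ellipses spanning the eye width
  for (side in c("l", "r")) {
    ec <- c(px[[paste0("eye_center_", side)]], py[[paste0("eye_center_", side)]])
    ew <- abs(px[[paste0("eye_outer_", side)]] - px[[paste0("eye_inner_", side)]])
    img <- img - 0.45 * blob(ec[1], ec[2], ew / 2.2, ew / 4.5)
  }
  # nose: vertical ridge from below the eye line to the nose base + wings
  nb <- c(px[["nose_base"]], py[["nose_base"]])
  ny0 <- py[["eye_center_r"]] + 0.25 * (nb[2] - py[["eye_center_r"]])
  ridge <- exp(-((X - nb[1])^2) / (2 * (0.012 * L_px)^2)) *
    stats::plogis((Y - ny0) / 2) * stats::plogis((nb[2] - Y) / 2)
  img <- img - 0.18 * ridge
  for (side in c("l", "r")) {
    nw <- c(px[[paste0("nose_wing_", side)]], py[[paste0("nose_wing_", side)]])
    img <- img - 0.22 * blob(nw[1], nw[2], 0.015 * L_px, 0.012 * L_px)
  }
  # mouth: dark horizontal band between the corners
  mc <- c(px[["mouth_center"]], py[["mouth_center"]])
  mw <- abs(px[["mouth_corner_r"]] - px[["mouth_corner_l"]])
  img <- img - 0.40 * blob(mc[1], mc[2], mw / 2.4, 0.015 * L_px)
  # jaw shading
  for (side in c("l", "r")) {
    jw <- c(px[[paste0("jaw_", side)]], py[[paste0("jaw_", side)]])
    img <- img - 0.10 * blob(jw[1], jw[2], 0.03 * L_px, 0.05 * L_px)
  }
  # zygomatic highlight
  for (side in c("l", "r")) {
    zg <- c(px[[paste0("zygomatic_", side)]], py[[paste0("zygomatic_", side)]])
    img <- img + 0.06 * blob(zg[1], zg[2], 0.04 * L_px, 0.04 * L_px)
  }
  if (fiducials) {
    for (k in seq_len(nrow(lm))) {
      img <- img * (1 - 0.98 * blob(lm$x[k], lm$y[k], 1.0, 1.0))
    }
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, landmarks = lm)
}
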