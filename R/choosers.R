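#' Present two options to a chooser
#'
#' Choosers are side-blind: they receive the two options in the (possibly
#' randomized) presentation order and return `1` for the left option, `2`
#' for the right option, or `0` for a declared indifference (resolved by the
#' engine in favor of the incumbent parent).
#'
#' @param chooser a chooser object.
#' @param left,right facial vectors as presented.
#' @param renderer optional rendering function for image-based choosers.
#' @return Integer verdict: 1, 2 or 0.
#' @export
choose_between <- function(chooser, left, right, renderer = NULL) {
  UseMethod("choose_between")
}

chooser_info <- function(chooser) UseMethod("chooser_info")

#' Uniformly random chooser (the null model)
#'
#' Picks left or right with probability 1/2 regardless of the stimuli: the
#' null model against which sculpting convergence is benchmarked.
#'
#' @return A chooser object.
#' @export
random_chooser <- function() {
  structure(list(), class = c("random_chooser", "face_chooser"))
}

#' @export
choose_between.random_chooser <- function(chooser, left, right,
                                          renderer = NULL) {
  if (runif(1L) < 0.5) 1L else 2L
}

#' @export
chooser_info.random_chooser <- function(chooser) {
  list(type = "random", beta = 0)
}

#' Simulated subject with a latent face-space attractor
#'
#' A behavioral stand-in for a human chooser: the subject holds a latent
#' attractor `f*` in face-space and prefers the option closer to it, with
#' logistic choice noise.  The probability of picking the left option is
#' `plogis(beta * D * (dist(right, f*) - dist(left, f*)))`, where `dist` is
#' the per-coordinate face-space distance of the configured metric and
#' `D = 11` converts it to an aggregate (summed-coordinate) utility scale,
#' so `beta` is an inverse temperature per coordinate.  `beta = 0` reduces
#' to the uniformly random null model; `beta = Inf` is the deterministic
#' nearest-to-attractor chooser (declaring indifference at exact ties, which
#' the engine resolves by retaining the parent).
#'
#' @param attractor the latent preferred facial vector `f*`.
#' @param beta non-negative inverse choice temperature.
#' @param ctx a [metric_context()] defining the face-space distance
#'   (default: Euclidean).
#' @param group optional group tag (e.g. a gender-like label) carried into
#'   study datasets.
#' @return A chooser object of class `simulated_subject`.
#' @export
#' @examples
#' subj <- simulated_subject(default_schema()$reference, beta = 6)
simulated_subject <- function(attractor, beta = 6,
                              ctx = metric_context("euclidean"),
                              group = NA_character_) {
  if (beta < 0) stop("'beta' must be non-negative")
  structure(list(attractor = attractor, beta = beta, ctx = ctx,
                 group = group),
            class = c("simulated_subject", "face_chooser"))
}

#' @export
choose_between.simulated_subject <- function(chooser, left, right,
                                             renderer = NULL) {
  dl <- face_distance(left, chooser$attractor, chooser$ctx)
  dr <- face_distance(right, chooser$attractor, chooser$ctx)
  if (is.infinite(chooser$beta)) {
    if (dl < dr) return(1L)
    if (dr < dl) return(2L)
    return(0L)
  }
  p_left <- stats::plogis(chooser$beta * 11 * (dr - dl))
  if (runif(1L) < p_left) 1L else 2L
}

#' @export
chooser_info.simulated_subject <- function(chooser) {
  list(type = "simulated", beta = chooser$beta,
       metric = chooser$ctx$metric, group = chooser$group)
}

#' Chooser wrapping an arbitrary decision function
#'
#' Builds a chooser from a function `fn(left, right)` returning 1, 2 or 0.
#' Useful for scripted or recording choosers in tests and simulations.
#'
#' @param fn decision function.
#' @param type label reported in experiment metadata.
#' @return A chooser object.
#' @export
function_chooser <- function(fn, type = "scripted") {
  structure(list(fn = fn, type = type),
            class = c("function_chooser", "face_chooser"))
}

#' @export
choose_between.function_chooser <- function(chooser, left, right,
                                            renderer = NULL) {
  as.integer(chooser$fn(left, right))
}

#' @export
chooser_info.function_chooser <- function(chooser) {
  list(type = chooser$type, beta = NA_real_)
}

#' Interactive command-line chooser
#'
#' Writes each stimulus pair side by side to a PNG file and reads `l` or `r`
#' from a connection (standard input by default).  Requires a renderer; used
#' by the command-line `sculpt` entry point for human-in-the-loop runs.
#'
#' @param pair_path path of the PNG file to (re)write for each choice.
#' @param input connection to read choices from.
#' @return A chooser object.
#' @export
interactive_chooser <- function(pair_path = "pair.png", input = stdin()) {
  structure(list(pair_path = pair_path, input = input),
            class = c("interactive_chooser", "face_chooser"))
}

#' @export
choose_between.interactive_chooser <- function(chooser, left, right,
                                               renderer = NULL) {
  if (is.null(renderer))
    stop("the interactive chooser requires a renderer")
  li <- renderer(left); ri <- renderer(right)
  h <- max(nrow(li), nrow(ri))
  pad <- function(m) rbind(m, matrix(1, h - nrow(m), ncol(m)))
  sep <- matrix(0, h, 4L)
  write_face_image(cbind(pad(li), sep, pad(ri)), chooser$pair_path)
  repeat {
    cat("Choice written to ", chooser$pair_path,
        " -- prefer [l]eft or [r]ight? ", sep = "")
    ans <- tolower(trimws(readLines(chooser$input, n = 1L)))
    if (length(ans) == 0L) stop("interactive chooser: input closed")
    if (ans %in% c("l", "left")) return(1L)
    if (ans %in% c("r", "right")) return(2L)
    cat("Please answer 'l' or 'r'.\n")
  }
}

#' @export
chooser_info.interactive_chooser <- function(chooser) {
  list(type = "interactive", beta = NA_real_)
}
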