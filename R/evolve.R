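#' Configuration of the sculpting engine
#'
#' Parameters of the binary-choice differential-evolution engine.  The
#' defaults are the experimental settings used throughout: population size
#' `N = 28`, `T = 10` generations, differential weight `mu = 0.15` and
#' per-coordinate crossover probability `rho = 1`, for a total of
#' `N * T = 280` binary choices per run.
#'
#' @param N population size (at least 4: differential evolution needs three
#'   distinct partners besides the target member).
#' @param T number of generations (at least 1).
#' @param mu differential weight applied to the difference vector.
#' @param rho per-coordinate crossover probability in `[0, 1]`.
#' @param schema a `face_schema` supplying coordinate bounds and the
#'   normalization constraint.
#' @param seed optional integer seed fixing the whole run.
#' @param randomize_sides present the parent on a random side at each choice
#'   (default `TRUE`); choosers must be side-blind either way.
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(N = 28L, T = 10L, mu = 0.15, rho = 1,
                          schema = default_schema(), seed = NULL,
                          randomize_sides = TRUE) {
  if (N < 4L) stop("'N' must be at least 4")
  if (T < 1L) stop("'T' must be at least 1")
  if (mu <= 0) stop("'mu' must be positive")
  if (rho < 0 || rho > 1) stop("'rho' must lie in [0, 1]")
  structure(list(N = as.integer(N), T = as.integer(T), mu = mu, rho = rho,
                 schema = schema, seed = seed,
                 randomize_sides = isTRUE(randomize_sides)),
            class = "engine_config")
}

#' @export
print.engine_config <- function(x, ...) {
  cat(sprintf("Sculpting engine: N = %d, T = %d, mu = %.3g, rho = %.3g (%d choices per run)\n",
              x$N, x$T, x$mu, x$rho, x$N * x$T))
  invisible(x)
}

#' Initialize a random population of facial vectors
#'
#' Draws `N` vectors coordinate-wise uniformly within the schema bounds and
#' projects each onto the `h = 1` constraint surface.
#'
#' @param config an `engine_config`.
#' @return Numeric matrix with one valid facial vector per row.
#' @export
init_population <- function(config) {
  sc <- config$schema
  lo <- sc$bounds$lo; hi <- sc$bounds$hi
  P <- matrix(NA_real_, config$N, 11L, dimnames = list(NULL, FACE_COORDS))
  for (n in seq_len(config$N)) {
    raw <- runif(11L, lo, hi)
    P[n, ] <- project_to_constraint(raw, sc)
  }
  P
}

#' Propose a differential-evolution offspring
#'
#' DE/rand/1/bin: three distinct partners `a, b, c` different from the
#' target member `n` are drawn, the mutant is
#' `m = f(a) + mu * (f(b) - f(c))`, binomial crossover with the parent
#' `f(n)` keeps each mutant coordinate with probability `rho` (one randomly
#' chosen coordinate is always taken from the mutant), and the result is
#' projected back onto the constraint surface.
#'
#' @param pop population matrix (one facial vector per row).
#' @param n index of the target member.
#' @param config an `engine_config`.
#' @return A valid facial vector (the offspring).
#' @export
propose_offspring <- function(pop, n, config) {
  N <- nrow(pop)
  if (N < 4L) stop("differential evolution requires a population of at least 4")
  partners <- sample(seq_len(N)[-n], 3L)
  mutant <- pop[partners[1L], ] +
    config$mu * (pop[partners[2L], ] - pop[partners[3L], ])
  keep <- runif(11L) < config$rho
  keep[sample.int(11L, 1L)] <- TRUE
  child <- pop[n, ]
  child[keep] <- mutant[keep]
  project_to_constraint(child, config$schema)
}

#' Run one generation of the sculpting loop
#'
#' For every member of the population an offspring is proposed, the
#' parent/offspring pair is presented to the chooser in randomized side
#' order, and the chooser's pick becomes the member of the next generation.
#' Exactly `N` choices are logged.  An indifferent chooser verdict (see
#' [choose_between()]) conservatively retains the parent.
#'
#' @param pop population matrix.
#' @param chooser a chooser object (see [simulated_subject()],
#'   [random_chooser()]).
#' @param config an `engine_config`.
#' @param generation generation index recorded in the log.
#' @param renderer optional function `(face_vector) -> image` supplying
#'   rendered stimuli to choosers that inspect images; simulated choosers
#'   act on the vectors alone, so large simulation studies skip rendering.
#' @return List with elements `pop` (next generation) and `log` (a
#'   `data.frame` slice of the choice log).
#' @export
run_generation <- function(pop, chooser, config, generation = 0L,
                           renderer = NULL) {
  N <- nrow(pop)
  nxt <- pop
  log <- data.frame(generation = integer(N), member = integer(N),
                    parent_side = character(N), chosen_side = character(N),
                    chose_offspring = logical(N), stringsAsFactors = FALSE)
  for (n in seq_len(N)) {
    off <- propose_offspring(pop, n, config)
    parent_left <- if (config$randomize_sides) runif(1L) < 0.5 else TRUE
    left <- if (parent_left) pop[n, ] else off
    right <- if (parent_left) off else pop[n, ]
    pick <- choose_between(chooser, left, right, renderer = renderer)
    if (!pick %in% c(0L, 1L, 2L))
      stop("chooser returned an invalid verdict; expected 1 (left), 2 (right) or 0 (indifferent)")
    chose_off <- (pick == 1L && !parent_left) || (pick == 2L && parent_left)
    if (chose_off) nxt[n, ] <- off
    log$generation[n] <- generation
    log$member[n] <- n
    log$parent_side[n] <- if (parent_left) "left" else "right"
    log$chosen_side[n] <- c("none", "left", "right")[pick + 1L]
    log$chose_offspring[n] <- chose_off
  }
  list(pop = nxt, log = log)
}

#' Run a full sculpting experiment
#'
#' Initializes a random population and evolves it for `T` generations under
#' the chooser's selection, logging every binary choice.  A complete run
#' issues exactly `N * T` choices.
#'
#' @inheritParams run_generation
#' @param config an `engine_config`; if `config$seed` is set the run is
#'   fully reproducible.
#' @param init optional initial population matrix (default: random).
#' @return An object of class `sculpt_experiment` with elements
#'   `populations` (list of `T + 1` matrices, generations `0 ... T`),
#'   `choices` (the full choice log), `config` and `chooser_info`.
#' @export
#' @examples
#' rec <- run_experiment(engine_config(N = 8, T = 2, seed = 1),
#'                       random_chooser())
#' nrow(rec$choices)  # 16
run_experiment <- function(config, chooser, renderer = NULL, init = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  pop <- if (is.null(init)) init_population(config) else init
  pops <- vector("list", config$T + 1L)
  pops[[1L]] <- pop
  logs <- vector("list", config$T)
  for (t in seq_len(config$T)) {
    step <- run_generation(pop, chooser, config, generation = t - 1L,
                           renderer = renderer)
    pop <- step$pop
    pops[[t + 1L]] <- pop
    logs[[t]] <- step$log
  }
  structure(list(populations = pops,
                 choices = do.call(rbind, logs),
                 config = config,
                 chooser_info = chooser_info(chooser)),
            class = "sculpt_experiment")
}

#' @export
print.sculpt_experiment <- function(x, ...) {
  cat(sprintf("Sculpting experiment: %d generations of %d vectors, %d choices (%s)\n",
              x$config$T, x$config$N, nrow(x$choices),
              x$chooser_info$type))
  invisible(x)
}

#' Final sculpted population of an experiment
#'
#' @param record a `sculpt_experiment`.
#' @return The generation-`T` population matrix.
#' @export
final_population <- function(record) {
  record$populations[[length(record$populations)]]
}
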