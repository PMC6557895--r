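# shared test utilities: small random valid populations and brute-force
# oracles kept independent of the package's vectorized implementations

random_face_vector <- function(schema = default_schema()) {
  project_to_constraint(runif(11, schema$bounds$lo, schema$bounds$hi), schema)
}

random_population <- function(n, schema = default_schema()) {
  t(replicate(n, random_face_vector(schema)))
}

# brute-force double loops (the oracle for the population statistics)
oracle_intra <- function(P, ctx) {
  n <- nrow(P); acc <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    acc <- c(acc, face_distance(P[i, ], P[j, ], ctx))
  mean(acc)
}

oracle_pseudo <- function(P, Q, ctx) {
  acc <- c()
  for (i in seq_len(nrow(P))) for (j in seq_len(nrow(Q)))
    acc <- c(acc, face_distance(P[i, ], Q[j, ], ctx))
  mean(acc)
}

# plain-Euclidean scalar oracle, independent of face_distance
oracle_euclid <- function(u, v) sqrt(sum((u - v)^2)) / sqrt(length(u))

# build study-style records with given per-population matrices
pops_to_records <- function(pops, subj, repl, tag = "E1") {
  do.call(rbind, lapply(seq_along(pops), function(k)
    population_records(pops[[k]], experiment_id = tag,
                       subject_id = subj[k], replicate = repl[k],
                       generation = 10L)))
}
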