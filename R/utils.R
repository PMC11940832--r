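# Run code with a local, seeded RNG stream without disturbing the caller's
# global RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Pairwise Euclidean distances from each point to each center row.
dist_to_centers <- function(x, y, cx, cy) {
  outer(x, cx, "-")^2 + outer(y, cy, "-")^2
}
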