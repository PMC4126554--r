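#' Random-walk seeding configuration
#'
#' Parameters of the random-walk initialization of the medium used by the
#' habit-emergence experiment: a number of independent walks through the
#' normalized sensorimotor volume, each contributing one node per visited
#' locus.  The defaults (100 walks of 50 steps, uniform step components in
#' `[-step_range, step_range]`) yield 5000 nodes.
#'
#' @param n_walks Number of walks.
#' @param steps_per_walk Loci (hence nodes) per walk.
#' @param step_range Half-width of the uniform step distribution.
#' @param seed Optional RNG seed; `NULL` uses the current RNG stream.
#' @return An object of class `random_walk_config`.
#' @export
random_walk_config <- function(n_walks = 100, steps_per_walk = 50,
                               step_range = 0.05, seed = NULL) {
  stopifnot(n_walks >= 1, steps_per_walk >= 1, step_range >= 0)
  structure(list(n_walks = n_walks, steps_per_walk = steps_per_walk,
                 step_range = step_range, seed = seed),
            class = "random_walk_config")
}

#' Generate nodes by random walks through sensorimotor space
#'
#' Each walk starts at a uniform-random point of `[0, 1]^dim` and iterates
#' `l[i+1] = l[i] + r`, with the components of `r` uniform in
#' `[-step_range, step_range]`; any step component that would leave the
#' unit volume is inverted (negated, i.e. reflected at the boundary).  A
#' node is emitted at every locus with position `l[i]`, velocity
#' `l[i+1] - l[i]` and weight 0; the final locus of a walk uses the next
#' proposed (unemitted) step so every node has a defined velocity.
#'
#' @param config A [random_walk_config()].
#' @param dim Dimensionality of the sensorimotor space.
#' @return A list with matrices `p` and `v` (one row per node,
#'   `n_walks * steps_per_walk` rows in total).
#' @export
random_walk_nodes <- function(config = random_walk_config(), dim = 4) {
  stopifnot(inherits(config, "random_walk_config"), dim >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  total <- config$n_walks * config$steps_per_walk
  P <- matrix(NA_real_, total, dim)
  V <- matrix(NA_real_, total, dim)
  sr <- config$step_range
  row <- 0L
  for (walk in seq_len(config$n_walks)) {
    l <- stats::runif(dim)
    for (i in seq_len(config$steps_per_walk)) {
      r <- stats::runif(dim, -sr, sr)
      nxt <- l + r
      out <- nxt < 0 | nxt > 1
      r[out] <- -r[out]
      nxt <- l + r
      row <- row + 1L
      P[row, ] <- l
      V[row, ] <- nxt - l
      l <- nxt
    }
  }
  list(p = P, v = V)
}

#' Seed a medium with random-walk nodes
#'
#' Adds the nodes of [random_walk_nodes()] to the medium with weight 0 and
#' a creation time one activation delay in the past, so the seeded nodes
#' shape behavior from the very first step of a trial.
#'
#' @param idsm An [idsm_new()] medium (modified in place).
#' @param config A [random_walk_config()].
#' @return The medium, invisibly.
#' @export
seed_idsm <- function(idsm, config = random_walk_config()) {
  nodes <- random_walk_nodes(config, dim = idsm$dim)
  add_nodes(idsm, nodes$p, nodes$v, w = 0,
            t_created = idsm$t - idsm$params$activation_delay)
  invisible(idsm)
}
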