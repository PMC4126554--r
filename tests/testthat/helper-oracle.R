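# Independent straight-loop oracle for the motor field, written directly from
# the per-node formulas (no shared code with the package internals).
oracle_motor_field <- function(med, x) {
  prm <- med$params
  mu <- med$motor_idx
  num <- numeric(length(mu))
  phi <- 0
  for (i in seq_len(med$n)) {
    if ((med$t - med$t_created[i]) < prm$activation_delay) next
    p <- med$P[, i]
    v <- med$V[, i]
    d <- 2 / (1 + exp(prm$k_d * sum((p - x)^2)))
    om <- 2 / (1 + exp(-prm$k_omega * med$w[i]))
    a <- p - x
    g <- if (sqrt(sum(v^2)) <= 1e-12) a else a - (sum(a * v) / sum(v^2)) * v
    num <- num + om * d * (v + g)[mu]
    phi <- phi + om * d
  }
  if (phi < prm$phi_floor || phi == 0) numeric(length(mu)) else num / phi
}

# Small random medium: n nodes in dim dimensions, a mix of activated and
# not-yet-activated nodes, weights spread over a wide range.
random_medium <- function(n, dim, t_now = 50, motor_idx = seq_len(dim)) {
  med <- idsm_new(dim, motor_idx = motor_idx)
  if (n > 0) {
    add_nodes(med,
              p = matrix(runif(n * dim), n, dim),
              v = matrix(runif(n * dim, -0.2, 0.2), n, dim),
              w = rnorm(n, 0, 200),
              t_created = runif(n, 0, t_now))
  }
  med$t <- t_now
  med
}
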