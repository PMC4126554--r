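#' Parameters of an iterant deformable sensorimotor medium
#'
#' Bundles the constants that shape the medium's kernels and dynamics.
#' Defaults are the published values of the node-based medium: a steep
#' distance kernel (`k_d = 1000`) so that only nodes very close to the
#' current sensorimotor state have appreciable influence, and a very flat
#' weight kernel (`k_omega = 0.0025`) so that weights must change by
#' hundreds of units before a node's influence saturates.
#'
#' @param k_d Steepness of the distance kernel (per squared normalized
#'   distance).  Larger values make node influence more local.
#' @param k_omega Steepness of the sigmoidal weight kernel (per weight unit).
#' @param k_t Node-creation density threshold: a new node is added only when
#'   the local node density falls below this value.
#' @param activation_delay Time-units after creation before a node starts to
#'   influence the motor state.
#' @param decay_rate Steady weight loss per time-unit (the dissipative term
#'   of the weight dynamics).
#' @param reinforcement_gain Gain on the proximity kernel in the weight
#'   reinforcement term.
#' @param dt Integration step, in time-units, used by the fixed-step Euler
#'   scheme throughout the package.
#' @param phi_floor Non-negative guard for the motor-field normalization:
#'   if the activated-node density at the query point falls below this
#'   value the field is the zero vector (motors hold).  The default is just
#'   above double-precision underflow, so the guard only fires when every
#'   kernel value is numerically zero; the field itself is a kernel-weighted
#'   average and is well defined at any positive density.
#' @return An object of class `idsm_params` (a named list).
#' @export
idsm_params <- function(k_d = 1000, k_omega = 0.0025, k_t = 1,
                        activation_delay = 10, decay_rate = 1,
                        reinforcement_gain = 10, dt = 0.01,
                        phi_floor = 1e-300) {
  stopifnot(k_d > 0, k_omega > 0, k_t > 0, activation_delay > 0,
            decay_rate > 0, reinforcement_gain > 0, dt > 0, phi_floor >= 0)
  structure(list(k_d = k_d, k_omega = k_omega, k_t = k_t,
                 activation_delay = activation_delay,
                 decay_rate = decay_rate,
                 reinforcement_gain = reinforcement_gain,
                 dt = dt, phi_floor = phi_floor),
            class = "idsm_params")
}

#' Create an empty sensorimotor medium
#'
#' The medium is a growing collection of nodes, each a record
#' `<position, velocity, weight, creation time>` of the sensorimotor flow at
#' a past moment.  All positions and velocities live in normalized
#' sensorimotor space, where every sensor and motor dimension is linearly
#' rescaled to \[0, 1\].
#'
#' The returned object has reference semantics (it is an environment):
#' [update_weights()], [maybe_create_node()] and [step_idsm()] modify it in
#' place and return it invisibly.  Use [idsm_clone()] for an independent
#' copy, e.g. before a frozen flow-field probe.
#'
#' @param dim Dimensionality of the sensorimotor space.
#' @param motor_idx Integer indices of the motor dimensions within the
#'   sensorimotor vector.
#' @param params An [idsm_params()] object.
#' @param capacity Initial node storage capacity (grows automatically).
#' @return An object of class `idsm`.
#' @export
idsm_new <- function(dim, motor_idx = seq_len(dim), params = idsm_params(),
                     capacity = 256L) {
  stopifnot(dim >= 1, all(motor_idx %in% seq_len(dim)),
            inherits(params, "idsm_params"))
  e <- new.env(parent = emptyenv())
  e$dim <- as.integer(dim)
  e$motor_idx <- as.integer(motor_idx)
  e$params <- params
  e$t <- 0
  e$n <- 0L
  e$cap <- as.integer(max(capacity, 1L))
  e$P <- matrix(NA_real_, dim, e$cap)      # one column per node
  e$V <- matrix(NA_real_, dim, e$cap)
  e$w <- numeric(e$cap)
  e$t_created <- numeric(e$cap)
  e$vnorm2 <- numeric(e$cap)               # cached squared norms of V
  class(e) <- "idsm"
  e
}

#' @export
print.idsm <- function(x, ...) {
  cat(sprintf("<idsm> %d-dimensional (%d motor), %d nodes, t = %g\n",
              x$dim, length(x$motor_idx), x$n, x$t))
  invisible(x)
}

#' Deep copy of a medium
#'
#' @param idsm An `idsm` object.
#' @return An independent copy; mutating one does not affect the other.
#' @export
idsm_clone <- function(idsm) {
  e <- new.env(parent = emptyenv())
  for (nm in ls(idsm, all.names = TRUE)) assign(nm, get(nm, envir = idsm), envir = e)
  class(e) <- "idsm"
  e
}

.grow_capacity <- function(idsm, need) {
  while (idsm$cap < need) {
    newcap <- idsm$cap * 2L
    P <- matrix(NA_real_, idsm$dim, newcap); P[, seq_len(idsm$n)] <- idsm$P[, seq_len(idsm$n)]
    V <- matrix(NA_real_, idsm$dim, newcap); V[, seq_len(idsm$n)] <- idsm$V[, seq_len(idsm$n)]
    idsm$P <- P; idsm$V <- V
    idsm$w <- c(idsm$w[seq_len(idsm$n)], numeric(newcap - idsm$n))
    idsm$t_created <- c(idsm$t_created[seq_len(idsm$n)], numeric(newcap - idsm$n))
    idsm$vnorm2 <- c(idsm$vnorm2[seq_len(idsm$n)], numeric(newcap - idsm$n))
    idsm$cap <- newcap
  }
  invisible(idsm)
}

#' Add nodes to a medium
#'
#' Low-level append used by node creation, seeding and snapshot loading.
#'
#' @param idsm An `idsm` object (modified in place).
#' @param p Node position(s): a vector of length `dim` or a matrix with one
#'   row per node.
#' @param v Node velocity(ies), same shape as `p`.
#' @param w Node weight(s); recycled.  Newly created nodes have weight 0
#'   ("neutral": neither stronger nor weaker than at creation).
#' @param t_created Creation time(s); recycled.  Defaults to the medium's
#'   current clock.
#' @return The medium, invisibly.
#' @export
add_nodes <- function(idsm, p, v, w = 0, t_created = idsm$t) {
  if (!is.matrix(p)) p <- matrix(p, nrow = 1L)
  if (!is.matrix(v)) v <- matrix(v, nrow = 1L)
  stopifnot(ncol(p) == idsm$dim, ncol(v) == idsm$dim, nrow(p) == nrow(v))
  k <- nrow(p)
  .grow_capacity(idsm, idsm$n + k)
  idx <- idsm$n + seq_len(k)
  idsm$P[, idx] <- t(p)
  idsm$V[, idx] <- t(v)
  idsm$w[idx] <- rep_len(w, k)
  idsm$t_created[idx] <- rep_len(t_created, k)
  idsm$vnorm2[idx] <- rowSums(v^2)
  idsm$n <- idsm$n + k
  invisible(idsm)
}

#' Nodes of a medium as a data frame
#'
#' @param idsm An `idsm` object.
#' @return A data frame with columns `id`, `t_created`, `w`, `p_1..p_D`,
#'   `v_1..v_D`.
#' @export
idsm_nodes <- function(idsm) {
  n <- idsm$n
  idx <- seq_len(n)
  out <- data.frame(id = idx, t_created = idsm$t_created[idx], w = idsm$w[idx])
  P <- t(idsm$P[, idx, drop = FALSE]); colnames(P) <- paste0("p_", seq_len(idsm$dim))
  V <- t(idsm$V[, idx, drop = FALSE]); colnames(V) <- paste0("v_", seq_len(idsm$dim))
  cbind(out, as.data.frame(P), as.data.frame(V))
}

## ---- kernels ---------------------------------------------------------------

#' Weight kernel
#'
#' Sigmoidal scaling of a node's influence by its weight,
#' `omega(w) = 2 / (1 + exp(-k_omega * w))`.  Strictly increasing, bounded
#' in (0, 2), and equal to 1 at the neutral weight 0.
#'
#' @param w Node weight(s).
#' @param k_omega Kernel steepness.
#' @return Values in (0, 2).
#' @export
weight_factor <- function(w, k_omega = 0.0025) {
  2 / (1 + exp(-k_omega * w))
}

#' Distance kernel
#'
#' Proximity of a node position to a sensorimotor state,
#' `d(p, x) = 2 / (1 + exp(k_d * ||p - x||^2))` with the Euclidean norm in
#' normalized sensorimotor space.  Equals 1 at zero distance and decays
#' steeply: at distance 0.1 (with the default `k_d`) it is already ~9e-5.
#'
#' @param p A node position (vector), or a matrix with one column per node.
#' @param x The query sensorimotor state (vector).
#' @param k_d Kernel steepness.
#' @return Values in (0, 1\]; one per node.
#' @export
proximity <- function(p, x, k_d = 1000) {
  if (is.matrix(p)) {
    if (nrow(p) != length(x)) stop("dimension mismatch between nodes and query state")
    d2 <- colSums((p - x)^2)
  } else {
    if (length(p) != length(x)) stop("dimension mismatch between node and query state")
    d2 <- sum((p - x)^2)
  }
  2 / (1 + exp(k_d * d2))
}

.active_index <- function(idsm) {
  n <- idsm$n
  if (n == 0L) return(integer(0))
  which((idsm$t - idsm$t_created[seq_len(n)]) >= idsm$params$activation_delay)
}

#' Local node density
#'
#' Sum of `weight_factor(w) * proximity(p, x)` over nodes: a measure of how
#' many nodes there are near `x` and how heavily weighted they are.  Node
#' creation compares the density over *all* nodes against the threshold
#' `k_t`; the motor-field normalization uses the density over *activated*
#' nodes only.
#'
#' @param idsm An `idsm` object.
#' @param x Query state in normalized sensorimotor space.
#' @param nodes `"all"` (default; creation rule) or `"active"` (field
#'   normalization).
#' @return A non-negative scalar; 0 for an empty medium.
#' @export
node_density <- function(idsm, x, nodes = c("all", "active")) {
  nodes <- match.arg(nodes)
  idx <- if (nodes == "active") .active_index(idsm) else seq_len(idsm$n)
  if (!length(idx)) return(0)
  sum(weight_factor(idsm$w[idx], idsm$params$k_omega) *
        proximity(idsm$P[, idx, drop = FALSE], x, idsm$params$k_d))
}

## ---- dynamics --------------------------------------------------------------

#' Advance node weights by one Euler step
#'
#' Every node's weight changes at rate
#' `-decay_rate + reinforcement_gain * proximity(p, x)`: a steady
#' degradation plus a reinforcement that only acts while the current
#' sensorimotor state is close to the node.  Applies to all nodes,
#' activated or not.
#'
#' @param idsm An `idsm` object (modified in place).
#' @param x Current normalized sensorimotor state.
#' @param dt Step size in time-units (0 leaves weights unchanged).
#' @return The medium, invisibly.
#' @export
update_weights <- function(idsm, x, dt) {
  n <- idsm$n
  if (n > 0L && dt != 0) {
    idx <- seq_len(n)
    d <- proximity(idsm$P[, idx, drop = FALSE], x, idsm$params$k_d)
    idsm$w[idx] <- idsm$w[idx] +
      dt * (-idsm$params$decay_rate + idsm$params$reinforcement_gain * d)
  }
  invisible(idsm)
}

#' Create a node if the local density is below threshold
#'
#' A node is appended at the current state (weight 0, creation time the
#' medium's clock) only when `node_density(idsm, x) < k_t` (strict
#' inequality, all nodes counted).  This caps how densely the medium
#' records any one region of sensorimotor space.
#'
#' @param idsm An `idsm` object (modified in place).
#' @param x Current normalized sensorimotor state.
#' @param v_est Estimated rate of change of the normalized state (backward
#'   finite difference over one integration step).
#' @return The medium, invisibly.
#' @export
maybe_create_node <- function(idsm, x, v_est) {
  if (node_density(idsm, x, "all") < idsm$params$k_t) {
    add_nodes(idsm, p = x, v = v_est, w = 0, t_created = idsm$t)
  }
  invisible(idsm)
}

#' Remove from `a` its component parallel to `v`
#'
#' Vector-projection removal `a - ((a.v)/||v||^2) v`; the result is
#' orthogonal to `v`.  Used so that a node's attraction influence does not
#' interfere with its velocity influence.  If `||v||` is below `tol` the
#' stored velocity is degenerate and `a` is returned unchanged.
#'
#' @param a Vector to deflect.
#' @param v Reference vector.
#' @param tol Degeneracy tolerance on `||v||`.
#' @return A vector orthogonal to `v` (or `a` itself in the degenerate case).
#' @export
perpendicular_component <- function(a, v, tol = 1e-12) {
  vn2 <- sum(v^2)
  if (vn2 <= tol^2) return(a)
  a - (sum(a * v) / vn2) * v
}

#' Motor velocity field of the medium
#'
#' The rate of change the medium imposes on the motor components of the
#' sensorimotor state at `x`: a density-normalized sum, over activated
#' nodes, of each node's velocity factor (its recorded motor velocity) and
#' attraction factor (the offset toward the node, with the component
#' parallel to the node's velocity removed).  Normalization by the
#' activated-node density makes the influence of nodes an average, not
#' cumulative.
#'
#' @param idsm An `idsm` object.
#' @param x Query state in normalized sensorimotor space.
#' @return A vector of length `length(motor_idx)`, in normalized units per
#'   time-unit; zero when there are no activated nodes or the activated
#'   density is below `phi_floor`.
#' @export
motor_field <- function(idsm, x) {
  .field_components(idsm, x)$combined
}

#' Motor field split into velocity and attraction parts
#'
#' Like [motor_field()] but reporting the two influences separately
#' (each normalized by the same activated-node density), as used by the
#' frozen flow-field probes.
#'
#' @inheritParams motor_field
#' @return A list with elements `velocity`, `attraction`, `combined`
#'   (vectors over motor dimensions) and `phi` (the activated-node density).
#' @export
motor_field_components <- function(idsm, x) {
  .field_components(idsm, x)
}

.field_components <- function(idsm, x) {
  mu <- idsm$motor_idx
  zero <- numeric(length(mu))
  out <- list(velocity = zero, attraction = zero, combined = zero, phi = 0)
  act <- .active_index(idsm)
  if (!length(act)) return(out)
  prm <- idsm$params
  P <- idsm$P[, act, drop = FALSE]
  V <- idsm$V[, act, drop = FALSE]
  coef <- weight_factor(idsm$w[act], prm$k_omega) * proximity(P, x, prm$k_d)
  phi <- sum(coef)
  out$phi <- phi
  if (phi < prm$phi_floor || phi == 0) return(out)
  a <- P - x                                  # offsets toward the nodes
  dot <- colSums(a * V)
  sc <- dot / idsm$vnorm2[act]
  sc[idsm$vnorm2[act] <= 1e-24] <- 0          # degenerate stored velocity
  gam <- a - V * rep(sc, each = nrow(V))
  vel <- as.vector(V[mu, , drop = FALSE] %*% coef) / phi
  att <- as.vector(gam[mu, , drop = FALSE] %*% coef) / phi
  out$velocity <- vel
  out$attraction <- att
  out$combined <- vel + att
  out
}

#' One full medium step
#'
#' Performs, in order: evaluate the motor field at `x`; advance all node
#' weights; create a node if the local density permits; advance the
#' medium's clock.  The ordering guarantees a node never reinforces or
#' influences the field at the instant of its own creation.  With
#' `frozen = TRUE` the medium (weights, nodes, clock) is left untouched and
#' only the field is returned.
#'
#' @param idsm An `idsm` object (modified in place unless frozen).
#' @param x Current normalized sensorimotor state.
#' @param v_est Backward finite-difference estimate of the normalized
#'   sensorimotor velocity.
#' @param dt Step size in time-units.
#' @param frozen If `TRUE`, compute the field without mutating the medium.
#' @return A list with elements `idsm` (the medium) and `field` (the motor
#'   velocity vector).
#' @export
step_idsm <- function(idsm, x, v_est, dt = idsm$params$dt, frozen = FALSE) {
  field <- .idsm_step(idsm, x, v_est, dt, drive = TRUE, frozen = frozen)
  list(idsm = idsm, field = field)
}

## Fused inner step used by step_idsm() and the experiment runner: computes
## the distance kernel once for all nodes and reuses it for the field, the
## weight update and the creation check.  Equivalent to the composition
## motor_field -> update_weights -> maybe_create_node -> clock (tested).
.idsm_step <- function(idsm, x, v_est, dt, drive = TRUE, frozen = FALSE) {
  prm <- idsm$params
  mu <- idsm$motor_idx
  field <- numeric(length(mu))
  n <- idsm$n
  if (n > 0L) {
    idx <- seq_len(n)
    P <- idsm$P[, idx, drop = FALSE]
    d <- 2 / (1 + exp(prm$k_d * colSums((P - x)^2)))
    if (drive) {
      act <- which((idsm$t - idsm$t_created[idx]) >= prm$activation_delay)
      if (length(act)) {
        coef <- (2 / (1 + exp(-prm$k_omega * idsm$w[act]))) * d[act]
        phi_act <- sum(coef)
        if (phi_act >= prm$phi_floor && phi_act > 0) {
          Pa <- P[, act, drop = FALSE]
          Va <- idsm$V[, act, drop = FALSE]
          a <- Pa - x
          sc <- colSums(a * Va) / idsm$vnorm2[act]
          sc[idsm$vnorm2[act] <= 1e-24] <- 0
          gam <- a - Va * rep(sc, each = nrow(Va))
          contrib <- (Va + gam)[mu, , drop = FALSE]
          field <- as.vector(contrib %*% coef) / phi_act
        }
      }
    }
    if (!frozen) {
      if (dt != 0) {
        idsm$w[idx] <- idsm$w[idx] +
          dt * (-prm$decay_rate + prm$reinforcement_gain * d)
      }
      phi_all <- sum((2 / (1 + exp(-prm$k_omega * idsm$w[idx]))) * d)
      if (phi_all < prm$k_t) add_nodes(idsm, x, v_est)
      idsm$t <- idsm$t + dt
    }
  } else if (!frozen) {
    add_nodes(idsm, x, v_est)                 # empty medium: density 0 < k_t
    idsm$t <- idsm$t + dt
  }
  field
}
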