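test_that("weight kernel is the published sigmoid", {
  expect_identical(weight_factor(0), 1)
  expect_equal(weight_factor(-1000), 2 / (1 + exp(2.5)), tolerance = 1e-12)
  expect_lt(abs(weight_factor(1e7) - 2), 1e-9)   # upper asymptote
  # monotone increasing and bounded in (0, 2) on random inputs
  w <- sort(runif(200, -2000, 2000))
  fw <- weight_factor(w)
  expect_true(all(diff(fw) > 0))
  expect_true(all(fw > 0 & fw < 2))
})

test_that("distance kernel is local and monotone decreasing", {
  p <- c(0.3, 0.7)
  expect_identical(proximity(p, p), 1)
  x <- c(0.3 + sqrt(0.001), 0.7)
  expect_equal(proximity(p, x), 2 / (1 + exp(1)), tolerance = 1e-12)
  expect_equal(proximity(p, c(0.4, 0.7)), 2 / (1 + exp(10)), tolerance = 1e-12)
  r <- sort(runif(100, 0, 0.5))
  d <- vapply(r, function(ri) proximity(c(0, 0), c(ri, 0)), 0)
  expect_true(all(diff(d) < 0))
  expect_true(all(d > 0 & d <= 1))
  expect_error(proximity(c(0, 0), c(0, 0, 0)), "dimension")
})

test_that("node density sums weighted proximities", {
  med <- idsm_new(2)
  x <- c(0.5, 0.5)
  expect_identical(node_density(med, x), 0)
  add_nodes(med, x, c(0, 0.1))
  expect_identical(node_density(med, x), 1)
  add_nodes(med, x, c(0, -0.1))
  expect_identical(node_density(med, x), 2)
  # activated subset is empty until the delay has elapsed
  expect_identical(node_density(med, x, "active"), 0)
  med$t <- med$params$activation_delay
  expect_identical(node_density(med, x, "active"), 2)
})

test_that("weights reinforce near the state and decay far from it", {
  med <- idsm_new(2)
  add_nodes(med, p = rbind(c(0.5, 0.5), c(0.1, 0.9)), v = matrix(0, 2, 2))
  update_weights(med, c(0.5, 0.5), dt = 0.01)
  expect_equal(med$w[1], 0.01 * (-1 + 10), tolerance = 1e-12)  # at the state
  expect_equal(med$w[2], -0.01, tolerance = 1e-6)              # far away
  w_before <- med$w[1:2]
  update_weights(med, c(0.5, 0.5), dt = 0)
  expect_identical(med$w[1:2], w_before)
})

test_that("weights decay at the decay rate when nothing is revisited", {
  set.seed(7)
  med <- random_medium(30, 2)
  x <- c(10, 10)  # clamp the state far outside the node cloud (> 0.3 away)
  w0 <- med$w[1:med$n]
  for (k in 1:100) update_weights(med, x, dt = 0.01)
  drop1 <- w0 - med$w[1:med$n]   # loss over one time-unit
  expect_true(all(abs(drop1 - 1) < 0.01))
})

test_that("nodes are created only below the density threshold", {
  med <- idsm_new(2)
  x <- c(0.2, 0.8)
  maybe_create_node(med, x, c(0, 0))        # empty medium: always created
  expect_identical(med$n, 1L)
  expect_identical(med$w[1], 0)
  maybe_create_node(med, x, c(0, 0))        # fresh node at x: phi = 1, refused
  expect_identical(med$n, 1L)
  # nudge density just below threshold: the strict inequality admits a node
  med2 <- idsm_new(2)
  r <- sqrt(log(2 / 0.99 - 1) / 1000)       # distance where d = 0.99
  add_nodes(med2, c(0.2 + r, 0.8), c(0, 0))
  expect_equal(node_density(med2, x), 0.99, tolerance = 1e-9)
  maybe_create_node(med2, x, c(0, 0))
  expect_identical(med2$n, 2L)
})

test_that("node creation pushes local density toward the threshold", {
  set.seed(11)
  for (rep in 1:20) {
    med <- random_medium(sample(0:15, 1), 3)
    x <- runif(3)
    before <- node_density(med, x)
    maybe_create_node(med, x, runif(3, -0.1, 0.1))
    expect_gte(node_density(med, x), min(med$params$k_t, before))
    expect_gte(med$n, 0L)
  }
})

test_that("perpendicular projection removal is orthogonal to the velocity", {
  expect_equal(perpendicular_component(c(1, 0), c(0, 1)), c(1, 0))
  expect_equal(perpendicular_component(c(0, 2), c(0, 1)), c(0, 0))
  expect_equal(perpendicular_component(c(1, 1), c(1, 0)), c(0, 1))
  expect_identical(perpendicular_component(c(1, 2), c(0, 0)), c(1, 2))  # degenerate
  set.seed(3)
  for (rep in 1:50) {
    dim <- sample(2:4, 1)
    a <- rnorm(dim); v <- rnorm(dim)
    g <- perpendicular_component(a, v)
    expect_lt(abs(sum(g * v)) / sqrt(sum(v^2)) / max(sqrt(sum(g * g)), 1e-12), 1e-9)
  }
})

test_that("a single activated node at the query point returns its motor velocity", {
  med <- idsm_new(2)
  add_nodes(med, c(0.5, 0.5), c(0, 0.1))
  med$t <- 10
  expect_identical(motor_field(med, c(0.5, 0.5)), c(0, 0.1))
  expect_identical(motor_field(idsm_new(2), c(0.5, 0.5)), c(0, 0))
})

test_that("motor field equals the straight-loop oracle on random instances", {
  set.seed(42)
  for (rep in 1:60) {
    dim <- sample(c(2, 4), 1)
    mu <- if (dim == 2) 1:2 else 1:2
    med <- random_medium(sample(0:20, 1), dim, motor_idx = mu)
    x <- runif(dim)
    got <- motor_field(med, x)
    want <- oracle_motor_field(med, x)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("the fused step equals the composition of the exported operations", {
  set.seed(19)
  for (rep in 1:25) {
    dim <- sample(c(2, 4), 1)
    med <- random_medium(sample(0:20, 1), dim)
    x <- runif(dim); v <- runif(dim, -0.1, 0.1); dt <- 0.01
    m1 <- idsm_clone(med)
    m2 <- idsm_clone(med)
    f1 <- step_idsm(m1, x, v, dt)$field
    f2 <- motor_field(m2, x)
    update_weights(m2, x, dt)
    maybe_create_node(m2, x, v)
    m2$t <- m2$t + dt
    expect_equal(f1, f2, tolerance = 1e-12)
    expect_identical(m1$n, m2$n)
    expect_equal(m1$w[seq_len(m1$n)], m2$w[seq_len(m2$n)], tolerance = 1e-12)
    expect_equal(m1$t, m2$t)
  }
})

test_that("stepping never deletes nodes and freezing has no side effects", {
  set.seed(5)
  med <- random_medium(10, 2)
  n_before <- med$n
  snap <- idsm_nodes(med); t_before <- med$t
  res <- step_idsm(med, runif(2), c(0, 0), dt = 0.01, frozen = TRUE)
  expect_identical(idsm_nodes(med), snap)
  expect_identical(med$t, t_before)
  expect_length(res$field, 2)
  for (k in 1:50) step_idsm(med, runif(2), runif(2, -0.1, 0.1), dt = 0.01)
  expect_gte(med$n, n_before)
  # dt = 0 leaves time and weights unchanged
  med2 <- random_medium(5, 2)
  w0 <- med2$w[1:5]; t0 <- med2$t
  step_idsm(med2, c(2, 2), c(0, 0), dt = 0)
  expect_identical(med2$w[1:5], w0)
  expect_identical(med2$t, t0)
})
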