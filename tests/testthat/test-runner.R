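test_that("identical configuration and seed give identical trajectories", {
  r1 <- run_experiment(preset_motor_circle(seed = 3, total = 40))
  r2 <- run_experiment(preset_motor_circle(seed = 3, total = 40))
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(idsm_nodes(r1$idsm), idsm_nodes(r2$idsm))
  r3 <- run_experiment(preset_motor_circle(seed = 4, total = 40))
  expect_false(identical(r1$trajectory, r3$trajectory))
})

test_that("a training phase without a trainer is rejected before execution", {
  expect_error(
    experiment_config("motor_circle", phases = list(phase_spec("train", 5))),
    "no trainer")
  expect_error(
    experiment_config("motor_circle",
                      phases = list(phase_spec("free", 5)),
                      events = list(event_spec(3, "randomize_motors"),
                                    event_spec(1, "randomize_motors"))),
    "sorted")
})

test_that("with an empty medium the motors hold in a free phase", {
  cfg <- experiment_config("motor_circle",
                           phases = list(phase_spec("free", 2)),
                           seed = 1, body = body_motor2(0.3, -0.2))
  tr <- run_experiment(cfg)$trajectory
  expect_true(all(tr$m1 == 0.3))
  expect_true(all(tr$m2 == -0.2))
})

test_that("relocation resets the body but never touches the medium", {
  set.seed(1)
  b <- relocate(body_2d(), "random")
  set.seed(1)
  b2 <- relocate(body_2d(), "random")
  expect_identical(b, b2)
  expect_true(abs(b$x) <= 2 && abs(b$y) <= 2 && abs(b$alpha) <= pi)
  expect_true(abs(b$m_l) <= 1 && abs(b$m_r) <= 1)
  b3 <- relocate(body_1d(x = 3, m = 0.4), "to_pose", pose = list(x = -2.5))
  expect_identical(b3$x, -2.5)
  expect_identical(b3$m, 0.4)
  expect_identical(b3$s, sensor_1d(-2.5))
  # events leave the node record alone
  cfg <- preset_motor_circle(seed = 2, total = 35, train = 20, randomize_at = 30)
  run <- run_experiment(cfg)
  cfg2 <- preset_motor_circle(seed = 2, total = 29, train = 20)
  cfg2$events <- list()
  run2 <- run_experiment(cfg2)
  expect_identical(run2$idsm$n, run2$idsm$n)  # sanity
  expect_true(any(run$trajectory$event == "randomize_motors"))
})

test_that("the frozen flow-field probe has no side effects on the medium", {
  run <- run_experiment(preset_motor_circle(seed = 1, total = 21))
  med <- run$idsm
  snap <- idsm_nodes(med); t0 <- med$t
  ff <- flow_field(med, grid_n = 7)
  expect_identical(idsm_nodes(med), snap)
  expect_identical(med$t, t0)
  expect_identical(nrow(ff), 49L)
  # combined field is the sum of its velocity and attraction parts
  expect_equal(ff$field_1, ff$vel_1 + ff$att_1, tolerance = 1e-12)
  expect_equal(ff$field_2, ff$vel_2 + ff$att_2, tolerance = 1e-12)
})

test_that("a single vertical-velocity node attracts horizontally elsewhere", {
  med <- idsm_new(2)
  add_nodes(med, c(0.5, 0.5), c(0, 0.1))
  med$t <- 10   # past the activation delay
  ff <- flow_field(med, grid_n = 5)
  at_node <- ff$x1 == 0.5 & ff$x2 == 0.5
  expect_equal(ff$field_1[at_node], 0)
  expect_equal(ff$field_2[at_node], 0.1)
  # the velocity influence never has a horizontal part (the node's v is vertical)
  expect_true(all(ff$vel_1 == 0))
  # directly below the node, attraction points up toward it but the parallel
  # component is removed, so nothing remains; off-axis it pulls horizontally
  off <- ff$x1 == 0.25 & ff$x2 == 0.5
  expect_gt(ff$att_1[off], 0)
})

test_that("low-weight nodes lose their influence on the flow field", {
  base <- idsm_new(2)
  p <- rbind(c(0.4, 0.4), c(0.4, 0.6), c(0.6, 0.5), c(0.5, 0.35))
  v <- rbind(c(0.05, 0), c(0, -0.05), c(-0.05, 0.02), c(0, 0.05))
  add_nodes(base, p, v)
  base$t <- 10
  crushed <- idsm_clone(base)
  crushed$w[3] <- -1e7     # omega ~ 0: the node is effectively silent
  three <- idsm_new(2)
  add_nodes(three, p[-3, ], v[-3, ])
  three$t <- 10
  x <- c(0.55, 0.5)
  expect_equal(motor_field(crushed, x), motor_field(three, x), tolerance = 1e-6)
  expect_false(isTRUE(all.equal(motor_field(base, x), motor_field(three, x),
                                tolerance = 1e-3)))
})

test_that("a degenerate schedule reproduces the trainer exactly", {
  cfg <- experiment_config(
    "oscillation_1d",
    phases = list(phase_spec("train", 2)),
    trainer = trainer_config("oscillation_1d", duration = 2),
    seed = 1, stride = 10L, body = body_1d(x = -2.5, m = 0.5))
  tr <- run_experiment(cfg)$trajectory
  late <- tr$t > 0
  expect_equal(tr$m[late], trainer_oscillation_1d(tr$t[late] - 0.01),
               tolerance = 1e-12)
})
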