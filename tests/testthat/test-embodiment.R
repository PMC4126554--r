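test_that("1-D light sensor follows the inverse-square law", {
  expect_identical(sensor_1d(0), 1)
  expect_equal(sensor_1d(-2.5), 1 / 7.25, tolerance = 1e-12)
  expect_lt(sensor_1d(1e4), 1e-7)
})

test_that("1-D body integrates its motor and clips it", {
  b <- body_1d(x = 0, m = 1)
  b2 <- step_body_1d(b, motor_rate = 0, dt = 0.01)
  expect_equal(b2$x, 0.01)
  expect_equal(b2$s, sensor_1d(0.01))
  b3 <- body_1d(x = 0, m = 0)
  expect_identical(step_body_1d(b3, 0, dt = 0.5)$x, 0)
  b4 <- body_1d(x = 0, m = 0.999)
  expect_identical(step_body_1d(b4, motor_rate = 50, dt = 0.01)$m, 1)  # clip
})

test_that("sensorimotor spaces have the advertised dimensionality", {
  expect_length(sm_state(body_1d()), 2)
  expect_length(sm_state(body_2d()), 4)
  expect_length(sm_state(body_motor2()), 2)
})

test_that("directional sensors read the reconstructed activation law", {
  # left sensor exactly on the light, facing it: limit value 2
  b <- body_2d(x = -0.25, y = 0, alpha = -pi / 3)
  expect_identical(sensors_2d(b)[1], 2)
  # sensor facing directly away from the light: zero regardless of distance
  b <- body_2d(x = 0.5, y = 0, alpha = -pi / 3)   # left sensor at (0.75, 0), b = (1, 0)
  expect_equal(sensors_2d(b)[1], 0, tolerance = 1e-12)
  # sensor orthogonal to the light direction at unit distance: 0.5
  b <- body_2d(x = -0.25, y = -1, alpha = -pi / 3)  # left sensor at (0, -1)
  expect_equal(sensors_2d(b)[1], 0.5, tolerance = 1e-12)
})

test_that("sensors are invariant under joint translation of robot and light", {
  set.seed(21)
  for (rep in 1:20) {
    pose <- list(x = runif(1, -2, 2), y = runif(1, -2, 2), a = runif(1, -pi, pi))
    shift <- runif(2, -4, 4)
    b1 <- body_2d(pose$x, pose$y, pose$a)
    b2 <- body_2d(pose$x + shift[1], pose$y + shift[2], pose$a,
                  light = c(shift[1], shift[2]))
    expect_equal(sensors_2d(b1), sensors_2d(b2), tolerance = 1e-9)
  }
})

test_that("wheeled kinematics match the differential-drive equations", {
  b <- body_2d(x = 0, y = 0, alpha = 0, m_l = 1, m_r = 1)
  b2 <- advance_body(b, dt = 0.01)
  expect_equal(c(b2$x, b2$y, b2$alpha), c(0.02, 0, 0), tolerance = 1e-12)
  # opposite motors: pure rotation
  b <- body_2d(0, 0, 0, m_l = -0.4, m_r = 0.4)
  b2 <- advance_body(b, dt = 0.01)
  expect_equal(c(b2$x, b2$y), c(0, 0))
  expect_equal(b2$alpha, 0.01 * 2 * 0.8, tolerance = 1e-12)
  # periodic wrap at the arena edge
  b <- body_2d(1.99, 0, 0, m_l = 1, m_r = 1)
  b2 <- advance_body(b, dt = 0.015)
  expect_equal(b2$x, -1.98, tolerance = 1e-12)
})

test_that("constant unequal motors trace a circle of the closed-form radius", {
  # speed = m_l + m_r, turn rate = 2 (m_r - m_l), radius = speed / turn rate
  b <- body_2d(0, 0, 0, m_l = 0.5, m_r = 1, arena_width = 1000)
  pts <- matrix(NA, 3, 2)
  for (k in 1:3000) {
    b <- advance_body(b, dt = 0.01)
    if (k %% 1000 == 0) pts[k / 1000, ] <- c(b$x, b$y)
  }
  # circumradius from three points on the path
  a <- dist(pts)
  s <- as.vector(a)
  area <- 0.25 * sqrt((s[1] + s[2] + s[3]) * (-s[1] + s[2] + s[3]) *
                        (s[1] - s[2] + s[3]) * (s[1] + s[2] - s[3]))
  R <- prod(s) / (4 * area)
  expect_equal(R, 1.5 / 1, tolerance = 0.01)
})

test_that("trajectories are identical for equivalent wrapped starting points", {
  b1 <- body_2d(1.5, -1.5, 0.3, m_l = 0.8, m_r = 0.6)
  b2 <- body_2d(1.5 - 4, -1.5 + 4, 0.3, m_l = 0.8, m_r = 0.6)
  for (k in 1:500) {
    b1 <- advance_body(b1, 0.01)
    b2 <- advance_body(b2, 0.01)
  }
  expect_equal(c(b1$x, b1$y, b1$alpha), c(b2$x, b2$y, b2$alpha), tolerance = 1e-9)
})

test_that("normalization maps raw ranges onto [0,1] and back", {
  map <- sm_map(body_1d())
  expect_identical(normalize_sm(c(-1, 0.5), map), c(m = 0, s = 0.5))
  expect_identical(normalize_sm(c(0, 1), map), c(m = 0.5, s = 1))
  map2 <- sm_map(body_2d())
  expect_equal(unname(normalize_sm(c(0, 0, 2, 0), map2)[3]), 1)
  set.seed(8)
  for (rep in 1:20) {
    raw <- denormalize_sm(runif(4), map2)
    expect_equal(denormalize_sm(normalize_sm(raw, map2), map2), raw,
                 tolerance = 1e-12)
  }
  expect_warning(normalize_sm(c(3, 0.5), map), "clipping")
})
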