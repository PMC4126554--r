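#' Normalization map between raw and normalized sensorimotor coordinates
#'
#' Linear per-dimension rescaling of raw sensor/motor ranges onto \[0, 1\].
#' All medium computations happen in the normalized space; bodies work in
#' raw units.  Ranges are fixed a priori per body rather than adapted
#' online.
#'
#' @param raw_min,raw_max Named numeric vectors of per-dimension range
#'   endpoints (`raw_min < raw_max`).
#' @return An object of class `sm_map`.
#' @export
sm_map_new <- function(raw_min, raw_max) {
  stopifnot(length(raw_min) == length(raw_max), all(raw_min < raw_max))
  structure(list(raw_min = raw_min, raw_max = raw_max,
                 names = names(raw_min)), class = "sm_map")
}

#' Map a raw sensorimotor vector into \[0, 1\] per dimension
#'
#' Values outside the declared ranges are clipped with a warning.
#'
#' @param raw Raw sensorimotor vector.
#' @param map An [sm_map_new()] object.
#' @return Normalized vector, each component in \[0, 1\].
#' @export
normalize_sm <- function(raw, map) {
  u <- (raw - map$raw_min) / (map$raw_max - map$raw_min)
  if (any(u < -1e-9) || any(u > 1 + 1e-9)) {
    warning("raw sensorimotor values outside declared ranges; clipping")
  }
  clip(u, 0, 1)
}

#' @rdname normalize_sm
#' @param u Normalized vector.
#' @export
denormalize_sm <- function(u, map) {
  map$raw_min + u * (map$raw_max - map$raw_min)
}

## ---- generic body interface (used by the experiment runner) ---------------

#' @export
sm_map <- function(body) UseMethod("sm_map")
#' @export
sm_state <- function(body) UseMethod("sm_state")
#' @export
motor_index <- function(body) UseMethod("motor_index")
#' @export
set_motors <- function(body, m) UseMethod("set_motors")
#' @export
advance_body <- function(body, dt) UseMethod("advance_body")
#' @export
step_body <- function(body, rates, dt) UseMethod("step_body")

#' Relocate a robot body
#'
#' Resets the body's pose and/or motors without touching the medium.
#' `"random"` draws a uniform position over the arena (and heading over
#' \[-pi, pi\] for the wheeled robot) and uniform motors in \[-1, 1\];
#' `"motors"` randomizes motors only; `"to_pose"` sets the pose fields
#' given in `pose`, leaving motors as they are.  Sensors are recomputed.
#'
#' @param body A body object.
#' @param mode One of `"random"`, `"motors"`, `"to_pose"`.
#' @param pose Named list of pose fields for `"to_pose"`.
#' @return The relocated body.
#' @export
relocate <- function(body, mode = c("random", "motors", "to_pose"), pose = NULL) {
  UseMethod("relocate")
}

## ---- 1-D light robot -------------------------------------------------------

#' Non-directional light sensor of the 1-D robot
#'
#' The light sits at the origin of an unbounded line; activation is
#' inversely proportional to one plus the squared distance:
#' `s = 1 / (1 + x^2)`, so `s = 1` at the light and decays toward 0.
#'
#' @param x Robot position(s).
#' @return Sensor value(s) in (0, 1\].
#' @export
sensor_1d <- function(x) 1 / (1 + x^2)

#' One-dimensional light robot
#'
#' A robot on an unbounded line with a single motor (its velocity,
#' `m` in \[-1, 1\]) and a single non-directional light sensor.  Its
#' sensorimotor space is two-dimensional: `(m, s)`.
#'
#' @param x Initial position.
#' @param m Initial motor value (clipped to \[-1, 1\]).
#' @return An object of class `body_1d`.
#' @export
body_1d <- function(x = -2.5, m = 0) {
  structure(list(x = x, m = clip(m, -1, 1), s = sensor_1d(x)),
            class = c("body_1d", "idsm_body"))
}

#' @export
sm_map.body_1d <- function(body) {
  sm_map_new(c(m = -1, s = 0), c(m = 1, s = 1))
}
#' @export
sm_state.body_1d <- function(body) c(m = body$m, s = body$s)
#' @export
motor_index.body_1d <- function(body) 1L
#' @export
set_motors.body_1d <- function(body, m) {
  body$m <- clip(m, -1, 1)
  body
}
#' @export
advance_body.body_1d <- function(body, dt) {
  body$x <- body$x + dt * body$m
  body$s <- sensor_1d(body$x)
  body
}

#' Step the 1-D robot under a normalized motor rate
#'
#' The motor is advanced by one Euler step in normalized coordinates
#' (then de-normalized and clipped to \[-1, 1\]), the position by
#' `dt * m`, and the sensor recomputed.
#'
#' @param body A [body_1d()] object.
#' @param motor_rate Motor velocity in normalized units per time-unit.
#' @param dt Step size.
#' @return The stepped body.
#' @export
step_body_1d <- function(body, motor_rate, dt) {
  body <- set_motors(body, body$m + dt * motor_rate * 2)  # raw range width 2
  advance_body(body, dt)
}
#' @export
step_body.body_1d <- function(body, rates, dt) step_body_1d(body, rates, dt)

#' @export
relocate.body_1d <- function(body, mode = c("random", "motors", "to_pose"),
                             pose = NULL) {
  mode <- match.arg(mode)
  if (mode == "random") {
    body$x <- stats::runif(1, -2.5, 2.5)
    body$m <- stats::runif(1, -1, 1)
  } else if (mode == "motors") {
    body$m <- stats::runif(1, -1, 1)
  } else {
    if (!is.null(pose$x)) body$x <- pose$x
    if (!is.null(pose$m)) body$m <- clip(pose$m, -1, 1)
  }
  body$s <- sensor_1d(body$x)
  body
}

## ---- 2-D two-wheel robot ---------------------------------------------------

#' Two-wheeled robot with directional light sensors
#'
#' Differential-drive robot of radius `r_body` in a square arena of width
#' `arena_width` with periodic boundaries and a point light (default at
#' the center).  Kinematics: `xdot = cos(alpha) (m_l + m_r)`,
#' `ydot = sin(alpha) (m_l + m_r)`, `alphadot = 2 (m_r - m_l)`, with both
#' wheel motors in \[-1, 1\].  Two directional light sensors sit on the
#' rim at angular offsets `+/- beta` from the heading.  The sensorimotor
#' space is four-dimensional: `(m_l, m_r, s_l, s_r)`.
#'
#' @param x,y Initial position (wrapped into the arena).
#' @param alpha Initial heading, radians (wrapped to \[-pi, pi\]).
#' @param m_l,m_r Initial wheel motors (clipped to \[-1, 1\]).
#' @param r_body Robot radius.
#' @param beta Sensor angular offset from the heading.
#' @param arena_width Arena period.
#' @param light Light position.
#' @return An object of class `body_2d`.
#' @export
body_2d <- function(x = 0, y = 0, alpha = 0, m_l = 0, m_r = 0,
                    r_body = 0.25, beta = pi / 3, arena_width = 4,
                    light = c(0, 0)) {
  b <- structure(list(x = x, y = y, alpha = alpha,
                      m_l = clip(m_l, -1, 1), m_r = clip(m_r, -1, 1),
                      s_l = NA_real_, s_r = NA_real_,
                      r_body = r_body, beta = beta,
                      arena_width = arena_width, light = light),
                 class = c("body_2d", "idsm_body"))
  b$x <- wrap_interval(b$x, -arena_width / 2, arena_width / 2)
  b$y <- wrap_interval(b$y, -arena_width / 2, arena_width / 2)
  b$alpha <- wrap_interval(b$alpha, -pi, pi)
  s <- sensors_2d(b)
  b$s_l <- s[1]; b$s_r <- s[2]
  b
}

#' Directional light sensor pair of the wheeled robot
#'
#' Each sensor at `(x + r cos(alpha + beta), y + r sin(alpha + beta))`
#' reads `s = ((b . c / ||c||) + 1) / (1 + D^2)`, where `b` is the unit
#' vector the sensor faces, `c` the minimal-image vector from the sensor
#' to the light and `D = ||c||`.  The value is 2 when facing the light at
#' zero distance (limit convention), 0 when facing directly away, and
#' 0.5 when orthogonal at unit distance; the raw range is \[0, 2\].
#'
#' @param state A [body_2d()] object.
#' @param light Light position (defaults to the body's).
#' @return `c(s_l, s_r)`.
#' @export
sensors_2d <- function(state, light = state$light) {
  out <- numeric(2)
  offs <- c(state$beta, -state$beta)          # left sensor at +beta
  for (k in 1:2) {
    ang <- state$alpha + offs[k]
    b <- c(cos(ang), sin(ang))
    spos <- c(state$x + state$r_body * b[1], state$y + state$r_body * b[2])
    cv <- min_image(light - spos, state$arena_width)
    D <- sqrt(sum(cv^2))
    out[k] <- if (D == 0) 2 else (sum(b * cv) / D + 1) / (1 + D^2)
  }
  out
}

#' @export
sm_map.body_2d <- function(body) {
  sm_map_new(c(m_l = -1, m_r = -1, s_l = 0, s_r = 0),
             c(m_l = 1, m_r = 1, s_l = 2, s_r = 2))
}
#' @export
sm_state.body_2d <- function(body) {
  c(m_l = body$m_l, m_r = body$m_r, s_l = body$s_l, s_r = body$s_r)
}
#' @export
motor_index.body_2d <- function(body) 1:2
#' @export
set_motors.body_2d <- function(body, m) {
  m <- clip(m, -1, 1)
  body$m_l <- m[1]; body$m_r <- m[2]
  body
}
#' @export
advance_body.body_2d <- function(body, dt) {
  sp <- body$m_l + body$m_r
  w2 <- body$arena_width / 2
  body$x <- wrap_interval(body$x + dt * cos(body$alpha) * sp, -w2, w2)
  body$y <- wrap_interval(body$y + dt * sin(body$alpha) * sp, -w2, w2)
  body$alpha <- wrap_interval(body$alpha + dt * 2 * (body$m_r - body$m_l), -pi, pi)
  s <- sensors_2d(body)
  body$s_l <- s[1]; body$s_r <- s[2]
  body
}

#' Step the wheeled robot under normalized motor rates
#'
#' Both wheel motors advance by one Euler step in normalized coordinates
#' (then de-normalized and clipped), the pose advances under the
#' differential-drive kinematics, position wraps periodically, and the
#' sensors are recomputed.
#'
#' @param body A [body_2d()] object.
#' @param motor_rates Length-2 vector of motor velocities in normalized
#'   units per time-unit.
#' @param dt Step size.
#' @return The stepped body.
#' @export
step_body_2d <- function(body, motor_rates, dt) {
  body <- set_motors(body, c(body$m_l, body$m_r) + dt * motor_rates * 2)
  advance_body(body, dt)
}
#' @export
step_body.body_2d <- function(body, rates, dt) step_body_2d(body, rates, dt)

#' @export
relocate.body_2d <- function(body, mode = c("random", "motors", "to_pose"),
                             pose = NULL) {
  mode <- match.arg(mode)
  w2 <- body$arena_width / 2
  if (mode == "random") {
    body$x <- stats::runif(1, -w2, w2)
    body$y <- stats::runif(1, -w2, w2)
    body$alpha <- stats::runif(1, -pi, pi)
    body$m_l <- stats::runif(1, -1, 1)
    body$m_r <- stats::runif(1, -1, 1)
  } else if (mode == "motors") {
    body$m_l <- stats::runif(1, -1, 1)
    body$m_r <- stats::runif(1, -1, 1)
  } else {
    for (f in c("x", "y", "alpha", "m_l", "m_r")) {
      if (!is.null(pose[[f]])) body[[f]] <- pose[[f]]
    }
    body$x <- wrap_interval(body$x, -w2, w2)
    body$y <- wrap_interval(body$y, -w2, w2)
    body$alpha <- wrap_interval(body$alpha, -pi, pi)
    body$m_l <- clip(body$m_l, -1, 1)
    body$m_r <- clip(body$m_r, -1, 1)
  }
  s <- sensors_2d(body)
  body$s_l <- s[1]; body$s_r <- s[2]
  body
}

## ---- 2-motor, 0-sensor agent ----------------------------------------------

#' Two-motor, zero-sensor agent
#'
#' A disembodied motor pair used to demonstrate the medium as a dynamical
#' system on motor space alone; its sensorimotor space is the two motor
#' values `(m_1, m_2)`, each in \[-1, 1\].
#'
#' @param m1,m2 Initial motor values.
#' @return An object of class `body_motor2`.
#' @export
body_motor2 <- function(m1 = 0, m2 = 0) {
  structure(list(m = clip(c(m1, m2), -1, 1)),
            class = c("body_motor2", "idsm_body"))
}

#' @export
sm_map.body_motor2 <- function(body) {
  sm_map_new(c(m1 = -1, m2 = -1), c(m1 = 1, m2 = 1))
}
#' @export
sm_state.body_motor2 <- function(body) c(m1 = body$m[1], m2 = body$m[2])
#' @export
motor_index.body_motor2 <- function(body) 1:2
#' @export
set_motors.body_motor2 <- function(body, m) {
  body$m <- clip(m, -1, 1)
  body
}
#' @export
advance_body.body_motor2 <- function(body, dt) body
#' @export
step_body.body_motor2 <- function(body, rates, dt) {
  set_motors(body, body$m + dt * rates * 2)
}
#' @export
relocate.body_motor2 <- function(body, mode = c("random", "motors", "to_pose"),
                                 pose = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("random", "motors")) {
    body$m <- stats::runif(2, -1, 1)
  } else if (!is.null(pose$m)) {
    body$m <- clip(pose$m, -1, 1)
  }
  body
}
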