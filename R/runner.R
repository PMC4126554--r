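#' Phase of an experiment schedule
#'
#' @param kind `"train"` (the trainer drives the motors while the medium
#'   records), `"free"` (the medium drives the motors) or `"frozen"` (the
#'   medium drives the motors but is itself left untouched).
#' @param duration Phase length in time-units.
#' @return A phase descriptor.
#' @export
phase_spec <- function(kind = c("train", "free", "frozen"), duration) {
  kind <- match.arg(kind)
  stopifnot(duration > 0)
  list(kind = kind, duration = duration)
}

#' Scheduled event of an experiment
#'
#' @param time Event time in time-units.
#' @param kind `"relocate_random"` (random pose and motors),
#'   `"randomize_motors"` (motors only) or `"relocate_to"` (explicit pose).
#' @param pose Named list of pose fields for `"relocate_to"`.
#' @return An event descriptor.
#' @export
event_spec <- function(time, kind = c("relocate_random", "randomize_motors",
                                      "relocate_to"), pose = NULL) {
  kind <- match.arg(kind)
  stopifnot(time >= 0)
  list(time = time, kind = kind, pose = pose)
}

#' Full configuration of a coupled medium/body experiment
#'
#' @param experiment One of `"motor_circle"`, `"oscillation_1d"`,
#'   `"trained_2d"`, `"random_init_2d"`; selects the body.
#' @param phases Ordered list of [phase_spec()] entries.
#' @param events List of [event_spec()] entries (sorted by time).
#' @param trainer A [trainer_config()], required if any phase is a
#'   training phase.
#' @param seeding Optional [random_walk_config()] applied before the run.
#' @param params An [idsm_params()] object.
#' @param seed RNG seed for the whole run (relocations, seeding).
#' @param stride Record every `stride`-th integration step.
#' @param body Optional explicit initial body (defaults per experiment).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("motor_circle", "oscillation_1d",
                                             "trained_2d", "random_init_2d"),
                              phases, events = list(), trainer = NULL,
                              seeding = NULL, params = idsm_params(),
                              seed = 1L, stride = 10L, body = NULL) {
  experiment <- match.arg(experiment)
  stopifnot(length(phases) >= 1)
  kinds <- vapply(phases, `[[`, "", "kind")
  if (any(kinds == "train") && is.null(trainer)) {
    stop("a training phase is scheduled but no trainer is configured")
  }
  if (length(events) > 1) {
    tv <- vapply(events, `[[`, 0, "time")
    if (is.unsorted(tv)) stop("events must be sorted by time")
  }
  structure(list(experiment = experiment, phases = phases, events = events,
                 trainer = trainer, seeding = seeding, params = params,
                 seed = seed, stride = as.integer(stride), body = body),
            class = "experiment_config")
}

.default_body <- function(experiment) {
  switch(experiment,
         motor_circle = body_motor2(),
         oscillation_1d = body_1d(x = -2.5, m = 0),
         trained_2d = body_2d(),
         random_init_2d = body_2d())
}

.body_state_names <- function(body) names(.body_state(body))

.body_state <- function(body) {
  if (inherits(body, "body_1d")) {
    c(x = body$x, m = body$m, s = body$s)
  } else if (inherits(body, "body_2d")) {
    c(x = body$x, y = body$y, alpha = body$alpha,
      m_l = body$m_l, m_r = body$m_r, s_l = body$s_l, s_r = body$s_r)
  } else {
    c(m1 = body$m[1], m2 = body$m[2])
  }
}

.apply_event <- function(body, ev) {
  switch(ev$kind,
         relocate_random = relocate(body, "random"),
         randomize_motors = relocate(body, "motors"),
         relocate_to = relocate(body, "to_pose", pose = ev$pose))
}

#' Run a phase-scheduled coupled experiment
#'
#' Executes the configured phase schedule with fixed-step Euler
#' integration: in training phases the trainer drives the motors while the
#' medium records nodes and updates weights; in free phases the medium's
#' motor field drives the motors; in frozen phases the field drives the
#' motors but the medium is not modified.  Relocation events reset the
#' body without touching the medium.  Within every step the medium
#' performs, in order: field evaluation, weight update, node-creation
#' check, clock advance.  Node velocities are backward finite differences
#' of the realized normalized trajectory; across a relocation event the
#' difference is reset to zero (a teleport has no meaningful velocity).
#'
#' @param config An [experiment_config()].
#' @return A list of class `idsm_run` with elements `trajectory` (data
#'   frame: `t`, `phase`, raw body state, normalized sensorimotor state
#'   `sm_*`, `event`), `idsm` (the final medium), `map` (the normalization
#'   map) and `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  dt <- config$params$dt
  body <- if (is.null(config$body)) .default_body(config$experiment) else config$body
  map <- sm_map(body)
  D <- length(map$raw_min)
  medium <- idsm_new(dim = D, motor_idx = motor_index(body),
                     params = config$params, capacity = 1024L)
  if (!is.null(config$seeding)) seed_idsm(medium, config$seeding)

  durations <- vapply(config$phases, `[[`, 0, "duration")
  steps_per_phase <- round(durations / dt)
  n_steps <- sum(steps_per_phase)
  phase_kind <- rep(vapply(config$phases, `[[`, "", "kind"), steps_per_phase)

  ev_step <- vapply(config$events, function(e) round(e$time / dt), 0)
  ev_ptr <- 1L

  stride <- config$stride
  n_rec <- n_steps %/% stride + 1L
  state_nms <- .body_state_names(body)
  REC <- matrix(NA_real_, n_rec, 1L + length(state_nms) + D)
  colnames(REC) <- c("t", state_nms, paste0("sm_", map$names))
  rec_phase <- character(n_rec)
  rec_event <- character(n_rec)
  rec_row <- 1L
  REC[1L, ] <- c(0, .body_state(body), normalize_sm(sm_state(body), map))
  rec_phase[1L] <- phase_kind[1L]
  rec_event[1L] <- ""
  pending_events <- character(0)

  x_prev <- normalize_sm(sm_state(body), map)
  for (k in seq_len(n_steps) - 1L) {
    # events scheduled at the start of this step
    while (ev_ptr <= length(ev_step) && ev_step[ev_ptr] == k) {
      body <- .apply_event(body, config$events[[ev_ptr]])
      pending_events <- c(pending_events, config$events[[ev_ptr]]$kind)
      x_prev <- normalize_sm(sm_state(body), map)   # no velocity across a teleport
      ev_ptr <- ev_ptr + 1L
    }
    ph <- phase_kind[k + 1L]
    x <- normalize_sm(sm_state(body), map)
    v_est <- (x - x_prev) / dt
    if (ph == "train") {
      .idsm_step(medium, x, v_est, dt, drive = FALSE)
      body <- .drive_trainer(body, config$trainer, k * dt, dt)
    } else if (ph == "free") {
      field <- .idsm_step(medium, x, v_est, dt, drive = TRUE)
      body <- step_body(body, field, dt)
    } else {                                        # frozen medium
      field <- .idsm_step(medium, x, v_est, dt, drive = TRUE, frozen = TRUE)
      body <- step_body(body, field, dt)
    }
    x_prev <- x
    if ((k + 1L) %% stride == 0L) {
      rec_row <- rec_row + 1L
      REC[rec_row, ] <- c((k + 1L) * dt, .body_state(body),
                          normalize_sm(sm_state(body), map))
      rec_phase[rec_row] <- ph
      rec_event[rec_row] <- paste(pending_events, collapse = ";")
      pending_events <- character(0)
    }
  }

  traj <- as.data.frame(REC[seq_len(rec_row), , drop = FALSE])
  traj$phase <- rec_phase[seq_len(rec_row)]
  traj$event <- rec_event[seq_len(rec_row)]
  structure(list(trajectory = traj, idsm = medium, map = map, config = config),
            class = "idsm_run")
}

#' @export
print.idsm_run <- function(x, ...) {
  cat(sprintf("<idsm_run> %s: %d recorded steps, %d nodes, t = %g\n",
              x$config$experiment, nrow(x$trajectory), x$idsm$n, x$idsm$t))
  invisible(x)
}

#' Sample the frozen motor field on a lattice
#'
#' Evaluates the medium's motor field on a regular grid of normalized
#' sensorimotor points with weights fixed and no node creation (the medium
#' is not modified), returning the velocity and attraction influences
#' separately and combined — the three panels of a flow-field portrait.
#' Grid points vary over the motor dimensions; any remaining (sensor)
#' dimensions are held at `base`.
#'
#' @param idsm An `idsm` object (read-only).
#' @param grid_n Grid resolution per motor dimension.
#' @param base Baseline normalized state supplying non-motor coordinates.
#' @return A data frame with the grid coordinates (`x1`, `x2`, ...), the
#'   velocity influence (`vel_*`), attraction influence (`att_*`),
#'   combined field (`field_*`) and the activated-node density `phi`.
#' @export
flow_field <- function(idsm, grid_n = 21, base = rep(0.5, idsm$dim)) {
  mu <- idsm$motor_idx
  g <- seq(0, 1, length.out = grid_n)
  grids <- rep(list(g), length(mu))
  pts <- as.matrix(expand.grid(grids))
  out <- matrix(NA_real_, nrow(pts), 3 * length(mu) + 1)
  for (i in seq_len(nrow(pts))) {
    x <- base
    x[mu] <- pts[i, ]
    fc <- motor_field_components(idsm, x)
    out[i, ] <- c(fc$velocity, fc$attraction, fc$combined, fc$phi)
  }
  df <- as.data.frame(cbind(pts, out))
  names(df) <- c(paste0("x", seq_along(mu)),
                 paste0("vel_", seq_along(mu)),
                 paste0("att_", seq_along(mu)),
                 paste0("field_", seq_along(mu)), "phi")
  df
}

## ---- presets ---------------------------------------------------------------

#' Preset: circular motor training of the 2-motor agent
#'
#' Train the 2-motor, 0-sensor agent on the circular signal for
#' `train` time-units, then release the medium; at `randomize_at` both
#' motors are set to uniform-random values in \[-1, 1\] and the medium
#' re-enacts the trained cycle.
#'
#' @param seed RNG seed.
#' @param total Total run length in time-units.
#' @param train Training duration.
#' @param randomize_at Time of the motor randomization event.
#' @param params An [idsm_params()] object.
#' @param stride Recording stride (integration steps).
#' @return An [experiment_config()].
#' @export
preset_motor_circle <- function(seed = 1, total = 100, train = 20,
                                randomize_at = 30, params = idsm_params(),
                                stride = 10L) {
  experiment_config(
    "motor_circle",
    phases = list(phase_spec("train", train), phase_spec("free", total - train)),
    events = list(event_spec(randomize_at, "randomize_motors")),
    trainer = trainer_config("circle_2motor", duration = train),
    params = params, seed = seed, stride = stride,
    body = body_motor2(m1 = 0.75, m2 = 0))
}

#' Preset: oscillation training of the 1-D light robot
#'
#' Starting at `x = -2.5`, drive the motor with the oscillatory trainer
#' for `train` time-units, then release the medium; at `relocate_at` the
#' robot is put back at its starting position (motor left as-is) and the
#' trained oscillation resumes.
#'
#' @inheritParams preset_motor_circle
#' @param relocate_at Time of the relocation event.
#' @return An [experiment_config()].
#' @export
preset_oscillation_1d <- function(seed = 1, total = 80, train = 20,
                                  relocate_at = 35, params = idsm_params(),
                                  stride = 10L) {
  experiment_config(
    "oscillation_1d",
    phases = list(phase_spec("train", train), phase_spec("free", total - train)),
    events = list(event_spec(relocate_at, "relocate_to", pose = list(x = -2.5))),
    trainer = trainer_config("oscillation_1d", duration = train),
    params = params, seed = seed, stride = stride,
    body = body_1d(x = -2.5, m = trainer_oscillation_1d(0)))
}

#' Preset: Braitenberg training of the wheeled robot
#'
#' Train the two-wheel robot with one of the Braitenberg-style controllers
#' for `train` time-units, then release the medium for `free` time-units.
#' Every `relocate_every` time-units (counted from t = 0, across the phase
#' boundary) the robot is relocated to a random position with random
#' motors, so the behavior is trained and probed from many initial
#' conditions.
#'
#' @inheritParams preset_motor_circle
#' @param kind Trainer kind: `"simple_phototaxis"`,
#'   `"sinusoidal_phototaxis"` or `"photophobia"`.
#' @param train Training duration.
#' @param free Free-phase duration.
#' @param relocate_every Relocation interval.
#' @return An [experiment_config()].
#' @export
preset_trained_2d <- function(kind = "simple_phototaxis", seed = 1,
                              train = 100, free = 400, relocate_every = 50,
                              params = idsm_params(), stride = 10L) {
  times <- seq(0, train + free - relocate_every, by = relocate_every)
  experiment_config(
    "trained_2d",
    phases = list(phase_spec("train", train), phase_spec("free", free)),
    events = lapply(times, event_spec, kind = "relocate_random"),
    trainer = trainer_config(kind, duration = train),
    params = params, seed = seed, stride = stride)
}

#' Preset: habit emergence from a randomly seeded medium
#'
#' No training: the medium is seeded with random-walk nodes and then runs
#' a sequence of `n_trials` free trials of `trial` time-units each; at the
#' start of every trial the robot is placed at a random position with
#' random motors.  The medium persists across trials.
#'
#' @inheritParams preset_motor_circle
#' @param n_trials Number of trials.
#' @param trial Trial duration.
#' @param seeding A [random_walk_config()]; its seed defaults to the run
#'   seed.
#' @return An [experiment_config()].
#' @export
preset_random_init_2d <- function(seed = 1, n_trials = 10, trial = 100,
                                  seeding = NULL, params = idsm_params(),
                                  stride = 10L) {
  if (is.null(seeding)) seeding <- random_walk_config(seed = seed)
  times <- seq(0, by = trial, length.out = n_trials)
  experiment_config(
    "random_init_2d",
    phases = list(phase_spec("free", n_trials * trial)),
    events = lapply(times, event_spec, kind = "relocate_random"),
    seeding = seeding, params = params, seed = seed, stride = stride)
}
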