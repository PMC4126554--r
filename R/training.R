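#' Configuration of an externally imposed training controller
#'
#' During a training phase the controller, not the medium, drives the
#' motors; the medium merely records nodes along the realized trajectory.
#' The direct controllers (`circle_2motor`, `oscillation_1d`) set the
#' motors exactly; the Braitenberg-style controllers
#' (`simple_phototaxis`, `sinusoidal_phototaxis`, `photophobia`) produce
#' clipped sensor-driven targets that the motors approach smoothly with
#' unit time constant.
#'
#' @param kind One of `"circle_2motor"`, `"oscillation_1d"`,
#'   `"simple_phototaxis"`, `"sinusoidal_phototaxis"`, `"photophobia"`.
#' @param duration Training duration in time-units.
#' @param amplitude Motor amplitude of the circular controller.
#' @param period Period of the circular controller, in time-units.
#' @return An object of class `trainer_config`.
#' @export
trainer_config <- function(kind, duration = 20, amplitude = 0.75, period = 10) {
  kind <- match.arg(kind, c("circle_2motor", "oscillation_1d",
                            "simple_phototaxis", "sinusoidal_phototaxis",
                            "photophobia"))
  stopifnot(duration > 0, amplitude > 0, period > 0)
  structure(list(kind = kind, duration = duration,
                 amplitude = amplitude, period = period),
            class = "trainer_config")
}

#' Circular motor training signal
#'
#' Sets the two motors of the 2-motor, 0-sensor agent directly onto a
#' circle of the given amplitude:
#' `m1 = A cos(2 pi t / T)`, `m2 = A sin(2 pi t / T)`.
#'
#' @param t Time in time-units.
#' @param amplitude Circle radius in motor units.
#' @param period Period in time-units.
#' @return `c(m1, m2)`.
#' @export
trainer_circle <- function(t, amplitude = 0.75, period = 10) {
  amplitude * c(cos(2 * pi * t / period), sin(2 * pi * t / period))
}

#' Oscillatory training signal for the 1-D robot
#'
#' Sets the single motor directly to `m = cos(t/2) / 2`, which drives the
#' robot back and forth on one side of the light.
#'
#' @param t Time in time-units.
#' @return Motor value.
#' @export
trainer_oscillation_1d <- function(t) cos(t / 2) / 2

#' Braitenberg-style motor targets
#'
#' Target left/right motor values from the two directional light sensors:
#' simple phototaxis is an inverse ipsilateral wiring
#' (`chi_l = 1 - 1.5 sigma_l`, `chi_r = 1 - 1.5 sigma_r`); sinusoidal
#' phototaxis adds an antisymmetric wiggle `+/- sin(2t)/2`; photophobia
#' uses the contralateral wiring (`chi_l = 1 - 1.5 sigma_r`,
#' `chi_r = 1 - 1.5 sigma_l`).  Targets are clipped to \[-1, 1\] before
#' being used in the smooth motor update.
#'
#' @param kind `"simple_phototaxis"`, `"sinusoidal_phototaxis"` or
#'   `"photophobia"`.
#' @param sigma_l,sigma_r Sensor values.
#' @param t Time (only the sinusoidal variant depends on it).
#' @return `c(chi_l, chi_r)`, clipped to \[-1, 1\].
#' @export
braitenberg_targets <- function(kind, sigma_l, sigma_r, t = 0) {
  chi <- switch(kind,
    simple_phototaxis = c(1 - 1.5 * sigma_l, 1 - 1.5 * sigma_r),
    sinusoidal_phototaxis = c(1 - 1.5 * sigma_l + sin(2 * t) / 2,
                              1 - 1.5 * sigma_r - sin(2 * t) / 2),
    photophobia = c(1 - 1.5 * sigma_r, 1 - 1.5 * sigma_l),
    stop("unknown trainer kind: ", kind))
  clip(chi, -1, 1)
}

#' Smooth approach of a motor toward its target
#'
#' One Euler step of `dm/dt = chi - m` (exponential approach with unit
#' time constant), used by the Braitenberg-style trainers.
#'
#' @param m Current motor value(s).
#' @param chi Target value(s).
#' @param dt Step size.
#' @return Updated motor value(s).
#' @export
motor_smoothing <- function(m, chi, dt) m + dt * (chi - m)

## Drive a body for one training step: set/update motors from the trainer
## at time t, then advance the body kinematics over [t, t + dt].
.drive_trainer <- function(body, trainer, t, dt) {
  body <- switch(trainer$kind,
    circle_2motor = set_motors(body, trainer_circle(t, trainer$amplitude,
                                                    trainer$period)),
    oscillation_1d = set_motors(body, trainer_oscillation_1d(t)),
    {
      chi <- braitenberg_targets(trainer$kind, body$s_l, body$s_r, t)
      set_motors(body, motor_smoothing(c(body$m_l, body$m_r), chi, dt))
    })
  advance_body(body, dt)
}
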