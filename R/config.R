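#' Simulation configuration
#'
#' Bundles the acquisition geometry and sampling parameters shared by the
#' synthetic-data generator and the sonar processing chain. Defaults mirror a
#' standard biomimetic sonar bench: 500 kHz sampling, a 180 degree scan from
#' -90 to +90 in 1.8 degree steps (101 angles), and a 20 cm target distance.
#'
#' @param sample_rate sampling rate in Hz.
#' @param speed_of_sound speed of sound in m/s.
#' @param n_angles number of angles in one scan plane.
#' @param angle_range two-element vector, scan limits in degrees.
#' @param target_distance transducer-to-flower distance in metres; sets the
#'   echo delay in the simulated impulse responses.
#' @param ir_length length of simulated impulse responses in samples.
#' @param seed integer seed that fully determines all random draws made by
#'   generator functions that take a `cfg`.
#' @return An object of class `sim_config` (a list).
#' @examples
#' cfg <- sim_config()
#' length(sim_angles(cfg))  # 101
#' @export
sim_config <- function(sample_rate = 5e5, speed_of_sound = 343,
                       n_angles = 101, angle_range = c(-90, 90),
                       target_distance = 0.20, ir_length = 2048,
                       seed = 1L) {
  stopifnot(sample_rate > 0, speed_of_sound > 0, n_angles >= 1,
            length(angle_range) == 2, angle_range[1] < angle_range[2],
            target_distance >= 0, ir_length >= 1)
  structure(list(sample_rate = sample_rate,
                 speed_of_sound = speed_of_sound,
                 n_angles = as.integer(n_angles),
                 angle_range = angle_range,
                 target_distance = target_distance,
                 ir_length = as.integer(ir_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Angle grid of a scan plane
#'
#' @param cfg a [sim_config()].
#' @return numeric vector of angles in degrees (length `cfg$n_angles`).
#' @export
sim_angles <- function(cfg) {
  seq(cfg$angle_range[1], cfg$angle_range[2], length.out = cfg$n_angles)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  sample rate     : %g Hz\n", x$sample_rate))
  cat(sprintf("  speed of sound  : %g m/s\n", x$speed_of_sound))
  cat(sprintf("  angles          : %d in [%g, %g] deg\n",
              x$n_angles, x$angle_range[1], x$angle_range[2]))
  cat(sprintf("  target distance : %g m\n", x$target_distance))
  cat(sprintf("  IR length       : %d samples\n", x$ir_length))
  invisible(x)
}
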