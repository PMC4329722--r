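#' Read a model configuration file
#'
#' Parses a nested YAML configuration whose keys mirror the standard
#' parameter table (`n_columns`, `coupling_strength`, `constant_input`,
#' `noise_intensity`, `noise_correlation_time`, `integration_step`,
#' `simulation_length`, `transient_length`, `driving_*`, `composed_*`, and an
#' optional `column:` block with the Jansen-Rit constants) into the package's
#' configuration objects. Missing keys fall back to the defaults of the
#' corresponding constructors.
#'
#' @param path YAML file.
#' @return A list with `net`, `params`, `ou`, `drive`, `sim`, and (when
#'   present) the raw `experiment` block.
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cp <- raw$column %||% list()
  params <- do.call(jr_params, cp)
  net <- jr_network(N = raw$n_columns %||% 4,
                    K = raw$coupling_strength %||% 15,
                    p_const = raw$constant_input %||% 75)
  ou <- ou_config(D = raw$noise_intensity %||% 350,
                  tau = raw$noise_correlation_time %||% 0.15)
  sim <- sim_config(h = raw$integration_step %||% 0.001,
                    duration = raw$simulation_length %||% 1010,
                    transient = raw$transient_length %||% 10,
                    seed = raw$seed %||% 1,
                    record_stride = raw$record_stride %||% 1L)
  mode <- raw$driving_mode %||% "none"
  drive <- drive_spec(mode,
                      amplitude = raw$driving_amplitude %||% 45,
                      frequency = raw$driving_frequency %||% 0.25,
                      amplitude_composed = raw$composed_amplitude,
                      f_min = raw$composed_f_min %||% 0.05,
                      f_max = raw$composed_f_max %||% 4,
                      f_step = raw$composed_f_step %||% 0.05,
                      phases = raw$composed_phases,
                      phase_seed = raw$composed_phase_seed %||% 1)
  list(net = net, params = params, ou = ou, drive = drive, sim = sim,
       experiment = raw$experiment)
}

#' Write a model configuration file
#'
#' Inverse of [read_model_config()]: serializes configuration objects to the
#' same YAML key set. Composed-drive phases are written out in full so a run
#' can be reproduced exactly.
#'
#' @param path Output YAML file.
#' @param net,params,ou,drive,sim Configuration objects.
#' @param experiment Optional experiment block (list), passed through.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(path, net = jr_network(),
                               params = jr_params(), ou = ou_config(),
                               drive = drive_spec("none"),
                               sim = sim_config(), experiment = NULL) {
  out <- list(
    n_columns = net$N,
    coupling_strength = if (net$N > 1) net$K[2, 1] else 0,
    constant_input = net$p_const,
    noise_intensity = ou$D,
    noise_correlation_time = ou$tau,
    integration_step = sim$h,
    simulation_length = sim$duration,
    transient_length = sim$transient,
    seed = sim$seed,
    record_stride = sim$record_stride,
    driving_mode = drive$mode,
    driving_amplitude = drive$amplitude,
    driving_frequency = drive$frequency,
    column = unclass(params)
  )
  if (drive$mode == "composed") {
    out$composed_amplitude <- drive$amplitude_composed
    out$composed_f_min <- drive$f_min
    out$composed_f_max <- drive$f_max
    out$composed_f_step <- drive$f_step
    out$composed_phases <- drive$phases
  }
  if (!is.null(experiment)) out$experiment <- experiment
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}
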