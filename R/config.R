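#' Assemble and validate an experiment configuration
#'
#' A declarative description of one simulated stretching experiment:
#' plant (preset name or explicit SLS parameters), controller overrides,
#' loading command, noise, fiber and optics, seed. Every field has the
#' package default, so an empty config reproduces the reference cyclic
#' loading run on the 7% w/v GelMA plant.
#'
#' @param plant Preset name (`"gelma_7pct"`, `"gelma_5p5pct"`) or a named
#'   list with `lambda1`, `lambda2`, `tau`.
#' @param design_plant Plant the controller is designed on (defaults to
#'   `plant`); set differently for mismatch/robustness studies.
#' @param controller Named list of [controller_design()] overrides
#'   (`Q`, `R`, `gamma`, `observer_poles`, `Q_ref`, `basis_order`).
#' @param command Named list of [loading_command()] overrides.
#' @param noise Named list of [noise_spec()] overrides, or `FALSE` for a
#'   noiseless run.
#' @param fiber Named list of [fiber_spec()] overrides.
#' @param vision Named list of [optics_spec()] overrides.
#' @param seed Integer seed (default 1).
#' @param out_dir Optional output directory for artefacts.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(plant = "gelma_7pct", design_plant = NULL,
                              controller = list(), command = list(),
                              noise = list(), fiber = list(),
                              vision = list(), seed = 1, out_dir = NULL) {
  as_params <- function(p) {
    if (inherits(p, "sls_parameters")) return(p)
    if (is.character(p)) return(gelma_preset(p))
    if (is.list(p)) return(do.call(sls_parameters, p))
    stop("cannot interpret plant specification", call. = FALSE)
  }
  plant <- as_params(plant)
  design_plant <- if (is.null(design_plant)) plant else as_params(design_plant)
  check_names <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop(sprintf("unknown %s field(s): %s", where,
                   paste0(where, ".", bad, collapse = ", ")), call. = FALSE)
    }
    x
  }
  controller <- check_names(controller,
    c("Q", "R", "gamma", "observer_poles", "Q_ref", "basis_order"), "controller")
  command <- check_names(command,
    c("offset_uN", "amplitude_uN", "frequency_Hz", "n_cycles", "dt_s"), "command")
  if (!isFALSE(noise)) {
    noise <- check_names(noise, c("mean_abs_uN", "model"), "noise")
  }
  fiber <- check_names(fiber, c("diameter_um", "L0_um", "S_um2"), "fiber")
  vision <- check_names(vision,
    c("resolution", "fov_mm", "objective_factor"), "vision")
  # YAML scalars may arrive as strings; coerce every numeric field
  num <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
  for (k in names(controller)) controller[[k]] <- num(controller[[k]])
  for (k in names(command)) command[[k]] <- num(command[[k]])
  for (k in names(fiber)) fiber[[k]] <- num(fiber[[k]])
  if (!isFALSE(noise) && !is.null(noise$mean_abs_uN)) {
    noise$mean_abs_uN <- as.numeric(noise$mean_abs_uN)
  }
  if (length(controller$Q)) controller$Q <- matrix(controller$Q, 2, 2)
  if (length(controller$Q_ref)) {
    controller$Q_ref <- matrix(controller$Q_ref, 2, 2)
  }
  if (length(controller$basis_order)) {
    controller$basis_order <- as.integer(controller$basis_order)
  }
  structure(list(plant = plant, design_plant = design_plant,
                 controller = controller, command = command,
                 noise = noise, fiber = fiber, vision = vision,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Top-level keys mirror the [experiment_config()] arguments, e.g.
#' ```yaml
#' plant: gelma_7pct
#' controller:
#'   gamma: 0.001
#' command:
#'   amplitude_uN: 5
#' seed: 1
#' ```
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("plant", "design_plant", "controller", "command", "noise",
               "fiber", "vision", "seed", "out_dir")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(experiment_config, raw)
}

#' Run a configured cyclic-loading experiment
#'
#' Builds the plant and controller, runs the closed loop, and (when
#' `out_dir` is set) writes the trace CSV and design JSON. Instability is
#' reported as a condition of class `fiberstretch_unstable`.
#'
#' @param config An [experiment_config()].
#' @return List with `trace`, `design`, `tracking` (summary tibble) and
#'   `files` (paths written, if any).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  model <- to_state_space(config$design_plant)
  design <- do.call(controller_design, c(list(model = model), config$controller))
  command <- do.call(loading_command, config$command)
  noise <- if (isFALSE(config$noise)) NULL else do.call(noise_spec, config$noise)
  trace <- run_closed_loop(config$plant, design, command, noise,
                           seed = config$seed)
  files <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    f1 <- file.path(config$out_dir, "trace.csv")
    f2 <- file.path(config$out_dir, "design.json")
    write_trace_csv(trace, f1)
    write_design_json(design, f2)
    files <- c(trace = f1, design = f2)
  }
  list(trace = trace, design = design,
       tracking = tracking_error(trace), files = files)
}
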