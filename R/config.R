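#' Run configuration with package defaults
#'
#' Central bundle of tunable parameters. Defaults follow the method's
#' standard operating point: nonbonded cutoff 8 A for interactive-style
#' energy evaluation but 100 A for automated docking (so no cutoff
#' crossings perturb the descent), temperature 300 K, a linear
#' distance-dependent dielectric, damped fixed-point receptor relaxation,
#' and clamped steepest-descent ligand steps.
#'
#' @param cutoff nonbonded cutoff, Angstrom.
#' @param dielectric list: `model` ("linear" or "constant"), `slope`
#'   (dimensionless, for eps_r(r) = slope * r / A) and `constant`.
#' @param temperature Kelvin.
#' @param solver list: `gamma` damping of the fixed-point receptor update,
#'   `tol` residual tolerance (Angstrom), `max_iter`.
#' @param docking list: `step_t` (A per kcal/mol/A), `step_r` (rad per
#'   kcal/mol/rad), `max_t` (A), `max_r` (rad), `f_tol`, `tau_tol`
#'   (convergence thresholds on net force and torque), `max_steps`,
#'   `min_scale` (smallest step-halving factor before the run is declared
#'   stalled).
#' @param seed integer random seed recorded in manifests.
#' @return A list of class `lrd_config`.
#' @export
run_config <- function(cutoff = 100,
                       dielectric = list(model = "linear", slope = 1, constant = 1),
                       temperature = 300,
                       solver = list(gamma = 0.2, tol = 1e-4, max_iter = 2000),
                       docking = list(step_t = 0.02, step_r = 0.005,
                                      max_t = 0.1, max_r = 0.02,
                                      f_tol = 0.5, tau_tol = 0.5,
                                      max_steps = 1000, min_scale = 1e-4),
                       seed = 1L) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  def <- list(cutoff = cutoff,
              dielectric = utils::modifyList(list(model = "linear", slope = 1, constant = 1),
                                             as.list(dielectric)),
              temperature = temperature,
              solver = utils::modifyList(list(gamma = 0.2, tol = 1e-4, max_iter = 2000),
                                         as.list(solver)),
              docking = utils::modifyList(list(step_t = 0.02, step_r = 0.005,
                                               max_t = 0.1, max_r = 0.02,
                                               f_tol = 0.5, tau_tol = 0.5,
                                               max_steps = 1000, min_scale = 1e-4),
                                          as.list(docking)),
              seed = as.integer(seed))
  if (!def$dielectric$model %in% c("linear", "constant")) {
    stop("dielectric model must be 'linear' or 'constant'")
  }
  class(def) <- c("lrd_config", "list")
  def
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; missing keys keep their
#' defaults.
#'
#' @param path YAML file.
#' @return An `lrd_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- run_config()
  merged <- utils::modifyList(unclass(base), y)
  do.call(run_config, merged[c("cutoff", "dielectric", "temperature",
                               "solver", "docking", "seed")])
}
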