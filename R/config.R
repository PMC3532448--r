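# Study configuration files: a YAML key-value file describing the cell,
# electrode, pulse, tissue profile, scan grid and search settings, so a
# whole stimulation experiment is reproducible from one text file.

#' Load a study configuration
#'
#' Reads a YAML configuration and materializes the package objects it
#' describes.  Recognized sections (all optional, with package defaults):
#' `cell` (arguments of [generate_rgc()] plus `axon_extension`),
#' `electrode` ([electrode_spec()]), `pulse` ([pulse_spec()]),
#' `inhomogeneity` ([inhomogeneity_profile()]), `scan` (`xlim`, `ylim`,
#' `step`, `z` for [scan_grid()]), `search` (`tol`, `cap`), `simulation`
#' ([sim_config()]) and `membrane` ([membrane_spec()]).
#'
#' @param path YAML file path
#' @return list with elements `cell`, `electrode`, `pulse`, `profile`,
#'   `grid`, `search`, `config` (simulation settings) and `spec`
#'   (membrane specification); absent sections yield NULL or defaults
#' @export
load_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  # YAML 1.1 would read the bare keys y/n as booleans; keep them literal
  keep_yn <- function(x)
    if (tolower(x) %in% c("y", "n")) x else tolower(x) %in% c("yes", "true", "on")
  cfg <- yaml::read_yaml(path, handlers = list("bool#yes" = keep_yn,
                                               "bool#no" = keep_yn))
  out <- list()

  out$cell <- if (!is.null(cfg$cell)) {
    ext <- cfg$cell$axon_extension %||% 900
    cfg$cell$axon_extension <- NULL
    extend_axon(do.call(generate_rgc, cfg$cell), ext)
  }
  out$electrode <- if (!is.null(cfg$electrode))
    do.call(electrode_spec, cfg$electrode)
  out$pulse <- if (!is.null(cfg$pulse)) do.call(pulse_spec, cfg$pulse)
  out$profile <- if (!is.null(cfg$inhomogeneity))
    do.call(inhomogeneity_profile, cfg$inhomogeneity)
  out$grid <- if (!is.null(cfg$scan))
    scan_grid(unlist(cfg$scan$xlim), unlist(cfg$scan$ylim),
              step = cfg$scan$step %||% 10, z = cfg$scan$z %||% 40)
  out$search <- list(tol = cfg$search$tol %||% 0.1,
                     cap = cfg$search$cap %||% 200)
  out$config <- if (!is.null(cfg$simulation))
    do.call(sim_config, cfg$simulation) else sim_config()
  out$spec <- if (!is.null(cfg$membrane))
    do.call(membrane_spec, cfg$membrane) else membrane_spec()
  out
}
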