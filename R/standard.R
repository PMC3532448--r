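# Study-condition cells: the synthetic stand-ins used throughout the
# analyses and tests.

#' Standard synthetic large-field RGC
#'
#' A large-field cell with a 191 um dendritic field (the Off-type study
#' condition; use 196 for the On-type), planar dendrites stratified below
#' the somatic plane, AIS centered 50 um from the somatic center, and the
#' axon linearly extended by 900 um so it runs well beyond the stimulation
#' test region.
#'
#' @param field_diameter dendritic field diameter, um
#' @param stratification_depth dendritic plane depth, um
#' @param seed RNG seed
#' @return `rgc_morphology`
#' @export
standard_rgc <- function(field_diameter = 191, stratification_depth = 15,
                         seed = 1) {
  extend_axon(generate_rgc(field_diameter,
                           stratification_depth = stratification_depth,
                           seed = seed), 900)
}

#' Standard synthetic midget RGC
#'
#' Small-field midget-type cell (dendritic span in the 5-100 um range) with
#' the same axonal layout and the 900 um axon extension.
#'
#' @param field_diameter dendritic field diameter, um
#' @param seed RNG seed
#' @return `rgc_morphology`
#' @export
standard_midget <- function(field_diameter = 50, seed = 1) {
  extend_axon(generate_rgc(field_diameter, stratification_depth = 10,
                           n_branches = 3, midget = TRUE, seed = seed), 900)
}
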