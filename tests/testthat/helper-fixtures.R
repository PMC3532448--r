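# Shared fixtures, built lazily and cached for the whole test run.  The
# "standard" cell is the study-condition large-field RGC (191 um field,
# 900 um axon extension); the "mini" cell is a smaller synthetic cell used
# where any excitable tree morphology will do and speed matters.

.fx <- new.env()

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

std_cell <- function() fx("std_cell", function() standard_rgc())
std_seg <- function() fx("std_seg", function() segmentize(std_cell()))
std_sys <- function() fx("std_sys", function() assemble(std_seg()))

mini_cell <- function() fx("mini_cell", function()
  extend_axon(generate_rgc(80, stratification_depth = 12, n_branches = 3,
                           seed = 4, axon_length = 150), 300))
mini_sys <- function() fx("mini_sys", function()
  assemble(segmentize(mini_cell())))

# passive membrane: leak only, raised so the length constant is a few
# hundred um (lambda = sqrt(a Rm / (2 Ra)))
passive_spec <- function(gl = 0.5) {
  spec <- membrane_spec()
  spec$regions[, c("gna", "gk", "ga", "gca", "gkca")] <- 0
  spec$regions$gl <- gl
  spec
}

# unbranched cable morphology: a small soma stub plus a straight axon of
# the given length and diameter along +x, with nodes every `node_step` um
straight_cable <- function(length_um, diam = 2, node_step = 24,
                           soma_diam = diam, type = 2L) {
  xs <- seq(node_step, length_um, by = node_step)
  if (tail(xs, 1) != length_um) xs <- c(xs, length_um)
  nodes <- data.frame(type = c(1L, rep(type, length(xs))),
                      x = c(0, xs), y = 0, z = 0,
                      r = c(soma_diam, rep(diam, length(xs))) / 2,
                      parent = c(0L, seq_along(xs)))
  morphology(nodes)
}

# soma-only patch morphology
soma_patch <- function(diam = 20) {
  morphology(data.frame(type = 1L, x = 0, y = 0, z = 0, r = diam / 2,
                        parent = 0L))
}

# brute-force threshold oracle: exhaustive upward linear scan in `step`
# increments; returns the first spiking amplitude
linear_scan_threshold <- function(sys, position, radius = 10, step = 0.025,
                                  start = step, cap = 20, z = 40) {
  electrode <- electrode_spec(radius, x = position[1], y = position[2], z = z)
  ve <- rgcstim:::ve_unit_factor(
    rgcstim:::compartment_midpoints(sys$seg), electrode)
  for (I in seq(start, cap, by = step)) {
    tr <- rgcstim:::probe_amplitude(sys, I, electrode, NULL, sim_config(),
                                    c(0, 0), ve_unit = ve)
    if (rgcstim:::trace_spiked(tr)) return(I)
  }
  NA_real_
}
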