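# Assembly and time integration of the compartmental cable equation on the
# morphology tree, with intracellular injection and per-compartment
# extracellular coupling.

#' Assemble the discretized cable system
#'
#' Builds the electrical quantities of the compartmental model: axial
#' conductances from the axial resistivity and compartment geometry
#' (half-cylinder resistances in series across each parent link), membrane
#' capacitance from area and Cm, and the region-resolved channel
#' conductances.  Boundary conditions are sealed ends.  The passive axial
#' operator is conservative: its row sums vanish, so a spatially uniform
#' extracellular potential drives no current.
#'
#' @param seg `rgc_segmented` cell
#' @param spec `membrane_spec`
#' @return object of class `cable_system`
#' @export
assemble <- function(seg, spec = membrane_spec()) {
  stopifnot(inherits(seg, "rgc_segmented"), inherits(spec, "membrane_spec"))
  comp <- seg$comp
  if (any(comp$len <= 0)) stop("zero-length compartment")
  if (any(comp$diam <= 0)) stop("zero-diameter compartment")
  n <- nrow(comp)
  area_cm2 <- comp$area * 1e-8
  # half-compartment axial resistance, Ohm: Ra (Ohm cm) * (L/2) / (pi r^2)
  len_cm <- comp$len * 1e-4
  rad_cm <- comp$diam / 2 * 1e-4
  r_half <- spec$ra * (len_cm / 2) / (pi * rad_cm^2)
  g_ax <- numeric(n)
  for (i in seq_len(n)[-1]) {
    p <- comp$parent[i]
    g_ax[i] <- 1000 / (r_half[i] + r_half[p]) # mS
  }
  ion <- list(ena = spec$ena, ek = spec$ek, el = spec$el,
              cao_mM = spec$cao_mM, ca_res_mM = spec$ca_res_mM,
              ca_tau_ms = spec$ca_tau_ms, ca_depth_um = spec$ca_depth_um,
              kca_kd_mM = spec$kca_kd_mM, rate_scale = spec$rate_scale,
              temp_C = spec$temp_C)
  structure(list(seg = seg, spec = spec,
                 parent0 = comp$parent - 1L, # 0-based, root -1
                 cap_uF = spec$cm * area_cm2,
                 g_ax = g_ax, area_cm2 = area_cm2,
                 gdens = conductance_matrix(seg, spec),
                 ion = ion,
                 soma = soma_compartment(seg),
                 cache = new.env(parent = emptyenv())),
            class = "cable_system")
}

#' @export
print.cable_system <- function(x, ...) {
  cat("Cable system:", length(x$cap_uF), "compartments, soma at index",
      x$soma, "\n")
  invisible(x)
}

#' Simulation configuration
#'
#' @param dt time step, ms (default 0.025)
#' @param duration simulated time, ms (default 40; use 500+ for intracellular
#'   injection protocols)
#' @param settle_ms stimulus-free settling run used to obtain the rest state
#'   before every protocol (the settled state is cached per system and step)
#' @param record compartment indices to record every step ("soma" = the soma
#'   compartment nearest the somatic center)
#' @param snapshot_times times (ms) at which to capture whole-cell Vm
#' @param stim_substeps fixed number of micro-steps used to integrate the
#'   steps in which the stimulus pulse is active (and the first step after
#'   it); the 0.1 ms pulse drives a stiff membrane transient that is
#'   resolved at dt/stim_substeps while the rest of the run keeps `dt`
#' @return object of class `sim_config`
#' @export
sim_config <- function(dt = 0.025, duration = 40, settle_ms = 200,
                       record = "soma", snapshot_times = numeric(0),
                       stim_substeps = 4) {
  if (dt <= 0) stop("dt must be positive")
  if (duration < dt) stop("duration must be >= dt")
  structure(list(dt = dt, duration = duration, settle_ms = settle_ms,
                 record = record, snapshot_times = snapshot_times,
                 stim_substeps = as.integer(stim_substeps)),
            class = "sim_config")
}

#' Rectangular intracellular current injection
#'
#' @param site compartment index (or "soma")
#' @param amplitude_pA current amplitude, pA
#' @param onset_ms onset, ms
#' @param duration_ms duration, ms (default 500, the calibration-protocol
#'   pulse length)
#' @return one-row data.frame; pass one or several (rbind) to [cable_run()]
#' @export
inject_current <- function(site, amplitude_pA, onset_ms = 0,
                           duration_ms = 500) {
  data.frame(site = I(list(site)), amp_pA = amplitude_pA,
             onset = onset_ms, dur = duration_ms)
}

# settled rest state, cached per (dt, settle_ms)
rest_state <- function(sys, dt, settle_ms) {
  key <- paste0("rest_", dt, "_", settle_ms)
  if (!is.null(sys$cache[[key]])) return(sys$cache[[key]])
  nst <- max(1L, round(settle_ms / dt))
  out <- run_cable_cpp(sys$parent0, sys$cap_uF, sys$g_ax, sys$area_cm2,
                       sys$gdens, sys$ion, dt, nst,
                       numeric(0), numeric(0),
                       matrix(numeric(0), 0, 4),
                       rep(sys$spec$el, length(sys$cap_uF)), NULL,
                       integer(0), integer(0), -1L, 0, 0, FALSE, 0L, 1L)
  sys$cache[[key]] <- out$state
  out$state
}

resolve_sites <- function(sys, sites) {
  if (is.character(sites))
    sites <- vapply(sites, function(s) {
      if (s == "soma") sys$soma else stop("unknown site label: ", s)
    }, integer(1))
  sites <- as.integer(sites)
  if (any(sites < 1 | sites > length(sys$cap_uF)))
    stop("record/injection site out of range")
  sites
}

#' Run a simulation
#'
#' Integrates the assembled cable system from its settled rest state.
#' Voltage advances by a Crank-Nicolson update solved in O(N) per step on
#' the tree; gates and the calcium pool advance by their exact exponential
#' relaxation.  The extracellular potential enters through the axial current
#' terms (currents flow down gradients of Vm + Ve), so a spatially uniform
#' Ve leaves the trace identical to no stimulus.
#'
#' @param sys `cable_system`
#' @param config `sim_config`
#' @param electrode optional `electrode_spec`
#' @param pulse optional `pulse_spec` (required with `electrode`)
#' @param profile optional `inhomogeneity_profile`
#' @param injections optional injection table from [inject_current()]
#' @param offset planar (x, y) offset of the cell relative to the electrode
#'   frame, um (used for mosaic cells)
#' @param stop_on_spike stop a few ms after the somatic spike threshold
#'   crossing (used by the threshold search)
#' @param extra_ms how long to keep integrating after that crossing
#' @param cross_min_ms crossings at or before this time are not counted as
#'   spikes (the threshold search sets it to the pulse offset, so the large
#'   passive membrane deflection driven directly by the field during the
#'   pulse is never mistaken for an action potential)
#' @param ve_unit optional explicit per-compartment field factor (mV/uA),
#'   overriding the electrode geometry (testing hook)
#' @return object of class `sim_trace`: time axis, recorded Vm, whole-cell
#'   snapshots, first 0 mV upward-crossing time per compartment, and the
#'   stimulus metadata
#' @export
cable_run <- function(sys, config = sim_config(), electrode = NULL,
                      pulse = NULL, profile = NULL, injections = NULL,
                      offset = c(0, 0), stop_on_spike = FALSE,
                      extra_ms = 2, cross_min_ms = 0, ve_unit = NULL) {
  stopifnot(inherits(sys, "cable_system"))
  dt <- config$dt
  nsteps <- round(config$duration / dt)
  rec <- resolve_sites(sys, config$record)

  stim_mid <- numeric(0)
  if (!is.null(ve_unit) || !is.null(electrode)) {
    if (is.null(pulse)) stop("an extracellular stimulus needs a pulse_spec")
    t_mid <- (seq_len(nsteps) - 0.5) * dt
    stim_mid <- pulse_current(pulse, t_mid)
    if (is.null(ve_unit))
      ve_unit <- ve_unit_factor(compartment_midpoints(sys$seg, offset),
                                electrode, profile)
    if (length(ve_unit) != length(sys$cap_uF))
      stop("ve_unit length must equal the number of compartments")
  } else ve_unit <- numeric(0)

  inj <- matrix(numeric(0), 0, 4)
  if (!is.null(injections) && nrow(injections) > 0) {
    sites <- vapply(injections$site, function(s) resolve_sites(sys, s),
                    integer(1))
    inj <- cbind(sites - 1L, injections$amp_pA * 1e-6,
                 injections$onset, injections$dur)
  }

  snap_steps <- sort(unique(pmax(round(config$snapshot_times / dt), 1L))) - 1L
  snap_steps <- snap_steps[snap_steps < nsteps]

  st0 <- rest_state(sys, dt, config$settle_ms)
  out <- run_cable_cpp(sys$parent0, sys$cap_uF, sys$g_ax, sys$area_cm2,
                       sys$gdens, sys$ion, dt, nsteps,
                       stim_mid, ve_unit, inj,
                       rep(sys$spec$el, length(sys$cap_uF)), st0,
                       rec - 1L, as.integer(snap_steps),
                       sys$soma - 1L, 0, cross_min_ms,
                       isTRUE(stop_on_spike), as.integer(round(extra_ms / dt)),
                       config$stim_substeps %||% 4L)

  vm <- out$vrec
  colnames(vm) <- paste0("c", rec)
  fc <- ifelse(out$first_cross < 0, NA_real_, (out$first_cross + 1) * dt)
  structure(list(time = out$t, vm = vm, record = rec,
                 snapshots = out$snaps, snapshot_times = out$snap_times,
                 first_cross_ms = fc, soma = sys$soma, dt = dt,
                 steps_done = out$steps_done,
                 stimulus = list(electrode = electrode, pulse = pulse,
                                 profile = profile, injections = injections,
                                 offset = offset),
                 final_state = out$state),
            class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat("Simulation trace:", length(x$time) - 1, "steps of", x$dt, "ms;",
      length(x$record), "recorded site(s)\n")
  sp <- detect_spikes(x)
  cat("  somatic spikes:", length(sp),
      if (length(sp)) paste("at", paste(signif(sp, 4), collapse = ", "), "ms")
      else "", "\n")
  invisible(x)
}

# recorded trace for one site as (time, v)
site_trace <- function(trace, site = trace$soma) {
  j <- match(site, trace$record)
  if (is.na(j)) stop("site ", site, " was not recorded")
  list(t = trace$time, v = trace$vm[, j])
}

#' Export a recorded single-site trace as CSV
#' @param trace `sim_trace`
#' @param path output file
#' @param site compartment index (default soma)
#' @return `path`, invisibly
#' @export
write_trace_csv <- function(trace, path, site = trace$soma) {
  tr <- site_trace(trace, site)
  utils::write.csv(data.frame(time_ms = tr$t, vm_mV = tr$v), path,
                   row.names = FALSE)
  invisible(path)
}

#' Mean inter-spike interval of a trace
#'
#' Mean of successive somatic spike-peak differences; flagged undefined
#' (NA with attribute) when the trace holds fewer than two spikes.
#' @param trace `sim_trace`
#' @param site recording site (default soma)
#' @return mean ISI, ms (NA if < 2 spikes)
#' @export
isi_curve <- function(trace, site = trace$soma) {
  peaks <- detect_spikes(trace, site)
  if (length(peaks) < 2) {
    out <- NA_real_
    attr(out, "n_spikes") <- length(peaks)
    return(out)
  }
  mean(diff(peaks))
}

#' Phase portrait of a recorded trace
#'
#' (Vm, dVm/dt) pairs with the derivative from centered finite differences.
#' @param trace `sim_trace`
#' @param site recording site (default soma)
#' @return data.frame with `v` (mV) and `dvdt` (mV/ms)
#' @export
phase_portrait <- function(trace, site = trace$soma) {
  tr <- site_trace(trace, site)
  n <- length(tr$v)
  if (n < 3) stop("trace too short for a phase portrait")
  dvdt <- (tr$v[3:n] - tr$v[1:(n - 2)]) / (tr$t[3:n] - tr$t[1:(n - 2)])
  data.frame(v = tr$v[2:(n - 1)], dvdt = dvdt)
}
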