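# Spike detection, response latency, binary-search threshold determination
# and 2-D threshold-map scans for single cells.

#' Detect somatic spikes in a trace
#'
#' A spike is an upward 0 mV crossing; the event time is the local Vm
#' maximum within the contiguous suprathreshold run that follows, so a
#' single excursion above 0 mV yields exactly one event.
#'
#' @param trace `sim_trace` (or a list with `t` and `v`)
#' @param site recording site (default soma)
#' @param threshold detection threshold, mV
#' @param window_from discard samples before this time, ms; a run already
#'   above threshold at the window start still counts as one event (its
#'   crossing merely happened earlier)
#' @return spike peak times, ms (possibly empty)
#' @export
detect_spikes <- function(trace, site = NULL, threshold = 0,
                          window_from = -Inf) {
  tr <- if (inherits(trace, "sim_trace"))
    site_trace(trace, site %||% trace$soma) else trace
  windowed <- is.finite(window_from) && window_from > tr$t[1]
  keep <- tr$t >= window_from
  v <- tr$v[keep]; t <- tr$t[keep]
  above <- v >= threshold
  if (!any(above)) return(numeric(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  # an event needs an upward crossing from below, except that a truncated
  # window may open mid-spike
  runs <- which(r$values & (starts > 1 | windowed))
  vapply(runs, function(k) {
    idx <- starts[k]:ends[k]
    t[idx[which.max(v[idx])]]
  }, numeric(1))
}

#' First-spike latency
#'
#' Duration between stimulus onset and the first action-potential peak.
#' @param onset_ms stimulus onset, ms
#' @param spikes spike peak times from [detect_spikes()]
#' @return latency, ms; NA (flagged) when no spike follows the onset
#' @export
spike_latency <- function(onset_ms, spikes) {
  spikes <- spikes[spikes >= onset_ms]
  if (!length(spikes)) {
    out <- NA_real_
    attr(out, "no_spike") <- TRUE
    return(out)
  }
  spikes[1] - onset_ms
}

# one stimulation probe: does amplitude I elicit a somatic spike?
# Returns the trace (integration stops shortly after the somatic crossing).
probe_amplitude <- function(sys, I, electrode, profile, config, offset,
                            ve_unit = NULL) {
  pulse <- pulse_spec(I, onset_ms = 1)
  # only crossings after the pulse offset count: during the pulse the field
  # drives a large passive membrane deflection that is not a spike
  cable_run(sys, config, electrode = electrode, pulse = pulse,
            profile = profile, offset = offset, stop_on_spike = TRUE,
            cross_min_ms = pulse$onset_ms + 2 * pulse$phase_ms,
            ve_unit = ve_unit)
}

trace_spiked <- function(trace) !is.na(trace$first_cross_ms[trace$soma])

# compartment where the 0 mV crossing happened first
initiation_site <- function(trace) {
  fc <- trace$first_cross_ms
  if (all(is.na(fc))) return(NA_integer_)
  which.min(fc)
}

#' Find the stimulation threshold at one electrode position
#'
#' Threshold is the minimum current of a charge-balanced cathodic-first
#' biphasic pulse (0.1 ms per phase) that evokes a somatic action potential
#' (0 mV crossing) within a 40 ms run.  A bracket is established by doubling
#' the amplitude from 1 uA up to `cap`; binary search then narrows it to
#' `tol` (0.1 uA for the 10 um electrode, 0.5 uA for larger sizes in the
#' study conditions).  The returned threshold is the spiking upper bracket,
#' so `threshold` spikes while `threshold - tol` does not.
#'
#' @param sys `cable_system`
#' @param position electrode center (x, y) in um, or an `electrode_spec`
#' @param radius electrode radius, um (ignored when `position` is an
#'   `electrode_spec`)
#' @param z electrode height above the somatic plane, um
#' @param tol search resolution, uA
#' @param cap maximum amplitude tried, uA; positions that fail to spike at
#'   the cap are reported not-excitable rather than raising an error
#' @param profile optional `inhomogeneity_profile`
#' @param config `sim_config` (40 ms runs by default)
#' @param offset planar cell offset, um
#' @return list with `threshold` (uA, NA when not excitable), `latency`
#'   (ms, first somatic peak after onset at threshold), `initiation`
#'   (compartment index of the earliest 0 mV crossing), `region` (its
#'   label), `excitable`, and the final bracket `lower`
#' @export
find_threshold <- function(sys, position, radius = 10, z = 40, tol = 0.1,
                           cap = 200, profile = NULL,
                           config = sim_config(), offset = c(0, 0)) {
  electrode <- if (inherits(position, "electrode_spec")) position
  else electrode_spec(radius, x = position[1], y = position[2], z = z)
  # spatial factor is amplitude-independent: compute once
  ve_unit <- ve_unit_factor(compartment_midpoints(sys$seg, offset),
                            electrode, profile)

  spikes_at <- function(I) {
    tr <- probe_amplitude(sys, I, electrode, profile, config, offset,
                          ve_unit = ve_unit)
    list(spiked = trace_spiked(tr), trace = tr)
  }

  lo <- 0; hi <- 1; hit <- NULL
  repeat {
    res <- spikes_at(hi)
    if (res$spiked) { hit <- res$trace; break }
    lo <- hi
    if (hi >= cap) break
    hi <- min(2 * hi, cap)
  }
  if (is.null(hit)) {
    return(list(threshold = NA_real_, latency = NA_real_,
                initiation = NA_integer_, region = NA_character_,
                excitable = FALSE, lower = lo))
  }
  while (hi - lo > tol) {
    mid <- (hi + lo) / 2
    res <- spikes_at(mid)
    if (res$spiked) { hi <- mid; hit <- res$trace } else lo <- mid
  }
  init <- initiation_site(hit)
  lat <- spike_latency(1, detect_spikes(hit, window_from = 1.2))
  list(threshold = hi, latency = as.numeric(lat), initiation = init,
       region = sys$seg$comp$region[init], excitable = TRUE, lower = lo)
}

#' Rectangular electrode scan grid
#'
#' @param xlim,ylim extents, um
#' @param step grid step, um (default 10, the study resolution)
#' @param z electrode height, um
#' @return data.frame of electrode positions (x, y, z)
#' @export
scan_grid <- function(xlim, ylim, step = 10, z = 40) {
  if (step <= 0) stop("grid step must be positive")
  g <- expand.grid(x = seq(xlim[1], xlim[2], by = step),
                   y = seq(ylim[1], ylim[2], by = step))
  g$z <- z
  g
}

# deterministic parallel map over rows; identical results for any worker
# count because tasks are independent and order is preserved
pmap_rows <- function(df, f, workers = 1) {
  idx <- seq_len(nrow(df))
  if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, function(i) f(df[i, ]), mc.cores = workers,
                       mc.preschedule = TRUE)
  } else lapply(idx, function(i) f(df[i, ]))
}

#' Map thresholds over a 2-D electrode scan
#'
#' Runs an independent [find_threshold()] at every grid position.  Results
#' are independent of evaluation order and worker count.
#'
#' @param sys `cable_system`
#' @param grid data.frame from [scan_grid()]
#' @param radius electrode radius, um
#' @param tol search resolution, uA
#' @param cap search cap, uA
#' @param profile optional `inhomogeneity_profile`
#' @param config `sim_config`
#' @param workers parallel workers (forked; 1 = serial)
#' @return data.frame: x, y, threshold (uA; NA where not excitable),
#'   latency (ms), initiation compartment and region
#' @export
threshold_map <- function(sys, grid, radius = 10, tol = 0.1, cap = 200,
                          profile = NULL, config = sim_config(),
                          workers = 1) {
  res <- pmap_rows(grid, function(row) {
    th <- find_threshold(sys, c(row$x, row$y), radius = radius, z = row$z,
                         tol = tol, cap = cap, profile = profile,
                         config = config)
    data.frame(x = row$x, y = row$y, threshold = th$threshold,
               latency = th$latency, initiation = th$initiation,
               region = th$region %||% NA_character_,
               excitable = th$excitable)
  }, workers = workers)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("threshold_map", class(out))
  out
}

#' AIS threshold of a cell
#'
#' Mean of three thresholds with the electrode centered above the proximal
#' end, mid-point and distal end of the axon initial segment.
#'
#' @param sys `cable_system`
#' @param radius electrode radius, um
#' @param z electrode height, um
#' @param tol,cap,profile,config as in [find_threshold()]
#' @return list with `threshold` (mean, uA), `per_site` (3 values) and the
#'   site positions
#' @export
ais_threshold <- function(sys, radius = 10, z = 40, tol = 0.1, cap = 200,
                          profile = NULL, config = sim_config()) {
  sites <- ais_sites(sys$seg)
  pos <- cbind(sys$seg$comp$x[sites], sys$seg$comp$y[sites])
  th <- vapply(seq_len(3), function(i) {
    find_threshold(sys, pos[i, ], radius = radius, z = z, tol = tol,
                   cap = cap, profile = profile, config = config)$threshold
  }, numeric(1))
  names(th) <- names(sites)
  list(threshold = mean(th), per_site = th,
       positions = data.frame(site = names(sites), x = pos[, 1],
                              y = pos[, 2]))
}
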