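# Mosaic-level stimulation: population thresholds, activated-cell counts
# and identities, and supra-threshold recruitment.  Cells are electrically
# independent and share the imposed extracellular field, so each cell is
# simulated on the shared template system with its own planar offset.
#
# Cells whose peak field magnitude (amplitude x max |Ve| unit factor) stays
# below VE_FLOOR_MV cannot possibly spike -- a spike from rest needs tens of
# millivolts of local drive -- so their simulations are skipped.  The bound
# is amplitude-dependent and deterministic, so results are unchanged.
VE_FLOOR_MV <- 2

# assembled template system for a mosaic
mosaic_system <- function(mos, spec = membrane_spec(), max_len = 12) {
  stopifnot(inherits(mos, "rgc_mosaic"))
  assemble(segmentize(mos$template, max_len), spec)
}

#' Cells activated by a stimulus over a mosaic
#'
#' Simulates every cell of the mosaic independently in the shared field of
#' the electrode for a 40 ms window; a cell is activated iff its somatic Vm
#' crosses 0 mV.
#'
#' @param mos `rgc_mosaic`
#' @param electrode `electrode_spec`
#' @param amplitude pulse amplitude, uA
#' @param sys assembled template system (built once per mosaic if omitted)
#' @param profile optional `inhomogeneity_profile`
#' @param config `sim_config`
#' @return data.frame of activated cells: id, first-spike latency (ms),
#'   spike-initiation compartment index and region label
#' @export
activated_cells <- function(mos, electrode, amplitude, sys = NULL,
                            profile = NULL, config = sim_config()) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  sys <- sys %||% mosaic_system(mos)
  empty <- data.frame(id = integer(0), latency = numeric(0),
                      initiation = integer(0), region = character(0))
  if (amplitude == 0) return(empty)
  rows <- lapply(seq_len(nrow(mos$cells)), function(i) {
    off <- c(mos$cells$x[i], mos$cells$y[i])
    ve <- ve_unit_factor(compartment_midpoints(sys$seg, off), electrode,
                         profile)
    if (amplitude * max(abs(ve)) < VE_FLOOR_MV) return(NULL)
    tr <- probe_amplitude(sys, amplitude, electrode, profile, config, off,
                          ve_unit = ve)
    if (!trace_spiked(tr)) return(NULL)
    init <- initiation_site(tr)
    data.frame(id = mos$cells$id[i],
               latency = as.numeric(spike_latency(1, detect_spikes(tr))),
               initiation = init, region = sys$seg$comp$region[init])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# does any cell spike at this amplitude? (cells scanned in id order with
# early exit; the predicate is deterministic)
any_activated <- function(mos, electrode, amplitude, sys, profile, config) {
  for (i in seq_len(nrow(mos$cells))) {
    off <- c(mos$cells$x[i], mos$cells$y[i])
    ve <- ve_unit_factor(compartment_midpoints(sys$seg, off), electrode,
                         profile)
    if (amplitude * max(abs(ve)) < VE_FLOOR_MV) next
    tr <- probe_amplitude(sys, amplitude, electrode, profile, config, off,
                          ve_unit = ve)
    if (trace_spiked(tr)) return(TRUE)
  }
  FALSE
}

#' Population threshold at one electrode position
#'
#' Minimum current that elicits a spike in one or more cells of the mosaic
#' (binary search on "any cell activated", the same bracketing as
#' [find_threshold()]).  Equals the minimum over per-cell thresholds to
#' within the search tolerance.
#'
#' @param mos `rgc_mosaic`
#' @param position electrode (x, y), um
#' @param radius electrode radius, um
#' @param z electrode height, um
#' @param tol search resolution, uA
#' @param cap search cap, uA
#' @param sys assembled template system (optional)
#' @param profile,config as elsewhere
#' @return list with `threshold` (uA; NA when no cell is excitable at the
#'   cap), `excitable`, and `lower` (final non-spiking bracket)
#' @export
population_threshold <- function(mos, position, radius = 10, z = 40,
                                 tol = 0.1, cap = 200, sys = NULL,
                                 profile = NULL, config = sim_config()) {
  if (nrow(mos$cells) == 0) stop("mosaic has no cells")
  sys <- sys %||% mosaic_system(mos)
  electrode <- electrode_spec(radius, x = position[1], y = position[2], z = z)
  lo <- 0; hi <- 1; found <- FALSE
  repeat {
    if (any_activated(mos, electrode, hi, sys, profile, config)) {
      found <- TRUE; break
    }
    lo <- hi
    if (hi >= cap) break
    hi <- min(2 * hi, cap)
  }
  if (!found)
    return(list(threshold = NA_real_, excitable = FALSE, lower = lo))
  while (hi - lo > tol) {
    mid <- (hi + lo) / 2
    if (any_activated(mos, electrode, mid, sys, profile, config)) hi <- mid
    else lo <- mid
  }
  list(threshold = hi, excitable = TRUE, lower = lo)
}

#' Population threshold, count and identity maps over a grid
#'
#' For every grid position: the population threshold, then the set of
#' activated cells at exactly that (spiking) amplitude.  Returns the map,
#' the histogram of activated-cell counts, and the identity map keyed by
#' the sorted tuple of activated cell ids.
#'
#' @param mos `rgc_mosaic`
#' @param grid data.frame from [scan_grid()]
#' @param radius electrode radius, um
#' @param tol,cap,profile,config as in [population_threshold()]
#' @param workers parallel workers
#' @return list with `map` (data.frame: x, y, threshold, n_active,
#'   identity, axon_dist), `histogram` (table of n_active) and the input
#'   metadata
#' @export
population_maps <- function(mos, grid, radius = 10, tol = 0.1, cap = 200,
                            profile = NULL, config = sim_config(),
                            workers = 1) {
  sys <- mosaic_system(mos)
  res <- pmap_rows(grid, function(row) {
    pos <- c(row$x, row$y)
    th <- population_threshold(mos, pos, radius = radius, z = row$z,
                               tol = tol, cap = cap, sys = sys,
                               profile = profile, config = config)
    if (!th$excitable)
      return(data.frame(x = row$x, y = row$y, threshold = NA_real_,
                        n_active = 0L, identity = NA_character_,
                        axon_dist = nearest_axon_distance(pos, mos)))
    electrode <- electrode_spec(radius, x = row$x, y = row$y, z = row$z)
    act <- activated_cells(mos, electrode, th$threshold, sys = sys,
                           profile = profile, config = config)
    data.frame(x = row$x, y = row$y, threshold = th$threshold,
               n_active = nrow(act),
               identity = paste(sort(act$id), collapse = "+"),
               axon_dist = nearest_axon_distance(pos, mos))
  }, workers = workers)
  map <- do.call(rbind, res)
  rownames(map) <- NULL
  list(map = map, histogram = table(map$n_active),
       radius = radius, tol = tol)
}

#' Supra-threshold recruitment sweep at one position
#'
#' Activated-cell sets at multiples (1-3x in the study conditions) of the
#' position's population threshold, with each cell's spike-initiation
#' region, so recruitment of distant cells via their passing axons is
#' visible in the labels.
#'
#' @param mos `rgc_mosaic`
#' @param position electrode (x, y), um
#' @param radius electrode radius, um
#' @param multipliers stimulus strengths as multiples of threshold
#' @param z,tol,cap,profile,config as elsewhere
#' @return object of class `recruitment_curve`: data.frame rows per
#'   multiplier with n_active, activated identity string and axon-initiated
#'   count, plus the per-multiplier activation tables in `details`
#' @export
suprathreshold_sweep <- function(mos, position, radius = 10,
                                 multipliers = c(1, 1.5, 2, 2.5, 3),
                                 z = 40, tol = 0.1, cap = 200,
                                 profile = NULL, config = sim_config()) {
  sys <- mosaic_system(mos)
  th <- population_threshold(mos, position, radius = radius, z = z,
                             tol = tol, cap = cap, sys = sys,
                             profile = profile, config = config)
  if (!th$excitable) stop("population threshold undefined at this position")
  electrode <- electrode_spec(radius, x = position[1], y = position[2], z = z)
  details <- lapply(multipliers, function(mult) {
    activated_cells(mos, electrode, mult * th$threshold, sys = sys,
                    profile = profile, config = config)
  })
  curve <- data.frame(
    multiplier = multipliers,
    amplitude = multipliers * th$threshold,
    n_active = vapply(details, nrow, integer(1)),
    identity = vapply(details, function(d) paste(sort(d$id), collapse = "+"),
                      character(1)),
    n_axon_initiated = vapply(details, function(d)
      sum(d$region %in% c("axon", "ais")), integer(1)))
  structure(list(threshold = th$threshold, position = position,
                 curve = curve, details = details),
            class = "recruitment_curve")
}

#' @export
print.recruitment_curve <- function(x, ...) {
  cat("Recruitment at (", paste(x$position, collapse = ", "),
      ") um; threshold", signif(x$threshold, 4), "uA\n")
  print(x$curve, row.names = FALSE)
  invisible(x)
}
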