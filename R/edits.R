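# Structural edits used in the single-cell threshold experiments.

#' Linearly extend the axon
#'
#' Appends a straight continuation of the terminal axon segment so that the
#' axon path length grows by exactly `length` um, with the terminal diameter
#' preserved.  Used to run the intraretinal axon well beyond the stimulation
#' test region (the study condition is a 900 um extension).
#'
#' @param m morphology with at least one axon section
#' @param length extension length, um (default 900)
#' @return edited `rgc_morphology`
#' @export
extend_axon <- function(m, length = 900) {
  if (length < 0) stop("extension length must be >= 0")
  if (length == 0) return(m)
  nd <- m$nodes
  ax <- which(nd$region %in% c("hillock", "ais", "axon"))
  if (!length(ax)) stop("morphology has no axon to extend")
  terminals <- ax[!(ax %in% nd$parent)]
  d <- path_distances(m)
  term <- terminals[which.max(d[terminals])]
  p <- nd$parent[term]
  u <- c(nd$x[term] - nd$x[p], nd$y[term] - nd$y[p], nd$z[term] - nd$z[p])
  u <- u / sqrt(sum(u^2))
  nd[nrow(nd) + 1L, ] <- list(SWC_AXON,
                              nd$x[term] + length * u[1],
                              nd$y[term] + length * u[2],
                              nd$z[term] + length * u[3],
                              nd$r[term], as.integer(term), NA)
  morphology(nd[, c("type", "x", "y", "z", "r", "parent")])
}

#' Remove the dendritic tree
#'
#' Deletes every dendrite-labelled section, leaving the soma and axon
#' untouched.  Used to test whether dendritic geometry contributes to the
#' AIS stimulation threshold.
#' @param m morphology
#' @return edited `rgc_morphology`
#' @export
edit_remove_dendrites <- function(m) {
  nd <- m$nodes
  keep <- which(nd$region != "dendrite")
  if (length(keep) == nrow(nd)) return(m)
  rank <- integer(nrow(nd)); rank[keep] <- seq_along(keep)
  out <- nd[keep, ]
  nz <- out$parent > 0L
  out$parent[nz] <- rank[out$parent[nz]]
  if (any(out$parent == 0L & seq_len(nrow(out)) != 1L))
    stop("dendrite removal disconnected the tree") # cannot happen: dendrite subtrees are dendritic
  morphology(out[, c("type", "x", "y", "z", "r", "parent")])
}

#' Shift the proximal axon along the electrode axis
#'
#' Translates all axon nodes within `first_len` um of axonal path (measured
#' from the soma surface, so the AIS is included) by `dz` um along z, with a
#' linear taper over the next `taper` um so the axon stays continuous.
#' Positive `dz` moves the proximal axon toward the vitreal electrode.
#'
#' @param m morphology
#' @param first_len axonal path length to shift, um (default 100)
#' @param dz z displacement, um
#' @param taper taper length beyond `first_len`, um
#' @return edited `rgc_morphology`
#' @export
edit_shift_proximal_axon <- function(m, first_len = 100, dz, taper = 20) {
  if (first_len <= 0) stop("first_len must be positive")
  if (dz == 0) return(m)
  nd <- m$nodes
  ax <- nd$region %in% c("hillock", "ais", "axon")
  s <- pmax(path_distances(m) - nd$r[1], 0) # axonal path from the soma surface
  w <- numeric(nrow(nd))
  w[ax & s <= first_len] <- 1
  tz <- ax & s > first_len & s <= first_len + taper
  w[tz] <- 1 - (s[tz] - first_len) / taper
  nd$z <- nd$z + dz * w
  morphology(nd[, c("type", "x", "y", "z", "r", "parent")])
}
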