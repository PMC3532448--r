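# Spatial discretization of a morphology into electrical compartments.

#' Discretize a morphology into compartments
#'
#' Splits every section into compartments shorter than `max_len` (the study
#' condition keeps every segment under 12 um so the cell samples the
#' extracellular potential at fine spatial granularity).  Each compartment
#' is a cylinder carrying the section diameter, so the per-section lateral
#' membrane area is conserved exactly under re-segmentation.  Axonal
#' compartments are relabelled (hillock / AIS / axon) from the path distance
#' of their midpoint, so the labels stay correct however coarsely the nodes
#' were placed.
#'
#' @param m `rgc_morphology`
#' @param max_len maximum compartment length, um (default 12)
#' @return object of class `rgc_segmented`: a list with `comp` (data.frame:
#'   parent index, region, length/diam um, area um^2, midpoint x/y/z, path
#'   distance from the somatic center) and the source morphology
#' @export
segmentize <- function(m, max_len = 12) {
  stopifnot(inherits(m, "rgc_morphology"))
  if (max_len <= 0) stop("max_len must be positive")
  nd <- m$nodes
  pd <- path_distances(m)
  n <- nrow(nd)

  comp <- list()
  k <- 0L
  add_comp <- function(parent, region, len, diam, mx, my, mz, path) {
    k <<- k + 1L
    comp[[k]] <<- list(parent = parent, region = region, len = len,
                       diam = diam, area = pi * diam * len,
                       x = mx, y = my, z = mz, path = path)
    k
  }

  # soma cylinder (length = diameter) lies along x, centered on the somatic
  # center; split like any other section
  d_soma <- 2 * nd$r[1]
  nseg <- max(1L, ceiling(d_soma / max_len))
  li <- d_soma / nseg
  soma_first <- NA_integer_
  prev <- 0L
  for (j in seq_len(nseg)) {
    mx <- nd$x[1] - d_soma / 2 + (j - 0.5) * li
    id <- add_comp(prev, "soma", li, d_soma, mx, nd$y[1], nd$z[1], 0)
    if (j == 1) soma_first <- id
    prev <- id
  }
  # neurite sections attach to the soma compartment containing the somatic
  # center, so the attachment point does not move under re-segmentation
  last_comp_of_node <- integer(n)
  last_comp_of_node[1] <- soma_first + (nseg - 1L) %/% 2L

  for (i in seq_len(n)[-1]) {
    p <- nd$parent[i]
    L <- pd[i] - pd[p]
    if (L <= 0) stop("zero-length section at node ", i)
    diam <- 2 * nd$r[i]
    if (diam <= 0) stop("zero-diameter section at node ", i)
    is_axon <- nd$type[i] == SWC_AXON
    # axon sections are cut exactly at the hillock/AIS boundaries so the
    # AIS span is independent of the segmentation granularity
    cuts <- c(0, 1)
    if (is_axon) {
      b <- (c(AIS_FROM, AIS_TO) - pd[p]) / L
      cuts <- sort(unique(c(0, b[b > 1e-9 & b < 1 - 1e-9], 1)))
    }
    prev <- last_comp_of_node[p]
    for (ci in seq_len(length(cuts) - 1)) {
      fa <- cuts[ci]; fb <- cuts[ci + 1]
      Ls <- (fb - fa) * L
      nseg <- max(1L, ceiling(Ls / max_len))
      li <- Ls / nseg
      for (j in seq_len(nseg)) {
        f <- fa + (j - 0.5) / nseg * (fb - fa)
        s_mid <- pd[p] + f * L
        region <- if (is_axon) {
          if (s_mid >= AIS_FROM && s_mid <= AIS_TO) "ais"
          else if (s_mid < AIS_FROM) "hillock" else "axon"
        } else nd$region[i]
        prev <- add_comp(prev, region, li, diam,
                         nd$x[p] + f * (nd$x[i] - nd$x[p]),
                         nd$y[p] + f * (nd$y[i] - nd$y[p]),
                         nd$z[p] + f * (nd$z[i] - nd$z[p]),
                         s_mid)
      }
    }
    last_comp_of_node[i] <- prev
  }

  comp <- do.call(rbind, lapply(comp, function(x)
    data.frame(x, stringsAsFactors = FALSE)))
  comp$parent <- as.integer(comp$parent)
  structure(list(comp = comp, morphology = m, max_len = max_len),
            class = "rgc_segmented")
}

#' @export
print.rgc_segmented <- function(x, ...) {
  tab <- table(x$comp$region)
  cat("Segmented cell:", nrow(x$comp), "compartments (max length",
      x$max_len, "um):\n  ",
      paste(names(tab), as.integer(tab), collapse = ", "), "\n")
  cat("  total membrane area:", signif(sum(x$comp$area), 5), "um^2\n")
  invisible(x)
}

# midpoints as an N x 3 matrix (um), optionally shifted in-plane
compartment_midpoints <- function(seg, offset = c(0, 0)) {
  cbind(seg$comp$x + offset[1], seg$comp$y + offset[2], seg$comp$z)
}

# index of the soma compartment nearest the somatic center
soma_compartment <- function(seg) {
  sc <- somatic_center(seg$morphology)
  i <- which(seg$comp$region == "soma")
  i[which.min(abs(seg$comp$x[i] - sc[1]))]
}

# proximal / mid / distal AIS compartment indices (by path distance)
ais_sites <- function(seg) {
  i <- which(seg$comp$region == "ais")
  if (!length(i)) stop("cell has no AIS-labelled compartments")
  s <- seg$comp$path[i]
  c(proximal = i[which.min(s)],
    mid = i[which.min(abs(s - (AIS_FROM + AIS_TO) / 2))],
    distal = i[which.max(s)])
}
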