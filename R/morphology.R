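#' @useDynLib rgcstim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm dist median
#' @importFrom utils read.table write.table read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# Morphology container
#
# A morphology is a rooted tree of tapered-cylinder sections held as an
# SWC-style node table: each non-root node defines one section running from
# its parent's coordinates to its own, with the node's radius.  The root is
# the soma, modelled as a cylinder whose length equals its diameter (same
# surface area as the equivalent sphere).  Units are micrometres throughout.
#
# Coordinate convention: the retina lies in the x-y plane, +z points toward
# the vitreous (the stimulating-electrode side), and the somatic center of
# the focal cell sits at the origin.
# ---------------------------------------------------------------------------

SWC_SOMA <- 1L
SWC_AXON <- 2L

# Path distances (from the somatic center) bounding the derived axonal
# region labels.  SWC has no code for the axon initial segment, so the
# hillock (first stretch of axon) and the AIS (high sodium-channel density,
# centered ~50 um from the somatic center with a 50 um span) are assigned by
# path distance; the AIS takes precedence where the nominal spans overlap.
AIS_FROM <- 25
AIS_TO <- 75

new_morphology <- function(nodes) {
  m <- structure(list(nodes = nodes), class = "rgc_morphology")
  m$nodes$region <- assign_regions(m)
  m
}

#' Construct a morphology from an SWC-style node table
#'
#' @param nodes data.frame with columns `type` (SWC integer code: 1 soma,
#'   2 axon, 3+ dendrite), `x`, `y`, `z`, `r` (radius, um) and `parent`
#'   (row index of the parent node; 0 for the single root). Nodes must be in
#'   topological order (parent before child).
#' @return An object of class `rgc_morphology`.
#' @export
morphology <- function(nodes) {
  stopifnot(is.data.frame(nodes),
            all(c("type", "x", "y", "z", "r", "parent") %in% names(nodes)))
  nodes <- nodes[, c("type", "x", "y", "z", "r", "parent")]
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  n <- nrow(nodes)
  roots <- which(nodes$parent == 0L)
  if (length(roots) != 1L)
    stop("morphology must have exactly one root node, found ", length(roots))
  if (roots != 1L)
    stop("root node must be the first row")
  if (nodes$type[1] != SWC_SOMA)
    stop("root node must be the soma (SWC type 1)")
  if (any(nodes$r <= 0))
    stop("all node radii must be positive")
  if (n > 1 && any(nodes$parent[-1] >= seq_len(n)[-1] | nodes$parent[-1] < 1L))
    stop("nodes must be topologically ordered with valid parent links")
  new_morphology(nodes)
}

#' @export
print.rgc_morphology <- function(x, ...) {
  tab <- table(x$nodes$region)
  cat("RGC morphology:", nrow(x$nodes), "nodes (",
      paste(names(tab), as.integer(tab), collapse = ", "), ")\n")
  cat("  somatic center: (", paste(signif(somatic_center(x), 4), collapse = ", "),
      ") um; soma diameter", 2 * x$nodes$r[1], "um\n")
  fd <- dendritic_field_diameter(x)
  if (fd > 0) cat("  dendritic field diameter:", signif(fd, 4), "um\n")
  al <- axon_path_length(x)
  if (al > 0) cat("  axon path length:", signif(al, 5), "um\n")
  invisible(x)
}

#' Somatic center of a morphology
#' @param m morphology
#' @return numeric xyz (um)
#' @export
somatic_center <- function(m) {
  unlist(m$nodes[1, c("x", "y", "z")], use.names = FALSE)
}

# Along-tree path distance (um) from the somatic center to every node.
path_distances <- function(m) {
  nd <- m$nodes
  n <- nrow(nd)
  d <- numeric(n)
  if (n == 1) return(d)
  for (i in 2:n) {
    p <- nd$parent[i]
    seg <- sqrt((nd$x[i] - nd$x[p])^2 + (nd$y[i] - nd$y[p])^2 +
                  (nd$z[i] - nd$z[p])^2)
    d[i] <- d[p] + seg
  }
  d
}

# Region labels from SWC type codes plus derived axonal sub-labels.
assign_regions <- function(m) {
  nd <- m$nodes
  region <- ifelse(nd$type == SWC_SOMA, "soma",
                   ifelse(nd$type == SWC_AXON, "axon", "dendrite"))
  ax <- which(region == "axon")
  if (length(ax)) {
    d <- path_distances(m)[ax]
    region[ax] <- ifelse(d >= AIS_FROM & d <= AIS_TO, "ais",
                         ifelse(d < AIS_FROM, "hillock", "axon"))
  }
  region
}

#' Dendritic field diameter
#'
#' Maximum pairwise in-plane (x-y) distance across the dendritic nodes; the
#' standard measure of the extent of the dendritic tree.
#' @param m morphology
#' @return diameter in um (0 if the cell has no dendrites)
#' @export
dendritic_field_diameter <- function(m) {
  dn <- m$nodes[m$nodes$region == "dendrite", c("x", "y")]
  if (nrow(dn) < 2) return(0)
  max(stats::dist(as.matrix(dn)))
}

axon_path_length <- function(m) {
  ax <- m$nodes$region %in% c("hillock", "ais", "axon")
  if (!any(ax)) return(0)
  max(path_distances(m)[ax])
}

# ---------------------------------------------------------------------------
# SWC input/output (standard 7-column dialect)
# ---------------------------------------------------------------------------

#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC: id, type, x, y, z, radius, parent (parent -1 for
#' the root).  Type codes are mapped 1 = soma, 2 = axon, anything else =
#' dendrite; hillock and AIS labels are derived from path distance.
#' @param path file path
#' @return `rgc_morphology`
#' @examples
#' swc <- system.file("extdata", "synthetic_rgc_example.swc",
#'                    package = "rgcstim")
#' m <- read_swc(swc)
#' dendritic_field_diameter(m)
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  raw <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z", "r",
                                         "parent"))
  if (nrow(raw) == 0) stop("empty SWC file: ", path)
  ids <- raw$id
  if (anyDuplicated(ids)) stop("duplicate node ids in SWC file")
  idx <- match(raw$parent, ids)
  root <- which(raw$parent == -1)
  if (length(root) != 1)
    stop("SWC file must contain exactly one root (parent -1)")
  if (any(is.na(idx[-root])))
    stop("SWC parent id referenced but never defined")
  parent <- idx
  parent[root] <- 0L
  # topological re-order (also detects cycles); a file already in
  # topological order is kept as-is so round trips preserve node order
  ord <- swc_topo_order(parent, root)
  if (root == 1L && all(parent[-1] < seq_along(parent)[-1]))
    ord <- seq_along(parent)
  rank <- integer(nrow(raw)); rank[ord] <- seq_along(ord)
  par_new <- parent[ord]
  nz <- par_new > 0L
  par_new[nz] <- rank[par_new[nz]]
  nodes <- data.frame(type = as.integer(raw$type[ord]),
                      x = raw$x[ord], y = raw$y[ord], z = raw$z[ord],
                      r = raw$r[ord], parent = par_new)
  morphology(nodes)
}

swc_topo_order <- function(parent, root) {
  n <- length(parent)
  children <- split(seq_len(n), parent)
  ord <- integer(n); ord[1] <- root
  k <- 1L; head_ <- 1L
  while (head_ <= k) {
    ch <- children[[as.character(ord[head_])]]
    if (!is.null(ch)) {
      ord[(k + 1):(k + length(ch))] <- ch
      k <- k + length(ch)
    }
    head_ <- head_ + 1L
  }
  if (k != n) stop("SWC parent links contain a cycle or unreachable nodes")
  ord
}

#' Write a morphology to an SWC file
#'
#' @param m morphology
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_swc <- function(m, path) {
  nd <- m$nodes
  type <- ifelse(nd$region == "soma", 1L,
                 ifelse(nd$region == "dendrite", 3L, 2L))
  out <- data.frame(id = seq_len(nrow(nd)), type = type,
                    x = nd$x, y = nd$y, z = nd$z, r = nd$r,
                    parent = ifelse(nd$parent == 0L, -1L, nd$parent))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC export (rgcstim)", con)
  utils::write.table(format(out, digits = 12, trim = TRUE, scientific = FALSE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Soma as a cylinder
# ---------------------------------------------------------------------------

#' Soma cylinder specification
#'
#' The soma is modelled as a cylinder with length equal to its diameter: the
#' lateral area pi d^2 then equals the surface area of the sphere with the
#' same diameter, so the somatic membrane area is conserved.
#' @param diameter soma diameter, um
#' @return list with `diameter`, `length` and `lateral_area` (um^2)
#' @export
soma_cylinder <- function(diameter) {
  if (!is.numeric(diameter) || length(diameter) != 1 || diameter <= 0)
    stop("soma diameter must be a positive scalar")
  list(diameter = diameter, length = diameter,
       lateral_area = pi * diameter^2)
}

# ---------------------------------------------------------------------------
# Synthetic RGC generator
# ---------------------------------------------------------------------------

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic retinal ganglion cell morphology
#'
#' Parametric stand-in for traced RGCs.  The cell has a cylindrical soma at
#' the origin, an axon running in the retinal plane along +x (with hillock
#' and AIS labelled by path distance), and a planar dendritic tree grown by
#' recursive bifurcation at the requested stratification depth (below the
#' somatic plane, away from the vitreous).  Branch angles and radii are
#' lightly jittered; a fixed seed makes the cell fully reproducible.
#'
#' @param field_diameter requested dendritic field diameter, um (e.g. 191 or
#'   196 for large-field mouse RGCs; 5-100 for midget cells)
#' @param stratification_depth depth of the dendritic plane below the somatic
#'   plane, um
#' @param n_branches number of primary dendrites
#' @param midget logical; midget-style cell (smaller soma, compact tree)
#' @param seed RNG seed
#' @param soma_diameter soma diameter, um
#' @param axon_length initial axon path length, um (use [extend_axon()] for
#'   the long intraretinal axon)
#' @return `rgc_morphology`
#' @export
generate_rgc <- function(field_diameter, stratification_depth = 15,
                         n_branches = 4, midget = FALSE, seed = 1,
                         soma_diameter = if (midget) 10 else 20,
                         axon_length = 200) {
  if (!is.numeric(field_diameter) || field_diameter <= 0)
    stop("field_diameter must be positive")
  if (field_diameter <= soma_diameter)
    stop("field_diameter must exceed the soma diameter")
  with_seed(seed, {
    rs <- soma_diameter / 2
    nodes <- data.frame(type = SWC_SOMA, x = 0, y = 0, z = 0, r = rs,
                        parent = 0L)
    add <- function(type, x, y, z, r, parent) {
      nodes[nrow(nodes) + 1L, ] <<- list(as.integer(type), x, y, z, r,
                                         as.integer(parent))
      nrow(nodes)
    }
    # --- axon along +x in the somatic plane (z = 0), nodes every ~10 um
    # near the soma so the proximal-axon edits resolve smoothly
    ax_s <- unique(c(seq(rs + 2.5, min(150, axon_length), by = 10),
                     if (axon_length > 150) seq(160, axon_length, by = 20),
                     axon_length))
    ax_s <- sort(ax_s[ax_s <= axon_length])
    prev <- 1L
    for (s in ax_s) {
      diam <- 1 + max(0, (40 - s) / 40) # hillock taper 2 -> 1 um
      prev <- add(SWC_AXON, s, 0, 0, diam / 2, prev)
    }
    # --- dendritic tree at z = -stratification_depth
    # Primary dendrites leave the soma, descend to the stratification plane
    # and bifurcate recursively; tips sit at the requested field radius so
    # the measured field diameter tracks the request.
    R <- field_diameter / 2
    zd <- -stratification_depth
    levels <- if (midget || R < 30) c(0.5, 1) else c(0.3, 0.65, 1)
    diams <- c(2, 1.2, 0.7, 0.5)
    grow <- function(parent, theta, level) {
      r_here <- levels[level] * R
      diam <- diams[min(level, length(diams))]
      id <- add(3L, r_here * cos(theta), r_here * sin(theta), zd,
                diam / 2, parent)
      if (level < length(levels)) {
        spread <- (0.9 / n_branches) / level
        grow(id, theta + spread + stats::rnorm(1, 0, 0.03), level + 1L)
        grow(id, theta - spread + stats::rnorm(1, 0, 0.03), level + 1L)
      }
    }
    for (k in seq_len(n_branches)) {
      theta <- 2 * pi * (k - 1) / n_branches + pi / n_branches +
        stats::rnorm(1, 0, 0.08)
      grow(1L, theta, 1L)
    }
    morphology(nodes)
  })
}
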