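#' Synthetic branched dendritic morphology
#'
#' Builds an idealised CA1-pyramidal-like morphology: a spherical soma at the
#' root, a tapering apical trunk, and oblique side branches attached at regular
#' intervals. The tree follows the SWC convention (one sample per node, each
#' node pointing to its parent) so it round-trips through [write_swc()] /
#' [read_swc()] and can be replaced by any reconstructed cell in SWC format.
#'
#' The trunk must reach at least 350 micrometres so that synapse populations
#' can be placed over the full 40--350 micrometre path-distance range used by
#' the simulation experiments.
#'
#' @param trunk_length Apical trunk length in micrometres (>= 350).
#' @param n_obliques Number of oblique side branches (>= 0).
#' @param oblique_spacing Spacing between successive oblique origins along the
#'   trunk, micrometres. The first oblique attaches at 60 micrometres.
#' @param oblique_length Length of each oblique branch, micrometres.
#' @param n_basal Number of basal dendrites leaving the soma (the basal tree
#'   loads the soma electrotonically like the real cell's s. oriens arbor).
#' @param basal_length Length of each basal dendrite, micrometres.
#' @param diameters Named list of diameters in micrometres: `soma` (sphere
#'   diameter), `trunk` (length-2, base and tip; linear taper), `oblique`
#'   (length-2, base and tip), `basal` (length-2, base and tip).
#' @param node_step Spacing of SWC sample points along neurites, micrometres.
#' @param seed Optional integer; adds reproducible small jitter to oblique
#'   branch angles. `NULL` gives a deterministic layout.
#' @return An object of class `dendrite_morphology`: a list with element
#'   `nodes`, a data frame with SWC columns `id, type, x, y, z, radius,
#'   parent` (micrometres; `parent = -1` for the root).
#' @examples
#' m <- generate_morphology(trunk_length = 400, n_obliques = 4)
#' max(path_distances(m))
#' @export
generate_morphology <- function(trunk_length = 500,
                                n_obliques = 12,
                                oblique_spacing = 30,
                                oblique_length = 220,
                                n_basal = 8,
                                basal_length = 250,
                                diameters = list(soma = 20,
                                                 trunk = c(3.0, 2.0),
                                                 oblique = c(1.0, 0.5),
                                                 basal = c(2.0, 0.5)),
                                node_step = 10,
                                seed = NULL) {
  if (trunk_length < 350)
    stop("trunk_length must be >= 350 um so synapses can be placed up to 350 um")
  if (n_obliques < 0) stop("n_obliques must be non-negative")
  d <- unlist(diameters)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("all diameters must be positive and finite")
  if (node_step <= 0) stop("node_step must be positive")

  if (!is.null(seed)) {
    old <- .Random.seed_exists()
    set.seed(as.integer(seed))
    on.exit(old(), add = TRUE)
  }

  soma_r <- diameters$soma / 2
  nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                      radius = soma_r, parent = -1L)

  # apical trunk along +y, linear taper
  ty <- seq(node_step, trunk_length, by = node_step)
  if (ty[length(ty)] < trunk_length) ty <- c(ty, trunk_length)
  tr <- diameters$trunk / 2
  trunk_radius <- tr[1] + (tr[2] - tr[1]) * ty / trunk_length
  trunk_ids <- seq_along(ty) + 1L
  nodes <- rbind(nodes, data.frame(
    id = trunk_ids, type = 4L, x = 0, y = ty, z = 0,
    radius = trunk_radius,
    parent = c(1L, trunk_ids[-length(trunk_ids)])))

  # oblique branches, alternating sides, slight distal tilt
  if (n_obliques > 0) {
    orr <- diameters$oblique / 2
    origins <- 60 + oblique_spacing * (seq_len(n_obliques) - 1)
    origins <- origins[origins < trunk_length - node_step]
    for (k in seq_along(origins)) {
      o <- origins[k]
      attach_id <- trunk_ids[which.min(abs(ty - o))]
      attach <- nodes[nodes$id == attach_id, ]
      side <- if (k %% 2 == 1) 1 else -1
      ang <- pi / 5 + if (is.null(seed)) 0 else stats::runif(1, -pi / 20, pi / 20)
      ux <- side * cos(ang); uy <- sin(ang)
      s <- seq(node_step, oblique_length, by = node_step)
      if (s[length(s)] < oblique_length) s <- c(s, oblique_length)
      rad <- orr[1] + (orr[2] - orr[1]) * s / oblique_length
      ids <- max(nodes$id) + seq_along(s)
      nodes <- rbind(nodes, data.frame(
        id = ids, type = 4L, x = attach$x + ux * s, y = attach$y + uy * s,
        z = 0, radius = rad,
        parent = c(attach_id, ids[-length(ids)])))
    }
  }

  # basal dendrites (type 3), fanning out below the soma
  if (n_basal > 0) {
    br <- diameters$basal / 2
    for (k in seq_len(n_basal)) {
      ang <- -pi / 2 + (k - (n_basal + 1) / 2) * (pi / (n_basal + 1))
      ux <- cos(ang); uy <- sin(ang)
      s <- seq(node_step, basal_length, by = node_step)
      if (s[length(s)] < basal_length) s <- c(s, basal_length)
      rad <- br[1] + (br[2] - br[1]) * s / basal_length
      ids <- max(nodes$id) + seq_along(s)
      nodes <- rbind(nodes, data.frame(
        id = ids, type = 3L, x = ux * s, y = uy * s, z = 0,
        radius = rad, parent = c(1L, ids[-length(ids)])))
    }
  }
  rownames(nodes) <- NULL
  structure(list(nodes = nodes), class = "dendrite_morphology")
}

# restore-RNG helper: returns a closure undoing set.seed side effects
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }
}

#' @export
print.dendrite_morphology <- function(x, ...) {
  n <- x$nodes
  cat("dendrite_morphology:", nrow(n), "SWC nodes,",
      sum(n$parent == -1L), "root\n")
  cat("  max path distance:", round(max(path_distances(x)), 1), "um\n")
  invisible(x)
}

#' Validate a morphology object
#'
#' Checks the SWC invariants: a single root, acyclic parent pointers, strictly
#' positive radii, and parents defined before use.
#'
#' @param morph A `dendrite_morphology`.
#' @return Invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_morphology <- function(morph) {
  n <- morph$nodes
  stopifnot(is.data.frame(n))
  if (sum(n$parent == -1L) != 1L) stop("morphology must have exactly one root")
  if (any(n$radius <= 0)) stop("all radii must be positive")
  if (anyDuplicated(n$id)) stop("duplicate SWC ids")
  idx <- match(n$parent, n$id)
  bad <- n$parent != -1L & is.na(idx)
  if (any(bad)) stop("parent ids must reference existing nodes")
  # acyclic: walking to the root from every node must terminate
  for (i in seq_len(nrow(n))) {
    seen <- integer(0); j <- i
    while (n$parent[j] != -1L) {
      if (j %in% seen) stop("cycle detected in parent pointers")
      seen <- c(seen, j)
      j <- idx[j]
    }
  }
  invisible(TRUE)
}

#' Path distance from the soma for every node
#'
#' Curvilinear (along-the-tree) distance from the root node to each SWC node,
#' in micrometres. Distances are additive along parent links, so they are
#' monotone non-decreasing along any root-to-tip path.
#'
#' @param morph A `dendrite_morphology`.
#' @return Numeric vector, one entry per node, in node order.
#' @export
path_distances <- function(morph) {
  n <- morph$nodes
  idx <- match(n$parent, n$id)
  d <- rep(NA_real_, nrow(n))
  d[n$parent == -1L] <- 0
  # nodes are not guaranteed topologically sorted after reading SWC
  remaining <- which(is.na(d))
  while (length(remaining)) {
    ready <- remaining[!is.na(d[idx[remaining]])]
    if (!length(ready)) stop("disconnected morphology")
    p <- idx[ready]
    seg <- sqrt((n$x[ready] - n$x[p])^2 + (n$y[ready] - n$y[p])^2 +
                  (n$z[ready] - n$z[p])^2)
    d[ready] <- d[p] + seg
    remaining <- setdiff(remaining, ready)
  }
  d
}

#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC: `id type x y z radius parent`, `#` comments allowed.
#'
#' @param path Path to an SWC file.
#' @return A `dendrite_morphology`.
#' @export
read_swc <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  tab$id <- as.integer(tab$id)
  tab$type <- as.integer(tab$type)
  tab$parent <- as.integer(tab$parent)
  m <- structure(list(nodes = tab), class = "dendrite_morphology")
  validate_morphology(m)
  m
}

#' Write a morphology to an SWC file
#'
#' @param morph A `dendrite_morphology`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_swc <- function(morph, path) {
  n <- morph$nodes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC generated by synaptrend", con)
  utils::write.table(format(n, scientific = FALSE, trim = TRUE), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
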