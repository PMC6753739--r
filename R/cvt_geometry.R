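#' Phantom design specification
#'
#' Collects the design parameters of a Voronoi-branch lung phantom: a cube
#' of printable resin branches whose bulk density matches an average adult
#' lung. Defaults follow the printed design: 4 cm cube, resin density
#' 1.11 g/cm^3, target bulk density 0.237 g/cm^3, branch diameters
#' 0.4--0.8 mm with joints up to 1.6 mm in diameter.
#'
#' @param cube_edge Cube edge length (cm).
#' @param n_points Number of Voronoi generating points. Not a free texture
#'   knob: the printed branch-diameter range and the target density jointly
#'   fix the total branch length the skeleton must supply (about
#'   4.7e3 cm here), and through the CVT edge-length law
#'   `L ~ 5.6 n^(2/3) V^(1/3)` that fixes the point count. The default 3000
#'   keeps the density-tuned diameters inside the printable 0.4--0.8 mm
#'   range (mean cell spacing about 2.8 mm).
#' @param seed Integer seed driving all stochastic design steps.
#' @param target_density Target bulk density (g/cm^3).
#' @param material_density Printing-material density (g/cm^3).
#' @param branch_diameter_range Branch diameter range (mm).
#' @param joint_diameter_max Maximum joint diameter (mm).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(cube_edge = 4, n_points = 3000, seed = 1,
                         target_density = 0.237, material_density = 1.11,
                         branch_diameter_range = c(0.4, 0.8),
                         joint_diameter_max = 1.6) {
  stopifnot(cube_edge > 0, n_points >= 1,
            target_density > 0, target_density < material_density,
            length(branch_diameter_range) == 2L,
            all(branch_diameter_range > 0),
            branch_diameter_range[1] <= branch_diameter_range[2],
            joint_diameter_max >= branch_diameter_range[2])
  structure(list(cube_edge = cube_edge, n_points = as.integer(n_points),
                 seed = as.integer(seed),
                 target_density = target_density,
                 material_density = material_density,
                 branch_diameter_range = branch_diameter_range,
                 joint_diameter_max = joint_diameter_max),
            class = "phantom_spec")
}

#' Poisson-disk sample of generating points in the cube
#'
#' Dart throwing: uniform candidate points are accepted only if they keep at
#' least the Poisson-disk radius `r_pd = r_factor * (V / n)^(1/3)` from all
#' previously accepted points. The blue-noise spacing keeps the initial
#' tessellation free of clustered generators before Lloyd relaxation.
#'
#' @param spec A [phantom_spec()].
#' @param r_factor Spacing factor relative to the mean point spacing
#'   `(V/n)^(1/3)`; the default 0.75 leaves dart throwing a comfortable
#'   feasibility margin.
#' @param max_attempts_per_point Dart budget per requested point.
#' @return An object of class `point_set`: list with `points` (n x 3 matrix,
#'   cm), `r_pd` (cm), `seed`.
#' @export
sample_poisson_disk <- function(spec, r_factor = 0.75,
                                max_attempts_per_point = 200L) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_points
  L <- spec$cube_edge
  r_pd <- r_factor * (L^3 / n)^(1 / 3)
  set.seed(spec$seed)
  pts <- matrix(NA_real_, n, 3L)
  accepted <- 0L
  attempts <- 0L
  budget <- max_attempts_per_point * n
  while (accepted < n && attempts < budget) {
    attempts <- attempts + 1L
    cand <- stats::runif(3L, 0, L)
    if (accepted > 0L) {
      d2 <- (pts[seq_len(accepted), 1L] - cand[1L])^2 +
            (pts[seq_len(accepted), 2L] - cand[2L])^2 +
            (pts[seq_len(accepted), 3L] - cand[3L])^2
      if (min(d2) < r_pd^2) next
    }
    accepted <- accepted + 1L
    pts[accepted, ] <- cand
  }
  if (accepted < ceiling(0.9 * n)) {
    stop(sprintf(
      "Poisson-disk sampling unsatisfiable: placed %d of %d points at r_pd = %.3f cm",
      accepted, n, r_pd))
  }
  structure(list(points = pts[seq_len(accepted), , drop = FALSE],
                 r_pd = r_pd, cube_edge = L, seed = spec$seed),
            class = "point_set")
}

#' Lloyd relaxation towards a centroidal Voronoi tessellation
#'
#' Iteratively replaces each generating point by the centroid of its Voronoi
#' cell clipped to the cube. Centroids are estimated on a fixed uniform
#' Monte Carlo sample cloud (drawn once per call from `sample_seed`), which
#' makes each iteration an exact Lloyd/k-means step on that cloud: the
#' quantization energy recorded in the trace is guaranteed non-increasing.
#'
#' @param points A [point_set()] (or the result of a previous relaxation).
#' @param iterations Maximum number of Lloyd iterations.
#' @param tolerance Stop when the maximum point movement (cm) falls below
#'   this value.
#' @param n_samples Size of the fixed sample cloud used for centroid
#'   estimation.
#' @param sample_seed Seed for the sample cloud; defaults to the point set's
#'   own seed offset by one.
#' @return A `point_set` with an added `energy_trace` attribute (mean squared
#'   sample-to-generator distance per iteration, cm^2).
#' @export
lloyd_relax <- function(points, iterations = 30L, tolerance = 1e-3,
                        n_samples = 1e5, sample_seed = points$seed + 1L) {
  stopifnot(inherits(points, "point_set"))
  pts <- points$points
  if (nrow(pts) < 1L) stop("empty point set")
  if (nrow(pts) > 1L) {
    dmin <- min(stats::dist(pts))
    if (dmin < 1e-12) stop("degenerate input: coincident generating points")
  }
  L <- points$cube_edge
  set.seed(sample_seed)
  samples <- matrix(stats::runif(3 * n_samples, 0, L), ncol = 3L)
  energy <- numeric(0)
  for (it in seq_len(iterations)) {
    step <- cpp_lloyd_step(samples, pts)
    energy <- c(energy, step$energy)
    moved <- sqrt(rowSums((step$centers - pts)^2))
    pts <- step$centers
    if (max(moved) < tolerance) break
  }
  out <- points
  out$points <- pts
  attr(out, "energy_trace") <- energy
  out
}

#' CVT quantization energy estimated by Monte Carlo integration
#'
#' Independent dense-sampling estimate of the energy
#' `sum_i integral over cell_i of |x - g_i|^2 dx / V`: mean squared distance
#' from a uniform point in the cube to its nearest generator. Used to
#' cross-check the energy trace reported by [lloyd_relax()].
#'
#' @param points A [point_set()].
#' @param n_samples Monte Carlo sample count.
#' @param seed Integer seed.
#' @return Mean squared distance (cm^2).
#' @export
cvt_energy <- function(points, n_samples = 2e5, seed = 99L) {
  stopifnot(inherits(points, "point_set"))
  set.seed(seed)
  s <- matrix(stats::runif(3 * n_samples, 0, points$cube_edge), ncol = 3L)
  idx <- cpp_nearest_index(s, points$points)
  mean(rowSums((s - points$points[idx, , drop = FALSE])^2))
}

#' Extract the Voronoi edge skeleton clipped to the cube
#'
#' Builds the Voronoi diagram of the generating points, clips it to the
#' cube, and returns its 1D edge skeleton as a branch network: the segments
#' where three cells meet (triple lines), cut at the cube faces with a
#' boundary node inserted where they exit. Optionally
#' (`include_surface = TRUE`) the traces of clipped Voronoi faces on the
#' cube surface are kept too; the default excludes them -- the skeleton
#' alone is the branch structure, and surface traces on the beam-parallel
#' faces would add long beam-aligned material runs. Only the largest
#' connected component is retained -- a disconnected fragment would be
#' unprintable.
#'
#' @param points A [point_set()] with at least 5 points.
#' @param spec A [phantom_spec()].
#' @param include_surface Keep cube-face traces of clipped Voronoi faces.
#' @param k_neighbors Bisector candidates per cell for the plane-intersection
#'   construction; must exceed the true neighbour count of every cell.
#' @return An object of class `branch_network`: `nodes` (m x 3, cm), `edges`
#'   (e x 2 node indices), `edge_radius` / `node_radius` (mm, `NA` until
#'   [assign_radii()]), plus the generating `spec`.
#' @export
build_voronoi_edges <- function(points, spec,
                                include_surface = FALSE,
                                k_neighbors = 45L) {
  stopifnot(inherits(points, "point_set"), inherits(spec, "phantom_spec"))
  pts <- points$points
  if (nrow(pts) < 5L) stop("need at least 5 generating points for a 3D tessellation")
  raw <- cpp_voronoi_cell_edges(pts, points$cube_edge,
                                as.integer(min(k_neighbors, nrow(pts) - 1L)))
  if (nrow(raw) == 0L) stop("tessellation failure: no Voronoi edges found")
  keep <- if (include_surface) raw[, "nbis"] >= 1 else raw[, "nbis"] == 2
  raw <- raw[keep, , drop = FALSE]
  .network_from_segments(raw[, 1:3, drop = FALSE], raw[, 4:6, drop = FALSE],
                         spec)
}

# Deduplicate segment soup into a node/edge network and keep the largest
# connected component.
.network_from_segments <- function(p0, p1, spec, digits = 7L) {
  key <- function(m) paste(round(m[, 1L], digits), round(m[, 2L], digits),
                           round(m[, 3L], digits), sep = ",")
  k0 <- key(p0); k1 <- key(p1)
  all_keys <- unique(c(k0, k1))
  id0 <- match(k0, all_keys); id1 <- match(k1, all_keys)
  coords <- rbind(p0, p1)[match(all_keys, c(k0, k1)), , drop = FALSE]
  e <- cbind(pmin(id0, id1), pmax(id0, id1))
  e <- e[e[, 1L] != e[, 2L], , drop = FALSE]
  e <- unique(e)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  in_main <- which(comp$membership == main)
  keep_e <- comp$membership[e[, 1L]] == main
  e <- e[keep_e, , drop = FALSE]
  remap <- match(seq_len(nrow(coords)), in_main)
  e <- cbind(remap[e[, 1L]], remap[e[, 2L]])
  nodes <- coords[in_main, , drop = FALSE]
  structure(list(nodes = nodes, edges = e,
                 edge_radius = rep(NA_real_, nrow(e)),
                 node_radius = rep(NA_real_, nrow(nodes)),
                 spec = spec),
            class = "branch_network")
}

#' @export
print.branch_network <- function(x, ...) {
  cat(sprintf("branch network: %d nodes, %d edges, total length %.1f cm%s\n",
              nrow(x$nodes), nrow(x$edges), total_edge_length(x),
              if (all(is.na(x$edge_radius))) " (radii unset)" else ""))
  invisible(x)
}

#' Total branch length of a network
#' @param network A `branch_network`.
#' @return Length in cm.
#' @export
total_edge_length <- function(network) {
  a <- network$nodes[network$edges[, 1L], , drop = FALSE]
  b <- network$nodes[network$edges[, 2L], , drop = FALSE]
  sum(sqrt(rowSums((a - b)^2)))
}

#' Assign branch and joint radii
#'
#' Draws each edge radius uniformly over half the specified diameter range
#' (radius 0.2--0.4 mm for the default 0.4--0.8 mm diameters) and sets each
#' node (joint) radius to `joint_factor` times the largest incident edge
#' radius, capped at half the maximum joint diameter. With the defaults the
#' joints span 0.4--1.6 mm in diameter, the printed joint thickening.
#'
#' @param network A `branch_network`.
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for the radius draw.
#' @param joint_factor Joint-to-branch radius ratio.
#' @return The network with `edge_radius` and `node_radius` filled in (mm).
#' @export
assign_radii <- function(network, spec, seed = spec$seed, joint_factor = 2) {
  stopifnot(inherits(network, "branch_network"), inherits(spec, "phantom_spec"))
  rr <- spec$branch_diameter_range / 2
  set.seed(seed)
  ne <- nrow(network$edges)
  network$edge_radius <- stats::runif(ne, rr[1L], rr[2L])
  rmax_node <- rep(0, nrow(network$nodes))
  for (col in 1:2) {
    agg <- tapply(network$edge_radius, network$edges[, col], max)
    ids <- as.integer(names(agg))
    rmax_node[ids] <- pmax(rmax_node[ids], agg)
  }
  network$node_radius <- pmin(joint_factor * rmax_node,
                              spec$joint_diameter_max / 2)
  network
}

#' Scale all radii of a network by a common factor
#'
#' Used by density tuning; the branch topology is untouched.
#' @param network A `branch_network` with radii assigned.
#' @param scale Multiplicative factor.
#' @return The scaled network, with a `radius_scale` attribute recording the
#'   cumulative scale applied.
#' @export
scale_radii <- function(network, scale) {
  stopifnot(scale > 0, !all(is.na(network$edge_radius)))
  network$edge_radius <- network$edge_radius * scale
  network$node_radius <- network$node_radius * scale
  prev <- attr(network, "radius_scale")
  attr(network, "radius_scale") <- if (is.null(prev)) scale else prev * scale
  network
}
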