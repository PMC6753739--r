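# Shared fixtures, memoized so expensive constructions run once per suite.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small phantom for unit tests: coarse texture, coarse grid, fast
small_spec <- function(seed = 11L) phantom_spec(n_points = 200, seed = seed)

small_network <- function(seed = 11L) {
  memo(paste0("net", seed), {
    spec <- small_spec(seed)
    pts <- lloyd_relax(sample_poisson_disk(spec), iterations = 10L,
                       n_samples = 3e4)
    assign_radii(build_voronoi_edges(pts, spec), spec)
  })
}

# full-scale design used by the acceptance suite (default spec conditions)
full_design <- function(seed) {
  memo(paste0("full", seed), {
    spec <- phantom_spec(seed = seed)
    pts <- lloyd_relax(sample_poisson_disk(spec))
    net <- assign_radii(build_voronoi_edges(pts, spec), spec)
    net <- tune_radius(net, spec)
    phantom <- voxelize(net, spec, n = 100L, supersampling = 4L)
    list(spec = spec, network = net, phantom = phantom,
         density = compute_density(phantom))
  })
}

calibrated_beam <- function(energy) {
  memo(paste0("beam", energy), calibrate_sigma_to_dfw(beam_spec(energy)))
}

# a single-capsule network builder for analytic-volume tests
capsule_network <- function(p0, p1, radius_mm, spec = small_spec()) {
  structure(list(nodes = rbind(p0, p1), edges = matrix(c(1L, 2L), 1),
                 edge_radius = radius_mm, node_radius = c(0, 0),
                 spec = spec),
            class = "branch_network")
}

# a phantom whose voxels are iid Bernoulli(q): the binomial range-mixing
# reference medium
binomial_phantom <- function(q, n = 60L, spacing = 0.04, seed = 5L,
                             material_density = 1.11) {
  set.seed(seed)
  occ <- array(stats::rbinom(n^3, 1L, q), c(n, n, n))
  structure(list(occupancy = occ, spacing = spacing, origin = c(0, 0, 0),
                 material_density = material_density, air_density = 0.0012),
            class = "voxel_phantom")
}
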