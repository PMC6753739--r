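test_that("Poisson-disk sampling honours the minimum spacing exhaustively", {
  spec <- phantom_spec(n_points = 100, seed = 7)
  ps <- sample_poisson_disk(spec)
  expect_gte(nrow(ps$points), 100 * 0.9)
  expect_true(all(ps$points > 0 & ps$points < 4))
  # all C(100, 2) pairwise distances
  expect_gte(min(dist(ps$points)), ps$r_pd)
})

test_that("Poisson-disk sampling is deterministic per seed and handles edge cases", {
  spec <- phantom_spec(n_points = 100, seed = 7)
  expect_identical(sample_poisson_disk(spec)$points,
                   sample_poisson_disk(spec)$points)
  one <- sample_poisson_disk(phantom_spec(n_points = 1, seed = 3))
  expect_equal(nrow(one$points), 1)
  expect_true(all(one$points > 0 & one$points < 4))
  # infeasible spacing factor must fail loudly, not undershoot silently
  expect_error(sample_poisson_disk(phantom_spec(n_points = 500, seed = 1),
                                   r_factor = 1.6,
                                   max_attempts_per_point = 30L),
               "unsatisfiable")
})

test_that("Lloyd relaxation sends one point to the cube centre and two to the half-cube centroids", {
  spec1 <- phantom_spec(n_points = 1, seed = 2)
  p1 <- sample_poisson_disk(spec1)
  r1 <- lloyd_relax(p1, iterations = 5L)
  expect_equal(as.numeric(r1$points), c(2, 2, 2), tolerance = 0.02)
  # two generators on the x axis: cells are the half cubes, centroids at 1/4
  # and 3/4 of the edge
  p2 <- structure(list(points = rbind(c(1.3, 2, 2), c(2.7, 2, 2)),
                       r_pd = 0.1, cube_edge = 4, seed = 5L),
                  class = "point_set")
  r2 <- lloyd_relax(p2, iterations = 25L, n_samples = 2e5)
  got <- r2$points[order(r2$points[, 1]), ]
  expect_equal(as.numeric(got[1, ]), c(1, 2, 2), tolerance = 0.03)
  expect_equal(as.numeric(got[2, ]), c(3, 2, 2), tolerance = 0.03)
})

test_that("Lloyd energy is non-increasing and matches an independent Monte Carlo estimate", {
  spec <- phantom_spec(n_points = 50, seed = 9)
  pts <- lloyd_relax(sample_poisson_disk(spec), iterations = 20L,
                     n_samples = 5e4)
  tr <- attr(pts, "energy_trace")
  expect_gte(length(tr), 2)
  expect_true(all(diff(tr) <= 1e-12))
  # dense-sampling oracle with fresh samples
  expect_equal(cvt_energy(pts, n_samples = 3e5), tr[length(tr)],
               tolerance = 0.02)
  expect_error(lloyd_relax(structure(list(
    points = rbind(c(1, 1, 1), c(1, 1, 1)), r_pd = 1, cube_edge = 4,
    seed = 1L), class = "point_set")), "degenerate")
})

test_that("Voronoi skeleton matches the brute-force Delaunay-dual construction for small n", {
  for (case in list(c(5, 31), c(7, 42), c(8, 53))) {
    n <- case[1]
    set.seed(case[2])
    # interior points, pairwise well separated
    pts <- matrix(runif(3 * n, 0.7, 3.3), ncol = 3)
    while (min(dist(pts)) < 0.4) pts <- matrix(runif(3 * n, 0.7, 3.3), ncol = 3)
    ps <- structure(list(points = pts, r_pd = 0.4, cube_edge = 4, seed = 1L),
                    class = "point_set")
    net <- build_voronoi_edges(ps, phantom_spec(n_points = n))
    got <- segment_set_key(network_segments(net))
    oracle <- largest_component_segments(voronoi_oracle_segments(pts, 4))
    expect_identical(got, segment_set_key(oracle))
  }
})

test_that("Voronoi skeleton edges never leave the cube and form one component", {
  net <- small_network()
  expect_true(all(net$nodes >= -1e-9 & net$nodes <= 4 + 1e-9))
  expect_true(all(net$edges >= 1 & net$edges <= nrow(net$nodes)))
  expect_false(any(duplicated(t(apply(net$edges, 1, sort)))))
  g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  expect_equal(igraph::components(g)$no, 1)
})

test_that("total skeleton length concentrates across seeds", {
  lens <- vapply(101:105, function(seed) {
    spec <- phantom_spec(n_points = 200, seed = seed)
    pts <- lloyd_relax(sample_poisson_disk(spec), iterations = 10L,
                       n_samples = 3e4)
    total_edge_length(build_voronoi_edges(pts, spec))
  }, numeric(1))
  expect_lt((max(lens) - min(lens)) / mean(lens), 0.10)
})

test_that("radius assignment respects printed diameter bounds and is seed-deterministic", {
  net <- small_network()
  spec <- small_spec()
  a <- assign_radii(net, spec, seed = 4L)
  b <- assign_radii(net, spec, seed = 4L)
  expect_identical(a$edge_radius, b$edge_radius)
  expect_true(all(a$edge_radius >= 0.2 & a$edge_radius <= 0.4))
  # joints: at least the thickest incident branch, at most 1.6 mm diameter
  expect_true(all(a$node_radius <= 0.8 + 1e-12))
  for (i in seq_len(nrow(a$edges))) {
    expect_gte(a$node_radius[a$edges[i, 1]], a$edge_radius[i] - 1e-12)
    expect_gte(a$node_radius[a$edges[i, 2]], a$edge_radius[i] - 1e-12)
  }
  # uniform-draw mean 0.3 mm within 3 standard errors
  se <- (0.4 - 0.2) / sqrt(12) / sqrt(length(a$edge_radius))
  expect_lt(abs(mean(a$edge_radius) - 0.3), 3 * se)
})

test_that("radius scaling is multiplicative and cumulative", {
  net <- assign_radii(small_network(), small_spec(), seed = 1L)
  s1 <- scale_radii(net, 1.5)
  expect_equal(s1$edge_radius, net$edge_radius * 1.5)
  s2 <- scale_radii(s1, 2)
  expect_equal(attr(s2, "radius_scale"), 3)
})
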