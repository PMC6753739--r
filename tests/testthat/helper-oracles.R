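# Independent brute-force constructions used as oracles.

# Clip a segment to the axis-aligned cube [0, L]^3 (Liang-Barsky); returns
# NULL if nothing remains.
clip_segment_cube <- function(p0, p1, L) {
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  for (a in 1:3) {
    if (abs(d[a]) < 1e-15) {
      if (p0[a] < -1e-12 || p0[a] > L + 1e-12) return(NULL)
    } else {
      ta <- -p0[a] / d[a]        # crosses x_a = 0
      tb <- (L - p0[a]) / d[a]   # crosses x_a = L
      if (d[a] > 0) { t0 <- max(t0, ta); t1 <- min(t1, tb) }
      else          { t0 <- max(t0, tb); t1 <- min(t1, ta) }
    }
  }
  if (t0 > t1) return(NULL)
  rbind(p0 + t0 * d, p0 + t1 * d)
}

# Circumcenter of a tetrahedron; NULL when nearly degenerate.
tet_circumcenter <- function(P) {
  A <- 2 * sweep(P[2:4, , drop = FALSE], 2, P[1, ])
  b <- rowSums(P[2:4, , drop = FALSE]^2) - sum(P[1, ]^2)
  if (abs(det(A)) < 1e-12) return(NULL)
  as.numeric(solve(A, b))
}

# Brute-force clipped 3D Voronoi edge skeleton via the Delaunay dual:
# every empty-circumsphere tetrahedron contributes a Voronoi vertex (its
# circumcenter); tetrahedra sharing a triangular face contribute the edge
# between their circumcenters; a hull face (in one tetrahedron only)
# contributes the unbounded ray along the face normal away from the opposite
# vertex. All pieces are clipped to the cube. Feasible for n <= ~12 points.
voronoi_oracle_segments <- function(pts, L) {
  n <- nrow(pts)
  stopifnot(n >= 5)
  combs <- utils::combn(n, 4)
  tets <- list()
  for (ci in seq_len(ncol(combs))) {
    idx <- combs[, ci]
    cc <- tet_circumcenter(pts[idx, , drop = FALSE])
    if (is.null(cc)) next
    r2 <- sum((pts[idx[1], ] - cc)^2)
    others <- setdiff(seq_len(n), idx)
    d2 <- rowSums(sweep(pts[others, , drop = FALSE], 2, cc)^2)
    if (all(d2 > r2 - 1e-9)) {
      tets[[length(tets) + 1L]] <- list(idx = sort(idx), cc = cc)
    }
  }
  segs <- list()
  add_seg <- function(p0, p1) {
    s <- clip_segment_cube(p0, p1, L)
    if (!is.null(s) && sum((s[1, ] - s[2, ])^2) > 1e-16) {
      segs[[length(segs) + 1L]] <<- s
    }
  }
  nt <- length(tets)
  face_key <- function(f) paste(f, collapse = "-")
  # faces -> owning tetrahedra
  face_map <- new.env()
  for (ti in seq_len(nt)) {
    for (drop in 1:4) {
      f <- face_key(tets[[ti]]$idx[-drop])
      face_map[[f]] <- c(face_map[[f]], ti)
    }
  }
  for (f in ls(face_map)) {
    owners <- face_map[[f]]
    fidx <- as.integer(strsplit(f, "-")[[1]])
    if (length(owners) == 2L) {
      add_seg(tets[[owners[1]]]$cc, tets[[owners[2]]]$cc)
    } else if (length(owners) == 1L) {
      tet <- tets[[owners[1]]]
      opp <- setdiff(tet$idx, fidx)
      fp <- pts[fidx, , drop = FALSE]
      nrm <- pracma::cross(fp[2, ] - fp[1, ], fp[3, ] - fp[1, ])
      nrm <- nrm / sqrt(sum(nrm^2))
      if (sum(nrm * (pts[opp, ] - fp[1, ])) > 0) nrm <- -nrm
      far <- tet$cc + nrm * (4 * L)
      add_seg(tet$cc, far)
    }
  }
  segs
}

# Canonical string form of a set of segments (endpoint-sorted, rounded) for
# set comparison up to tolerance.
segment_set_key <- function(segs, digits = 6) {
  keys <- vapply(segs, function(s) {
    a <- round(s[1, ], digits) + 0; b <- round(s[2, ], digits) + 0
    ka <- paste(sprintf("%.6f", a), collapse = ",")
    kb <- paste(sprintf("%.6f", b), collapse = ",")
    paste(sort(c(ka, kb)), collapse = "|")
  }, character(1))
  sort(unique(keys))
}

network_segments <- function(net) {
  lapply(seq_len(nrow(net$edges)), function(i) {
    rbind(net$nodes[net$edges[i, 1], ], net$nodes[net$edges[i, 2], ])
  })
}

# Keep only the largest connected component of a segment soup, mirroring the
# printability filter of the package construction.
largest_component_segments <- function(segs, digits = 6) {
  key <- function(p) paste(sprintf("%.6f", round(p, digits) + 0), collapse = ",")
  k0 <- vapply(segs, function(s) key(s[1, ]), character(1))
  k1 <- vapply(segs, function(s) key(s[2, ]), character(1))
  ids <- unique(c(k0, k1))
  e <- cbind(match(k0, ids), match(k1, ids))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  segs[comp$membership[e[, 1]] == main]
}
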