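#' Write / read a depth-dose curve as CSV
#'
#' Two numeric columns `depth_cm, dose_rel` with a header. Reading accepts
#' any uniform depth bin; a curve whose bin differs from `expect_bin` is
#' resampled onto that bin with a warning (linear interpolation, which
#' preserves the 80--20 falloff to within half a bin).
#'
#' @param curve A [depth_dose_curve()].
#' @param path File path.
#' @param expect_bin Depth bin (cm) the reader resamples to; `NULL` keeps
#'   the file's own bin.
#' @return `write_pdd_csv()` returns `path` invisibly; `read_pdd_csv()`
#'   returns a [depth_dose_curve()].
#' @export
write_pdd_csv <- function(curve, path) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  utils::write.csv(data.frame(depth_cm = curve$depths, dose_rel = curve$dose),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pdd_csv
#' @export
read_pdd_csv <- function(path, expect_bin = 0.02) {
  df <- utils::read.csv(path, colClasses = "character")
  if (ncol(df) < 2L) stop("expected a 2-column CSV with header")
  z <- suppressWarnings(as.numeric(df[[1L]]))
  d <- suppressWarnings(as.numeric(df[[2L]]))
  bad <- which(!is.finite(z) | !is.finite(d))
  if (length(bad) > 0L) {
    stop(sprintf("malformed value in data row %d of %s", bad[1L], path))
  }
  if (any(diff(z) <= 0)) stop("depth column must be strictly increasing")
  bin <- z[2L] - z[1L]
  if (!is.null(expect_bin) && abs(bin - expect_bin) > 1e-9) {
    warning(sprintf("resampling from %.4f to %.4f cm depth bin", bin, expect_bin))
    zz <- seq(min(z), max(z), by = expect_bin)
    d <- stats::approx(z, d, xout = zz, rule = 2L)$y
    z <- zz
  }
  depth_dose_curve(z, d)
}

#' Serialize / restore a branch network as JSON
#'
#' Nodes, edges, radii, the generating spec and any tuning attributes, in a
#' plain JSON layout.
#'
#' @param network A `branch_network`.
#' @param path File path.
#' @return `write_network_json()` returns `path` invisibly;
#'   `read_network_json()` returns a `branch_network`.
#' @export
write_network_json <- function(network, path) {
  stopifnot(inherits(network, "branch_network"))
  payload <- list(
    nodes = unclass(network$nodes),
    edges = unclass(network$edges),
    edge_radius_mm = network$edge_radius,
    node_radius_mm = network$node_radius,
    spec = unclass(network$spec),
    radius_scale = attr(network, "radius_scale"),
    achieved_density = attr(network, "achieved_density"))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(phantom_spec, p$spec[c("cube_edge", "n_points", "seed",
                                         "target_density", "material_density",
                                         "branch_diameter_range",
                                         "joint_diameter_max")])
  net <- structure(list(nodes = as.matrix(p$nodes),
                        edges = matrix(as.integer(as.matrix(p$edges)),
                                       ncol = 2L),
                        edge_radius = p$edge_radius_mm,
                        node_radius = p$node_radius_mm,
                        spec = spec),
                   class = "branch_network")
  attr(net, "radius_scale") <- p$radius_scale
  attr(net, "achieved_density") <- p$achieved_density
  net
}

#' Write a voxel phantom as MetaImage (.mhd + .raw)
#'
#' Binary occupancy as unsigned 8-bit MetaImage, the exchange format of the
#' Monte Carlo workflow. A JSON sidecar (`<path>.json`) records spacing,
#' density and provenance.
#'
#' @param phantom A `voxel_phantom` (binarized with [binarize()] first for
#'   the two-material map; fractional grids are thresholded at 0.5).
#' @param path Path of the `.mhd` header; the `.raw` payload sits next
#'   to it.
#' @param sidecar Optional named list merged into the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_mhd <- function(phantom, path, sidecar = list()) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  dims <- dim(phantom$occupancy)
  raw_path <- sub("\\.mhd$", ".raw", path)
  if (identical(raw_path, path)) raw_path <- paste0(path, ".raw")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %d %d %d", dims[1L], dims[2L], dims[3L]),
           sprintf("ElementSpacing = %.6g %.6g %.6g",
                   10 * phantom$spacing, 10 * phantom$spacing,
                   10 * phantom$spacing),
           sprintf("Offset = %.6g %.6g %.6g",
                   10 * phantom$origin[1L], 10 * phantom$origin[2L],
                   10 * phantom$origin[3L]),
           "ElementType = MET_UCHAR",
           sprintf("ElementDataFile = %s", basename(raw_path)))
  writeLines(hdr, path)
  bin <- as.integer(phantom$occupancy > 0.5)
  writeBin(as.raw(bin), raw_path)
  meta <- c(list(format = "MetaImage MET_UCHAR",
                 dims = dims, spacing_mm = 10 * phantom$spacing,
                 material_density = phantom$material_density,
                 air_density = phantom$air_density,
                 fill_fraction = mean(phantom$occupancy > 0.5)),
            sidecar)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Write a voxel phantom as NRRD (fractional occupancy, float)
#'
#' @param phantom A `voxel_phantom`.
#' @param path Path of the `.nrrd` file (attached raw payload).
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(phantom, path) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  dims <- dim(phantom$occupancy)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    "NRRD0004\n",
    "type: float\ndimension: 3\n",
    sprintf("sizes: %d %d %d\n", dims[1L], dims[2L], dims[3L]),
    sprintf("spacings: %.6g %.6g %.6g\n", 10 * phantom$spacing,
            10 * phantom$spacing, 10 * phantom$spacing),
    "endian: little\nencoding: raw\n\n")
  writeChar(hdr, con, eos = NULL)
  writeBin(as.numeric(phantom$occupancy), con, size = 4L, endian = "little")
  invisible(path)
}

#' Run the full phantom-design and transport pipeline
#'
#' Generate (Poisson disk + Lloyd + Voronoi skeleton + radii), tune the
#' radii to the target density, voxelize, trace rays, degrade the calibrated
#' pristine curves and tabulate the falloff metrics -- the end-to-end
#' workflow from design parameters to the degradation table. Artifacts are
#' written under `out_dir` when given, each with the seed and a config hash
#' in its JSON sidecar.
#'
#' @param spec A [phantom_spec()].
#' @param energies Beam energies (MeV) to transport; each uses its built-in
#'   pristine DFW calibration target.
#' @param out_dir Output directory, or `NULL` to skip file output.
#' @param n,supersampling Voxel grid parameters.
#' @param verbose Print stage progress.
#' @return A list with the tuned `network`, `phantom`, `wepl`, per-energy
#'   `curves` and a `metrics` data frame (energy, pristine and degraded DFW
#'   in cm, peak value in percent, sigma bookkeeping in mm).
#' @export
run_pipeline <- function(spec = phantom_spec(), energies = c(155, 200),
                         out_dir = NULL, n = 100L, supersampling = 4L,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("stage 1/5: Poisson-disk seeding + Lloyd relaxation (%d points, seed %d)",
      spec$n_points, spec$seed)
  pts <- sample_poisson_disk(spec)
  pts <- lloyd_relax(pts)
  say("stage 2/5: Voronoi edge skeleton")
  net <- build_voronoi_edges(pts, spec)
  net <- assign_radii(net, spec)
  say("stage 3/5: density tuning on the %d^3 grid", n)
  net <- tune_radius(net, spec, n = n, supersampling = supersampling)
  phantom <- voxelize(net, spec, n = n, supersampling = supersampling)
  say("  achieved density %.5f g/cm^3 (target %.3f)",
      compute_density(phantom), spec$target_density)
  say("stage 4/5: ray tracing")
  wepl <- cast_rays(phantom, jitter_seed = spec$seed + 2L)
  say("  WEPL sigma %.2f mm over %d rays", wepl$sigma_wepl, wepl$n_rays)
  say("stage 5/5: transport + analysis")
  curves <- list()
  rows <- list()
  for (E in energies) {
    bspec <- calibrate_sigma_to_dfw(beam_spec(E))
    pristine <- pristine_pdd(bspec)
    degraded <- degrade_curve(pristine, wepl)
    m_pr <- falloff_metrics(pristine)
    m_dg <- falloff_metrics(degraded, pristine)
    curves[[as.character(E)]] <- list(pristine = pristine, degraded = degraded)
    rows[[as.character(E)]] <- data.frame(
      energy_mev = E,
      dfw_pristine_cm = m_pr$dfw,
      dfw_degraded_cm = m_dg$dfw,
      peak_value_pct = m_dg$peak_value,
      sigma_pristine_mm = m_pr$sigma,
      sigma_voronoi_mm = m_dg$sigma,
      sigma_hetero_mm = sigma_hetero_quadrature(m_dg$sigma, m_pr$sigma),
      sigma_wepl_mm = wepl$sigma_wepl)
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  result <- list(network = net, phantom = phantom, wepl = wepl,
                 curves = curves, metrics = metrics, spec = spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(unclass(spec), cfg_path, digits = NA,
                         auto_unbox = TRUE)
    cfg_hash <- unname(tools::md5sum(cfg_path))
    side <- list(seed = spec$seed, config_hash = cfg_hash)
    write_network_json(net, file.path(out_dir, "network.json"))
    write_mhd(binarize(phantom), file.path(out_dir, "phantom.mhd"),
              sidecar = side)
    for (E in energies) {
      write_pdd_csv(curves[[as.character(E)]]$pristine,
                    file.path(out_dir, sprintf("pristine%d.csv", E)))
      write_pdd_csv(curves[[as.character(E)]]$degraded,
                    file.path(out_dir, sprintf("pdd%d.csv", E)))
    }
    jsonlite::write_json(c(list(seed = spec$seed, config_hash = cfg_hash),
                           as.list(metrics)),
                         file.path(out_dir, "metrics.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  result
}
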