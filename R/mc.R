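#' Monte Carlo transport configuration
#'
#' @param n_photons Photon packets launched per source. 1e6 is a
#'   production-level count; 1e4 suffices for smoke tests.
#' @param seed Integer seed (all randomness flows through it).
#' @param scattering_mode `"reduced_isotropic"` (isotropic scattering at
#'   `mus = mus_prime`, the similarity relation; default, ~10x faster) or
#'   `"henyey_greenstein"` (`mus = mus_prime / (1 - g)`).
#' @param max_path Path-length cap in cm; photons are carried with analytic
#'   weight (no roulette) until exit or this cap.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n_photons = 1e6, seed = 1L,
                      scattering_mode = c("reduced_isotropic",
                                          "henyey_greenstein"),
                      max_path = 100) {
  scattering_mode <- match.arg(scattering_mode)
  stopifnot(n_photons >= 1, max_path > 0)
  structure(list(n_photons = as.integer(n_photons), seed = as.integer(seed),
                 scattering_mode = scattering_mode, max_path = max_path),
            class = "mc_config")
}

pair_key <- function(m, j) sprintf("m%d_j%d", m, j)

#' Monte Carlo photon transport through the voxelized slab
#'
#' Launches `n_photons` packets downward at each source position, samples
#' scattering step lengths from the transport free path, accumulates exact
#' per-voxel path lengths along each trajectory, and applies absorption as
#' continuous weight attenuation `exp(-mua * path)`. A photon exiting the
#' top surface within `acceptance_radius` of detector `j` is recorded for
#' pair `(m, j)`; recorded weights are renormalized to sum to one within
#' each pair. All top-surface exits are additionally binned by exit radius
#' from the source, giving a diffuse-reflectance profile for validation
#' against diffusion theory (see [diffusion_reflectance()]).
#'
#' @param grid A [voxel_grid()].
#' @param optics An [optical_properties()] object.
#' @param probe A [make_probe()] layout (detectors on the `z = 0` face).
#' @param mc An [mc_config()].
#' @param rbin_edges Radial bin edges (cm) for the reflectance profile.
#' @return An object of class `sensitivity_tensor`: per-pair entries with
#'   normalized weights `w`, a sparse photon x voxel path-length matrix
#'   `S` (cm), per-photon total paths, and detection counts; plus the
#'   radial reflectance profile (per cm^2 per launched photon) and all
#'   input metadata.
#' @export
run_monte_carlo <- function(grid, optics, probe, mc = mc_config(),
                            rbin_edges = seq(0, 5, by = 0.25)) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(optics, "optical_properties"),
            inherits(probe, "probe_layout"), inherits(mc, "mc_config"))
  use_hg <- mc$scattering_mode == "henyey_greenstein"
  mus <- if (use_hg) optics$mus_prime / (1 - optics$anisotropy_g)
         else optics$mus_prime
  src <- probe$source_positions
  det <- probe$detector_positions
  set.seed(mc$seed)
  raw <- mc_transport_cpp(grid$nx, grid$ny, grid$nz, grid$voxel_edge,
                          mus, optics$mua, optics$anisotropy_g, use_hg,
                          src, det, probe$acceptance_radius,
                          mc$n_photons, mc$max_path,
                          as.numeric(rbin_edges))
  M <- nrow(src); J <- nrow(det)
  nvox <- n_voxels(grid)
  pairs <- vector("list", M * J)
  names(pairs) <- as.vector(t(outer(seq_len(M), seq_len(J), pair_key)))
  for (m in seq_len(M)) {
    for (j in seq_len(J)) {
      p <- raw$pairs[[(m - 1) * J + j]]
      nq <- length(p$w)
      if (nq == 0) {
        pairs[[pair_key(m, j)]] <- list(m = m, j = j, n_detected = 0L)
        next
      }
      photon <- rep.int(seq_len(nq), diff(p$ptr))
      S <- Matrix::sparseMatrix(i = photon, j = p$vox, x = p$len,
                                dims = c(nq, nvox))
      pairs[[pair_key(m, j)]] <- list(
        m = m, j = j, n_detected = nq,
        w = p$w / sum(p$w), raw_weight = sum(p$w),
        S = S, total_path = p$tot)
    }
  }
  area <- pi * diff(rbin_edges^2)
  refl <- sweep(raw$refl, 2, area * mc$n_photons, "/")
  structure(list(pairs = pairs, grid = grid, optics = optics, probe = probe,
                 mc = mc,
                 reflectance = list(edges = rbin_edges,
                                    mid = (rbin_edges[-1] +
                                           rbin_edges[-length(rbin_edges)]) / 2,
                                    R = refl),
                 top_weight = raw$top_weight),
            class = "sensitivity_tensor")
}

#' @export
print.sensitivity_tensor <- function(x, ...) {
  nd <- vapply(x$pairs, function(p) p$n_detected, integer(1))
  cat(sprintf("<sensitivity_tensor> %d pairs, %d photons/source, %d detected (%d empty pairs)\n",
              length(x$pairs), x$mc$n_photons, sum(nd), sum(nd == 0)))
  invisible(x)
}

#' Keys of usable (non-empty) pairs in a sensitivity tensor
#' @param sens A [run_monte_carlo()] result.
#' @return Character vector of pair keys with at least one detected photon.
#' @export
usable_pairs <- function(sens) {
  names(sens$pairs)[vapply(sens$pairs, function(p) p$n_detected > 0,
                           logical(1))]
}

#' Semi-infinite diffusion-theory diffuse reflectance
#'
#' Closed-form steady-state reflectance `R(rho)` (per cm^2 per injected
#' photon) for a semi-infinite homogeneous medium under the
#' extrapolated-boundary dipole approximation, used as the independent
#' oracle for Monte Carlo validation. Index-matched boundary (`A = 1`),
#' consistent with the transport defaults.
#'
#' @param rho Source-detector separations, cm.
#' @param optics An [optical_properties()] object.
#' @return Reflectance values at `rho`.
#' @export
diffusion_reflectance <- function(rho, optics) {
  mut <- optics$mua + optics$mus_prime
  z0 <- 1 / mut
  D <- 1 / (3 * mut)
  zb <- 2 * D                      # A = 1, index matched
  mueff <- sqrt(optics$mua / D)
  r1 <- sqrt(z0^2 + rho^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho^2)
  (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
     (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2) / (4 * pi)
}

#' Mean detected photon path length per source-detector pair
#' @param sens A [run_monte_carlo()] result.
#' @return Named numeric vector (pair keys) of weighted mean total path
#'   lengths in cm; `NA` for empty pairs.
#' @export
mean_pair_path <- function(sens) {
  vapply(sens$pairs, function(p) {
    if (p$n_detected == 0) return(NA_real_)
    sum(p$w * p$total_path)
  }, numeric(1))
}
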