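#' Voxel grid for the breast-slab tissue model
#'
#' Defines the voxelized slab through which photons are propagated and on
#' which blood flow index (BFI) maps live. Under the defaults the slab
#' measures 8 x 8 x 3 cm with cubic 0.5 cm voxels (16 x 16 x 6 = 1536
#' voxels), the probe face lying at `z = 0`.
#'
#' Voxel indexing is 0-based `(ix, iy, iz)` with `iz` increasing with depth;
#' the linear index is `i = iz*nx*ny + iy*nx + ix` (1-based in R storage).
#' Depth layer `z = 2` in 1-based slice notation covers 0.5--1.0 cm.
#'
#' @param nx,ny,nz Voxel counts along x, y and depth.
#' @param voxel_edge Cubic voxel edge length in cm.
#' @param origin Coordinates (cm) of the probe-surface corner.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(nx = 16L, ny = 16L, nz = 6L, voxel_edge = 0.5,
                       origin = c(0, 0, 0)) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  stopifnot(nx >= 1L, ny >= 1L, nz >= 1L, voxel_edge > 0,
            length(origin) == 3)
  structure(list(nx = nx, ny = ny, nz = nz, voxel_edge = voxel_edge,
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, edge %.2f cm (%.1f x %.1f x %.1f cm slab)\n",
              x$nx, x$ny, x$nz, x$voxel_edge,
              x$nx * x$voxel_edge, x$ny * x$voxel_edge, x$nz * x$voxel_edge))
  invisible(x)
}

#' Number of voxels in a grid
#' @param grid A [voxel_grid()].
#' @return Integer voxel count `nx*ny*nz`.
#' @export
n_voxels <- function(grid) grid$nx * grid$ny * grid$nz

#' Tissue optical properties
#'
#' Breast-like defaults: reduced scattering 8.0 cm^-1, absorption
#' 0.05 cm^-1, refractive index 1.37, anisotropy 0.9, wavelength 785 nm.
#' The optical wave-vector magnitude `k0 = 2*pi*n/lambda` is derived, never
#' stored independently.
#'
#' @param mus_prime Reduced scattering coefficient, cm^-1.
#' @param mua Absorption coefficient, cm^-1.
#' @param refractive_index Tissue refractive index (dimensionless).
#' @param anisotropy_g Scattering anisotropy factor in `[0, 1)`.
#' @param wavelength Light wavelength in cm (785e-7 cm = 785 nm).
#' @return An object of class `optical_properties` with derived field `k0`.
#' @export
optical_properties <- function(mus_prime = 8.0, mua = 0.05,
                               refractive_index = 1.37, anisotropy_g = 0.9,
                               wavelength = 785e-7) {
  stopifnot(mus_prime > 0, mua > 0, refractive_index > 0, wavelength > 0,
            anisotropy_g >= 0, anisotropy_g < 1)
  structure(list(mus_prime = mus_prime, mua = mua,
                 refractive_index = refractive_index,
                 anisotropy_g = anisotropy_g, wavelength = wavelength,
                 k0 = 2 * pi * refractive_index / wavelength),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("<optical_properties> mus'=%.2f cm^-1, mua=%.3f cm^-1, n=%.2f, g=%.2f, k0=%.4g cm^-1\n",
              x$mus_prime, x$mua, x$refractive_index, x$anisotropy_g, x$k0))
  invisible(x)
}

#' Concentric-circle source-detector probe layout
#'
#' Sources sit evenly spaced on an outer circle and detectors on an inner
#' circle, both centered on the probe face. With the default 8 sources at
#' radius 3 cm and 6 detectors at radius 1 cm, the 48 source-detector pairs
#' span separations of 2--4 cm, giving sensitivity at the 5--10 mm imaging
#' depth.
#'
#' @param n_sources,n_detectors Counts on the outer/inner circle.
#' @param source_radius,detector_radius Circle radii in cm.
#' @param center Circle center (cm), default the probe-face center.
#' @param face_size Side of the square probe face in cm.
#' @param acceptance_radius Detection radius around each detector, cm.
#' @param source_phase,detector_phase Angular offsets in radians.
#' @return An object of class `probe_layout` with matrices
#'   `source_positions` (M x 2) and `detector_positions` (J x 2).
#' @export
make_probe <- function(n_sources = 8L, n_detectors = 6L,
                       source_radius = 3.0, detector_radius = 1.0,
                       center = c(4, 4), face_size = 8,
                       acceptance_radius = 0.25,
                       source_phase = 0, detector_phase = 0) {
  stopifnot(n_sources >= 1, n_detectors >= 1, source_radius > 0,
            detector_radius > 0, acceptance_radius > 0)
  ring <- function(n, r, phase) {
    a <- phase + 2 * pi * (seq_len(n) - 1) / n
    cbind(x = center[1] + r * cos(a), y = center[2] + r * sin(a))
  }
  src <- ring(n_sources, source_radius, source_phase)
  det <- ring(n_detectors, detector_radius, detector_phase)
  pts <- rbind(src, det)
  if (any(pts < 0) || any(pts > face_size))
    stop("probe layout exceeds the ", face_size, " x ", face_size,
         " cm probe face", call. = FALSE)
  sep <- sqrt(outer(src[, 1], det[, 1], "-")^2 +
              outer(src[, 2], det[, 2], "-")^2)
  if (any(sep < 1e-9))
    stop("degenerate layout: a source and a detector coincide", call. = FALSE)
  structure(list(source_positions = src, detector_positions = det,
                 acceptance_radius = acceptance_radius,
                 face_size = face_size),
            class = "probe_layout")
}

#' @export
print.probe_layout <- function(x, ...) {
  sep <- pair_separations(x)
  cat(sprintf("<probe_layout> %d sources x %d detectors = %d pairs, separations %.2f-%.2f cm\n",
              nrow(x$source_positions), nrow(x$detector_positions),
              length(sep), min(sep), max(sep)))
  invisible(x)
}

#' Pairwise source-detector separations
#' @param probe A [make_probe()] layout.
#' @return Numeric M x J matrix of separations in cm.
#' @export
pair_separations <- function(probe) {
  src <- probe$source_positions
  det <- probe$detector_positions
  sqrt(outer(src[, 1], det[, 1], "-")^2 + outer(src[, 2], det[, 2], "-")^2)
}

#' Blood flow index map
#'
#' @param values Voxelwise blood flow index alpha*Db in cm^2/s, length
#'   `n_voxels(grid)`, ordered by the linear voxel index.
#' @param grid The [voxel_grid()] the values live on.
#' @return An object of class `bfi_map`.
#' @export
bfi_map <- function(values, grid) {
  stopifnot(length(values) == n_voxels(grid), all(is.finite(values)),
            all(values >= 0))
  structure(list(values = as.numeric(values), grid = grid),
            class = "bfi_map")
}

#' @export
print.bfi_map <- function(x, ...) {
  cat(sprintf("<bfi_map> %d voxels, range [%.3g, %.3g] cm^2/s\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Spherical lesion specification
#'
#' @param center Lesion center `(x, y, z)` in cm (`z` is depth).
#' @param diameter Lesion diameter in cm.
#' @param contrast Blood-flow contrast multiplier over background.
#' @param texture_sigma Relative lognormal heterogeneity within the lesion.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, diameter, contrast, texture_sigma = 0) {
  stopifnot(length(center) == 3, diameter > 0, contrast > 0,
            texture_sigma >= 0)
  structure(list(center = as.numeric(center), diameter = diameter,
                 contrast = contrast, texture_sigma = texture_sigma),
            class = "lesion_spec")
}

voxel_centers <- function(grid) {
  h <- grid$voxel_edge
  cx <- grid$origin[1] + (seq_len(grid$nx) - 0.5) * h
  cy <- grid$origin[2] + (seq_len(grid$ny) - 0.5) * h
  cz <- grid$origin[3] + (seq_len(grid$nz) - 0.5) * h
  # linear index i = iz*nx*ny + iy*nx + ix: x varies fastest
  list(x = rep(cx, times = grid$ny * grid$nz),
       y = rep(rep(cy, each = grid$nx), times = grid$nz),
       z = rep(cz, each = grid$nx * grid$ny))
}

#' Build a blood-flow phantom with spherical lesions
#'
#' Voxels whose centers fall inside a lesion sphere take the value
#' `background_bfi * contrast`, multiplied by lognormal texture noise with
#' log-sd `texture_sigma` (mean-preserving: `meanlog = -sigma^2/2`).
#' Overlapping lesions are resolved by letting the larger perturbed value
#' win (max-contrast policy).
#'
#' @param grid A [voxel_grid()].
#' @param background_bfi Background blood flow index, cm^2/s. The default
#'   4.5e-8 is a typical healthy-breast level.
#' @param lesions List of [lesion_spec()] objects (possibly empty).
#' @param seed Integer seed; the map is deterministic given the seed.
#' @return A [bfi_map()].
#' @export
make_phantom <- function(grid, background_bfi = 4.5e-8, lesions = list(),
                         seed = 1L) {
  stopifnot(background_bfi > 0)
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  vc <- voxel_centers(grid)
  vals <- rep(background_bfi, n_voxels(grid))
  set.seed(seed)
  for (les in lesions) {
    stopifnot(inherits(les, "lesion_spec"))
    r <- les$diameter / 2
    inside <- (vc$x - les$center[1])^2 + (vc$y - les$center[2])^2 +
      (vc$z - les$center[3])^2 <= r^2
    if (!any(inside)) next
    tex <- if (les$texture_sigma > 0)
      stats::rlnorm(sum(inside), meanlog = -les$texture_sigma^2 / 2,
                    sdlog = les$texture_sigma)
    else rep(1, sum(inside))
    cand <- background_bfi * les$contrast * tex
    vals[inside] <- pmax(vals[inside], cand)
  }
  bfi_map(vals, grid)
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Generate a labeled synthetic cohort of lesion phantoms
#'
#' Each subject carries one spherical lesion. Benign-like lesions draw
#' their diameter from Normal(11.4, 8.4) mm truncated to `[3, 40]` mm and
#' their blood-flow contrast from Uniform(2, 5) with low within-lesion
#' heterogeneity; malignant-like lesions draw diameter from
#' Normal(20.4, 9.7) mm truncated to the same range and contrast from
#' Uniform(5, 15) with high heterogeneity, emulating the larger magnitude
#' and heterogeneity of malignant blood flow. Lesion centers fall uniformly
#' in the central probe region at depths overlapping the imaged 0.5--1 cm
#' layer.
#'
#' @param n_benign,n_malignant Subject counts per class.
#' @param grid A [voxel_grid()].
#' @param background_bfi Background blood flow index, cm^2/s.
#' @param seed Integer seed; cohorts are bitwise reproducible.
#' @param benign_texture,malignant_texture Lognormal texture log-sd per class.
#' @return A list with class `dct_cohort`: elements `phantoms` (list of
#'   [bfi_map()]), `labels` (factor, `benign`/`malignant`), `lesions`
#'   (list of [lesion_spec()]), and `id`.
#' @export
make_cohort <- function(n_benign, n_malignant, grid = voxel_grid(),
                        background_bfi = 4.5e-8, seed = 1L,
                        benign_texture = 0.1, malignant_texture = 0.35) {
  stopifnot(n_benign >= 0, n_malignant >= 0)
  n <- n_benign + n_malignant
  labels <- factor(rep(c("benign", "malignant"), c(n_benign, n_malignant)),
                   levels = c("benign", "malignant"))
  phantoms <- vector("list", n)
  lesions <- vector("list", n)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, max(n, 1))
  for (k in seq_len(n)) {
    malignant <- labels[k] == "malignant"
    set.seed(seeds[k])
    diam_cm <- if (malignant)
      rtruncnorm1(1, 20.4, 9.7, 3, 40) / 10
    else
      rtruncnorm1(1, 11.4, 8.4, 3, 40) / 10
    contrast <- if (malignant) stats::runif(1, 5, 15) else stats::runif(1, 2, 5)
    tex <- if (malignant) malignant_texture else benign_texture
    ctr <- c(stats::runif(2, 2, 6), stats::runif(1, 0.6, 1.2))
    les <- lesion_spec(ctr, diam_cm, contrast, tex)
    phantoms[[k]] <- make_phantom(grid, background_bfi, list(les),
                                  seed = seeds[k] %% .Machine$integer.max)
    lesions[[k]] <- les
  }
  structure(list(phantoms = phantoms, labels = labels, lesions = lesions,
                 id = if (n) sprintf("s%03d", seq_len(n)) else character(0)),
            class = "dct_cohort")
}

#' @export
print.dct_cohort <- function(x, ...) {
  cat(sprintf("<dct_cohort> %d subjects (%d benign, %d malignant)\n",
              length(x$phantoms), sum(x$labels == "benign"),
              sum(x$labels == "malignant")))
  invisible(x)
}
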