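#' Delay-time grid for autocorrelation curves
#'
#' @param n Number of delay times.
#' @param tau_min,tau_max Range in seconds; points are geometrically spaced
#'   (multi-tau style). The default grid reaches down to 10 ns so that the
#'   early-decay window of strongly perturbed (high blood flow) channels
#'   still contains several bins.
#' @return An object of class `delay_grid` (numeric vector of taus).
#' @export
delay_grid <- function(n = 96L, tau_min = 1e-8, tau_max = 1e-1) {
  stopifnot(n >= 2, tau_min > 0, tau_max > tau_min)
  structure(exp(seq(log(tau_min), log(tau_max), length.out = n)),
            class = "delay_grid")
}

#' Correlation curve container
#'
#' @param taus Delay times, seconds (strictly increasing, positive).
#' @param values Correlation values; `g1` curves lie in `[0, 1]`, `g2`
#'   curves in `[1, 1 + beta]`.
#' @param kind `"g1"` (field) or `"g2"` (intensity).
#' @param pair Integer `(m, j)` source-detector indices.
#' @param beta Siegert coherence factor (used by `g2` curves).
#' @return An object of class `corr_curve`.
#' @export
corr_curve <- function(taus, values, kind = c("g1", "g2"), pair = c(NA, NA),
                       beta = 0.5) {
  kind <- match.arg(kind)
  taus <- as.numeric(taus)
  stopifnot(length(taus) == length(values), all(taus > 0),
            all(diff(taus) > 0))
  structure(list(taus = taus, values = as.numeric(values), kind = kind,
                 pair = pair, beta = beta),
            class = "corr_curve")
}

#' @export
print.corr_curve <- function(x, ...) {
  cat(sprintf("<corr_curve> %s, pair (%s, %s), %d taus in [%.1e, %.1e] s\n",
              x$kind, x$pair[1], x$pair[2], length(x$taus),
              min(x$taus), max(x$taus)))
  invisible(x)
}

# Per-photon decay rates 2 * sum_i k0^2 * mus' * alphaDb(i) * s(i,q) for one
# pair; the exponent of the exact Monte Carlo forward model.
photon_decay_rates <- function(pair, bfi, optics) {
  2 * optics$k0^2 * optics$mus_prime *
    as.numeric(pair$S %*% bfi$values)
}

#' Exact Monte Carlo forward model for g1
#'
#' Synthesizes the noiseless electric-field autocorrelation
#' `g1(m, j, tau) = sum_q w(q) * exp(-2 tau sum_i k0^2 alphaDb(i) s(i,q) mus')`
#' for every usable source-detector pair from a sensitivity tensor and a
#' blood flow map. This is the exact model whose Taylor expansion yields
#' the first- and Nth-order linear reconstruction systems.
#'
#' @param sens A [run_monte_carlo()] sensitivity tensor.
#' @param bfi A [bfi_map()] on the same grid.
#' @param optics An [optical_properties()] object.
#' @param taus A [delay_grid()] (or numeric vector of positive delays).
#' @return Named list (pair keys) of `g1` [corr_curve()]s; empty pairs are
#'   skipped with a warning.
#' @export
synth_g1 <- function(sens, bfi, optics = sens$optics, taus = delay_grid()) {
  stopifnot(inherits(sens, "sensitivity_tensor"), inherits(bfi, "bfi_map"))
  if (!identical(unclass(bfi$grid), unclass(sens$grid)))
    stop("sensitivity tensor and BFI map are on different grids",
         call. = FALSE)
  keys <- usable_pairs(sens)
  if (length(keys) < length(sens$pairs))
    warning(length(sens$pairs) - length(keys),
            " empty pair(s) skipped in forward synthesis", call. = FALSE)
  taus <- as.numeric(taus)
  out <- lapply(sens$pairs[keys], function(p) {
    r <- photon_decay_rates(p, bfi, optics)
    vals <- as.numeric(p$w %*% exp(-outer(r, taus)))
    corr_curve(taus, vals, "g1", pair = c(p$m, p$j))
  })
  out
}

#' Siegert relation: g1 to g2 and back
#'
#' `siegert_g2()` maps a field curve to an intensity curve via
#' `g2 = 1 + beta * g1^2`; `invert_siegert()` recovers `g1` with the
#' nonnegative root, clipping `g2 < 1` (noise) to 1 and `g1 > 1` to 1.
#'
#' @param curve A `g1` (resp. `g2`) [corr_curve()].
#' @param beta Coherence factor in `(0, 1]`.
#' @return The transformed [corr_curve()].
#' @export
siegert_g2 <- function(curve, beta = 0.5) {
  stopifnot(inherits(curve, "corr_curve"), curve$kind == "g1",
            beta > 0, beta <= 1)
  corr_curve(curve$taus, 1 + beta * curve$values^2, "g2",
             pair = curve$pair, beta = beta)
}

#' @rdname siegert_g2
#' @export
invert_siegert <- function(curve, beta = curve$beta) {
  stopifnot(inherits(curve, "corr_curve"), curve$kind == "g2",
            beta > 0, beta <= 1)
  g1 <- sqrt(pmax(curve$values - 1, 0) / beta)
  corr_curve(curve$taus, pmin(g1, 1), "g1", pair = curve$pair, beta = beta)
}

#' Additive Gaussian measurement noise on a g2 curve
#'
#' Simple seedable stand-in for correlator noise: independent Gaussian
#' perturbation per delay bin with flat standard deviation `sigma`, then
#' clipped to `g2 >= 1`.
#'
#' @param curve A `g2` [corr_curve()].
#' @param sigma Noise standard deviation (per bin).
#' @param seed Optional integer seed for a deterministic draw.
#' @return The perturbed `g2` [corr_curve()].
#' @export
add_noise <- function(curve, sigma = 5e-3, seed = NULL) {
  stopifnot(inherits(curve, "corr_curve"), curve$kind == "g2", sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (sigma == 0) return(curve)
  v <- pmax(curve$values + stats::rnorm(length(curve$values), 0, sigma), 1)
  corr_curve(curve$taus, v, "g2", pair = curve$pair, beta = curve$beta)
}

#' Simulate a full acquisition: optical-switch schedule and 15-s averaging
#'
#' Emulates the acquisition protocol: the optical switch visits each of the
#' M source positions in turn while J detectors record in parallel, the
#' correlator emitting one g2 curve per second for `dwell` seconds at each
#' position. Under the defaults (M = 8, J = 6, dwell = 15 s) this yields
#' 6 x 8 x 15 = 720 raw intensity autocorrelation curves over a 120-s
#' schedule. Each raw curve receives independent noise, is transformed back
#' to g1 via the Siegert relation, and the `dwell` g1 curves of each pair
#' are averaged into one curve per source-detector pair.
#'
#' @param sens A [run_monte_carlo()] sensitivity tensor.
#' @param bfi A [bfi_map()].
#' @param optics An [optical_properties()] object.
#' @param taus A [delay_grid()].
#' @param noise_sigma Per-bin Gaussian g2 noise standard deviation.
#' @param beta Siegert coherence factor.
#' @param dwell Curves recorded per switch position (1 Hz for `dwell` s).
#' @param seed Integer seed.
#' @return An object of class `acquisition_frame`: `curves` (named list of
#'   averaged g1 [corr_curve()]s), `raw_count` (curves averaged per pair),
#'   `n_raw` (total raw curves), and `duration` (schedule length, s).
#' @export
simulate_acquisition <- function(sens, bfi, optics = sens$optics,
                                 taus = delay_grid(), noise_sigma = 5e-3,
                                 beta = 0.5, dwell = 15L, seed = 1L) {
  g1_true <- synth_g1(sens, bfi, optics, taus)
  set.seed(seed)
  M <- nrow(sens$probe$source_positions)
  curves <- lapply(g1_true, function(cv) {
    g2_true <- siegert_g2(cv, beta)
    reps <- vapply(seq_len(dwell), function(t) {
      invert_siegert(add_noise(g2_true, noise_sigma))$values
    }, numeric(length(cv$taus)))
    corr_curve(cv$taus, rowMeans(reps), "g1", pair = cv$pair, beta = beta)
  })
  structure(list(curves = curves, raw_count = as.integer(dwell),
                 n_raw = length(g1_true) * as.integer(dwell),
                 duration = M * as.integer(dwell),
                 noise_sigma = noise_sigma, beta = beta),
            class = "acquisition_frame")
}

#' @export
print.acquisition_frame <- function(x, ...) {
  cat(sprintf("<acquisition_frame> %d averaged g1 curves (%d raw, %d per pair), %d s schedule\n",
              length(x$curves), x$n_raw, x$raw_count, x$duration))
  invisible(x)
}
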