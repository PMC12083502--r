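#' Reconstruct and featurize a synthetic cohort end to end
#'
#' For each phantom in a cohort: synthesize the acquisition (noisy g2
#' curves, Siegert inversion, 15-s averaging), reconstruct the relative
#' blood-flow volume with the NL-DCT / split-Bregman solver, take the
#' classification depth slice, and compute the 12 image features. A single
#' sensitivity tensor is shared across subjects (the probe and optics do
#' not change between patients).
#'
#' @param cohort A [make_cohort()] cohort.
#' @param sens A [run_monte_carlo()] sensitivity tensor.
#' @param optics Optical properties.
#' @param taus Delay grid.
#' @param noise_sigma Acquisition noise level.
#' @param config A [recon_config()].
#' @param layer Classification slice depth layer (1-based).
#' @param seed Base seed; subject `k` uses `seed + k` for its acquisition.
#' @return A data.frame: `id`, 12 feature columns, `label`.
#' @export
cohort_features <- function(cohort, sens, optics = sens$optics,
                            taus = delay_grid(), noise_sigma = 5e-3,
                            config = recon_config(), layer = 2L,
                            seed = 1L) {
  stopifnot(inherits(cohort, "dct_cohort"))
  slices <- vector("list", length(cohort$phantoms))
  for (k in seq_along(cohort$phantoms)) {
    frame <- simulate_acquisition(sens, cohort$phantoms[[k]], optics, taus,
                                  noise_sigma = noise_sigma,
                                  seed = seed + k)
    rec <- reconstruct(frame, sens, optics, config)
    slices[[k]] <- take_slice(rec, layer)
  }
  names(slices) <- cohort$id
  feature_table(slices, cohort$labels)
}
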