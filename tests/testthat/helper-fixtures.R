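# Shared small fixtures and independent brute-force oracles.

default_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      grid <- voxel_grid()
      optics <- optical_properties()
      probe <- make_probe()
      sens <- run_monte_carlo(grid, optics, probe,
                              mc_config(n_photons = 2e4, seed = 42))
      cache <<- list(grid = grid, optics = optics, probe = probe,
                     sens = sens)
    }
    cache
  }
})

# Hand-built sensitivity tensor: one pair, explicit photons, for
# closed-form forward-model checks.
toy_tensor <- function(grid = voxel_grid(nx = 2, ny = 2, nz = 1),
                       optics = optical_properties(),
                       w = 1, vox = list(1L), len = list(1.0)) {
  nq <- length(w)
  S <- Matrix::sparseMatrix(
    i = rep(seq_len(nq), lengths(vox)),
    j = unlist(vox), x = unlist(len),
    dims = c(nq, n_voxels(grid)))
  probe <- make_probe(n_sources = 1, n_detectors = 1,
                      source_radius = 0.4, detector_radius = 0.2,
                      center = c(0.5, 0.5), face_size = 1)
  pairs <- list(m1_j1 = list(m = 1L, j = 1L, n_detected = nq,
                             w = w / sum(w), raw_weight = sum(w), S = S,
                             total_path = Matrix::rowSums(S)))
  structure(list(pairs = pairs, grid = grid, optics = optics,
                 probe = probe, mc = mc_config(n_photons = nq, seed = 1)),
            class = "sensitivity_tensor")
}

# Brute-force AUC-ROC: pairwise concordance with ties counted 1/2.
auc_concordance <- function(prob, pos) {
  p1 <- prob[pos]; p0 <- prob[!pos]
  tot <- 0
  for (a in p1) for (b in p0)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(p1) * length(p0))
}

# Brute-force GLCM contrast/energy oracle (16 levels, 4 symmetric unit
# offsets, averaged), written independently of the package internals.
glcm_oracle <- function(img, levels = 16L) {
  rng <- range(img)
  q <- if (rng[2] > rng[1])
    pmin(floor((img - rng[1]) / (rng[2] - rng[1]) * levels) + 1, levels)
  else matrix(1, nrow(img), ncol(img))
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  con <- en <- numeric(4)
  for (o in seq_along(offs)) {
    P <- matrix(0, levels, levels)
    for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
      r2 <- r + offs[[o]][1]; c2 <- cc + offs[[o]][2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        P[q[r, cc], q[r2, c2]] <- P[q[r, cc], q[r2, c2]] + 1
        P[q[r2, c2], q[r, cc]] <- P[q[r2, c2], q[r, cc]] + 1
      }
    }
    P <- P / sum(P)
    for (i in seq_len(levels)) for (j in seq_len(levels)) {
      con[o] <- con[o] + (i - j)^2 * P[i, j]
      en[o] <- en[o] + P[i, j]^2
    }
  }
  c(contrast = mean(con), energy = mean(en))
}
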