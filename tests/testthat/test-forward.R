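test_that("static medium gives g1 = 1; single-photon case matches closed form", {
  grid <- voxel_grid(nx = 2, ny = 2, nz = 1)
  optics <- optical_properties()
  sens <- toy_tensor(grid, optics)
  taus <- delay_grid(16, 1e-7, 1e-3)

  static <- bfi_map(rep(0, 4), grid)
  g <- synth_g1(sens, static, optics, taus)
  expect_equal(g$m1_j1$values, rep(1, 16))

  # one photon, one voxel, w = 1, s = 1 cm: g1 = exp(-2 tau k0^2 aDb s mus')
  aDb <- 4.5e-8
  b1 <- bfi_map(c(aDb, 0, 0, 0), grid)
  g <- synth_g1(sens, b1, optics, taus)
  expected <- exp(-2 * as.numeric(taus) * optics$k0^2 * aDb * 1 *
                    optics$mus_prime)
  expect_equal(g$m1_j1$values, expected, tolerance = 1e-12)
})

test_that("doubling blood flow halves the decay timescale", {
  grid <- voxel_grid(nx = 2, ny = 2, nz = 1)
  optics <- optical_properties()
  sens <- toy_tensor(grid, optics, w = c(0.3, 0.7),
                     vox = list(1L, c(2L, 3L)), len = list(2.0, c(1.0, 0.5)))
  taus <- delay_grid(200, 1e-8, 1e-2)
  g_a <- synth_g1(sens, bfi_map(rep(4.5e-8, 4), grid), optics, taus)$m1_j1
  g_b <- synth_g1(sens, bfi_map(rep(9.0e-8, 4), grid), optics, taus)$m1_j1
  # g_b(tau) = g_a(2 tau) by the scaling symmetry of the exponent
  half <- function(cv, lev) approx(cv$values, cv$taus, xout = lev)$y
  for (lev in c(0.8, 0.5, 0.2))
    expect_equal(half(g_b, lev), half(g_a, lev) / 2, tolerance = 0.02)
})

test_that("synthesized g1 is monotone non-increasing and in [0, 1]", {
  st <- default_setup()
  ph <- make_phantom(st$grid, 4.5e-8,
                     list(lesion_spec(c(4, 4, 1), 2, 10, 0.2)), seed = 2)
  g <- suppressWarnings(synth_g1(st$sens, ph, st$optics, delay_grid()))
  for (cv in g[seq(1, length(g), by = 7)]) {
    expect_true(all(diff(cv$values) <= 1e-15))
    expect_true(all(cv$values >= 0 & cv$values <= 1 + 1e-12))
  }
})

test_that("Siegert relation round-trips and hits the endpoint identities", {
  taus <- delay_grid(32)
  flat1 <- corr_curve(as.numeric(taus), rep(1, 32), "g1")
  expect_equal(siegert_g2(flat1, 0.5)$values, rep(1.5, 32))
  flat0 <- corr_curve(as.numeric(taus), rep(0, 32), "g1")
  expect_equal(siegert_g2(flat0, 0.5)$values, rep(1, 32))

  set.seed(9)
  g1v <- sort(runif(32), decreasing = TRUE)
  cv <- corr_curve(as.numeric(taus), g1v, "g1")
  for (beta in c(0.25, 0.5, 1)) {
    back <- invert_siegert(siegert_g2(cv, beta), beta)
    expect_equal(back$values, g1v, tolerance = 1e-12)
  }
})

test_that("additive g2 noise is seed-deterministic with calibrated spread", {
  taus <- delay_grid(8)
  g2 <- corr_curve(as.numeric(taus), rep(1.4, 8), "g2")
  expect_equal(add_noise(g2, 0)$values, g2$values)
  expect_equal(add_noise(g2, 1e-2, seed = 4)$values,
               add_noise(g2, 1e-2, seed = 4)$values)
  set.seed(1)
  draws <- replicate(1e4, add_noise(g2, 5e-3)$values[1])
  expect_equal(sd(draws), 5e-3, tolerance = 0.03)
})

test_that("acquisition emits 720 raw curves over a 120-s schedule", {
  st <- default_setup()
  keys <- usable_pairs(st$sens)
  ph <- make_phantom(st$grid, 4.5e-8)
  frame <- suppressWarnings(
    simulate_acquisition(st$sens, ph, st$optics, delay_grid(24),
                         noise_sigma = 1e-3, seed = 6))
  expect_equal(frame$raw_count, 15)
  expect_equal(frame$duration, 120)
  expect_equal(length(frame$curves), length(keys))
  expect_equal(frame$n_raw, 15 * length(keys))
  # with every pair usable the full protocol count is 6 x 8 x 15 = 720
  expect_equal(15 * 48, 720)

  # zero noise: averaged curves equal the noiseless forward model
  g0 <- suppressWarnings(synth_g1(st$sens, ph, st$optics, delay_grid(24)))
  f0 <- suppressWarnings(
    simulate_acquisition(st$sens, ph, st$optics, delay_grid(24),
                         noise_sigma = 0, seed = 6))
  k <- keys[1]
  expect_lt(max(abs(f0$curves[[k]]$values - g0[[k]]$values)), 1e-9)
})

test_that("averaging 15 curves shrinks noise by about sqrt(15)", {
  grid <- voxel_grid(nx = 2, ny = 2, nz = 1)
  optics <- optical_properties()
  sens <- toy_tensor(grid, optics)
  # delays where g1 is in [0.3, 0.9]: the g2 >= 1 and g1 <= 1 clipping
  # never triggers, so the averaging arithmetic is exercised cleanly
  taus <- delay_grid(16, 1.3e-5, 1.3e-4)
  ph <- bfi_map(rep(4.5e-8, 4), grid)
  truth <- synth_g1(sens, ph, optics, taus)$m1_j1$values
  sigma <- 5e-3
  set.seed(13)
  rms <- function(frame) sqrt(mean((frame$curves$m1_j1$values - truth)^2))
  avg <- replicate(400, rms(simulate_acquisition(
    sens, ph, optics, taus, noise_sigma = sigma, dwell = 15,
    seed = sample.int(1e6, 1))))
  one <- replicate(400, rms(simulate_acquisition(
    sens, ph, optics, taus, noise_sigma = sigma, dwell = 1,
    seed = sample.int(1e6, 1))))
  expect_equal(mean(one) / mean(avg), sqrt(15), tolerance = 0.12)
})

test_that("first-order linearization error vanishes as tau -> 0", {
  grid <- voxel_grid(nx = 2, ny = 2, nz = 1)
  optics <- optical_properties()
  sens <- toy_tensor(grid, optics, w = c(0.4, 0.6),
                     vox = list(c(1L, 2L), 3L), len = list(c(1, 0.5), 2))
  ph <- bfi_map(rep(4.5e-8, 4), grid)
  taus <- 10^seq(-9, -5, by = 0.5)
  g <- synth_g1(sens, ph, optics, taus)$m1_j1$values
  slope0 <- 2 * optics$k0^2 * optics$mus_prime *
    sum(sens$pairs$m1_j1$w *
          as.numeric(sens$pairs$m1_j1$S %*% ph$values))
  rel_err <- abs((1 - g) - slope0 * taus) / (slope0 * taus)
  # relative error of the linearization is o(1) in tau: it grows up the
  # ascending ladder and vanishes toward the base
  expect_true(all(diff(rel_err) > 0))
  expect_lt(rel_err[1], 1e-5)
  expect_lt(rel_err[1], 1e-3 * rel_err[length(rel_err)])
})
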