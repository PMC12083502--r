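test_that("slope extraction is exact on linear input and recovers exp rates", {
  taus <- delay_grid(96, 1e-8, 1e-1)
  tv <- as.numeric(taus)

  flat <- corr_curve(tv, rep(1, 96), "g1")
  expect_equal(extract_slope(flat, 0.1)$b, 0)

  # fully decayed curve: no usable early bins -> excluded with warning
  fast <- corr_curve(tv, exp(-1e9 * tv), "g1")
  expect_warning(res <- extract_slope(fast, 0.1), "fewer than 3")
  expect_null(res)

  c0 <- 50
  lin <- corr_curve(tv, pmax(1 - c0 * tv, 0), "g1")
  expect_equal(extract_slope(lin, 0.1)$b, c0, tolerance = 1e-12)

  gam <- 1e4
  ex <- corr_curve(tv, exp(-gam * tv), "g1")
  expect_equal(extract_slope(ex, 0.05)$b, gam, tolerance = 0.02)
})

test_that("system assembly matches the scalar closed form and the tau->0 slope", {
  grid <- voxel_grid(nx = 2, ny = 2, nz = 1)
  optics <- optical_properties()
  sens <- toy_tensor(grid, optics, w = 1, vox = list(1L), len = list(1.5))
  sys <- assemble_system(sens, optics, c(m1_j1 = 1))
  expect_equal(unname(sys$A[1, 1]),
               2 * optics$k0^2 * 1.5 * optics$mus_prime)
  expect_equal(sys$A[1, 2:4], rep(0, 3), ignore_attr = TRUE)

  # finite-difference oracle: A alpha_true vs numerical tau->0 derivative
  # of the exact forward model, on real Monte Carlo sensitivities
  st <- default_setup()
  ph <- make_phantom(st$grid, 4.5e-8,
                     list(lesion_spec(c(4, 4, 0.75), 1.6, 10)), seed = 1)
  eps <- 1e-12
  g <- suppressWarnings(synth_g1(st$sens, ph, st$optics, c(eps, 2 * eps)))
  fd <- vapply(g, function(cv) (1 - cv$values[1]) / eps, numeric(1))
  sys <- assemble_system(st$sens, st$optics, fd)
  pred <- as.numeric(sys$A %*% ph$values)
  expect_lt(max(abs(pred / sys$b - 1)), 0.005)
})

test_that("assembled first-order system is consistent with extracted slopes", {
  st <- default_setup()
  ph <- make_phantom(st$grid, 4.5e-8)
  frame <- suppressWarnings(
    simulate_acquisition(st$sens, ph, st$optics, delay_grid(),
                         noise_sigma = 0, seed = 3))
  slopes <- suppressWarnings(
    vapply(frame$curves, function(cv) extract_slope(cv, 0.1)$b, numeric(1)))
  sys <- assemble_system(st$sens, st$optics, slopes)
  expect_true(all(sys$A >= 0))
  expect_true(all(sys$b >= 0))
  pred <- as.numeric(sys$A %*% ph$values)
  expect_lt(sqrt(sum((pred - sys$b)^2)) / sqrt(sum(sys$b^2)), 0.05)
})

test_that("higher-order correction equals the scalar Taylor remainder", {
  grid <- voxel_grid(nx = 2, ny = 2, nz = 1)
  optics <- optical_properties()
  sens <- toy_tensor(grid, optics, w = 1, vox = list(1L), len = list(1))
  aDb <- 4.5e-8
  ph <- bfi_map(c(aDb, 0, 0, 0), grid)
  x <- 2 * optics$k0^2 * aDb * optics$mus_prime
  taus <- 10^seq(-7, -4, by = 0.25)
  curves <- list(m1_j1 = corr_curve(taus, exp(-x * taus), "g1",
                                    pair = c(1, 1)))

  zero <- bfi_map(rep(0, 4), grid)
  corr0 <- higher_order_correct(curves, sens, optics, zero, order = 3)
  expect_equal(corr0$m1_j1, rep(0, length(taus)))

  for (N in 2:3) {
    corr <- higher_order_correct(curves, sens, optics, ph, order = N)
    y <- (1 - curves$m1_j1$values) + corr$m1_j1
    # corrected data minus the first-order term = -(remainder beyond order N)
    remainder <- exp(-x * taus) -
      Reduce(`+`, lapply(0:N, function(k) (-x * taus)^k / factorial(k)))
    expect_equal(y - x * taus, -remainder, tolerance = 1e-10)
  }
})

test_that("Nth-order reconstruction tightens the wide-window fit residual", {
  st <- default_setup()
  ph <- make_phantom(st$grid, 4.5e-8)
  taus <- delay_grid()
  frame <- suppressWarnings(
    simulate_acquisition(st$sens, ph, st$optics, taus, noise_sigma = 0,
                         seed = 3))
  rec1 <- suppressWarnings(
    reconstruct(frame, st$sens, st$optics, recon_config(order = 1)))
  rec3 <- suppressWarnings(
    reconstruct(frame, st$sens, st$optics, recon_config(order = 3)))
  est1 <- attr(rec1, "bfi"); est3 <- attr(rec3, "bfi")
  # residual of 1 - g1 ~ b tau over the wide window, with and without the
  # order-2..3 compensation computed from each estimate
  resid <- function(est, order) {
    corr <- if (order > 1)
      higher_order_correct(frame, st$sens, st$optics, est, order) else NULL
    tot <- 0
    for (k in names(frame$curves)) {
      cv <- frame$curves[[k]]
      y <- 1 - cv$values
      if (!is.null(corr)) y <- y + corr[[k]]
      use <- (1 - cv$values) < 0.6
      b <- sum(cv$taus[use] * y[use]) / sum(cv$taus[use]^2)
      tot <- tot + sum((y[use] - b * cv$taus[use])^2)
    }
    tot
  }
  expect_lt(resid(est3, 3), resid(est1, 1))
  expect_equal(mean(est3$values) / mean(est1$values), 1, tolerance = 0.25)
})

test_that("split-Bregman TV solver hits its oracle limits", {
  g4 <- voxel_grid(nx = 4, ny = 1, nz = 1)
  # b = 0 -> zero map
  sys0 <- structure(list(A = diag(4), b = rep(0, 4), keys = letters[1:4]),
                    class = "linear_system")
  expect_equal(solve_bregman_tv(sys0, g4)$values, rep(0, 4))

  # identity system, fidelity-dominated: recovers the data
  target <- c(1e-8, 5e-8, 2e-8, 8e-8)
  sysI <- structure(list(A = diag(4) * 1e8, b = target * 1e8,
                         keys = letters[1:4]), class = "linear_system")
  rec <- solve_bregman_tv(sysI, g4,
                          recon_config(mu = 1e6, bregman_iters = 200))
  expect_equal(rec$values, target, tolerance = 1e-3)
  obj <- attr(rec, "objective")
  expect_true(all(diff(obj) <= 1e-8 * pmax(obj[-length(obj)], 1)))

  # small well-conditioned system at weak TV vs nonnegative LS oracle
  skip_if_not_installed("pracma")
  set.seed(21)
  g6 <- voxel_grid(nx = 3, ny = 2, nz = 1)
  A <- matrix(runif(8 * 6, 0.5, 2), 8, 6) * 1e8
  xtrue <- c(2, 0, 7, 4, 0, 1) * 1e-8
  b <- as.numeric(A %*% xtrue)
  sys <- structure(list(A = A, b = b, keys = paste0("p", 1:8)),
                   class = "linear_system")
  nnls <- pracma::lsqnonneg(A * 1e-8, b * 1e-8)$x
  rec <- solve_bregman_tv(sys, g6,
                          recon_config(mu = 1e7, bregman_iters = 400,
                                       inner_tol = 1e-12))
  expect_lt(sqrt(sum((rec$values - nnls)^2)) / sqrt(sum(nnls^2)), 0.01)
})

test_that("relative-BFI normalization has mean exactly 1", {
  grid <- voxel_grid(nx = 2, ny = 1, nz = 1)
  expect_equal(normalize_rbfi(bfi_map(c(3e-8, 3e-8), grid))$values, c(1, 1))
  expect_equal(normalize_rbfi(bfi_map(c(1, 3), grid))$values, c(0.5, 1.5))
  set.seed(4)
  for (i in 1:5) {
    g <- voxel_grid(nx = 4, ny = 3, nz = 2)
    m <- normalize_rbfi(bfi_map(rexp(24), g))
    expect_equal(mean(m$values), 1, tolerance = 1e-12)
  }
  expect_error(normalize_rbfi(bfi_map(c(0, 0), grid)), "degenerate")
})

test_that("homogeneous phantom reconstructs flat and 16x16x6", {
  st <- default_setup()
  ph <- make_phantom(st$grid, 4.5e-8)
  frame <- suppressWarnings(
    simulate_acquisition(st$sens, ph, st$optics, delay_grid(),
                         noise_sigma = 0, seed = 3))
  rec <- suppressWarnings(reconstruct(frame, st$sens, st$optics))
  expect_equal(dim(array(rec$values, c(rec$grid$nx, rec$grid$ny,
                                       rec$grid$nz))), c(16, 16, 6))
  expect_equal(mean(rec$values), 1, tolerance = 1e-12)
  expect_lt(max(abs(rec$values - 1)), 0.15)
})

test_that("reconstruction localizes an inclusion and tracks its contrast", {
  st <- default_setup()
  contrasts <- c(2, 5, 10)
  rec_contrast <- numeric(3)
  for (i in seq_along(contrasts)) {
    les <- lesion_spec(c(4, 4, 0.75), 1.6, contrasts[i])
    ph <- make_phantom(st$grid, 4.5e-8, list(les), seed = 8)
    frame <- suppressWarnings(
      simulate_acquisition(st$sens, ph, st$optics, delay_grid(),
                           noise_sigma = 0, seed = 4))
    rec <- suppressWarnings(reconstruct(frame, st$sens, st$optics))
    sl <- take_slice(rec, 2)
    rec_contrast[i] <- max(sl) / median(sl)
    if (contrasts[i] == 10) {
      am <- which(sl == max(sl), arr.ind = TRUE)[1, ]
      # lesion center (4, 4) cm spans voxels 8-9 in x and y
      expect_true(all(abs(am - 8.5) <= 1.5))
    }
  }
  expect_true(all(diff(rec_contrast) > 0))
})
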