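# Joint MR-PET variational reconstruction.

test_that("Poisson negative log-likelihood matches direct evaluation", {
  sino <- sinogram(matrix(c(2, 3), 1, 2), 0, randoms_rate = 0)
  id2 <- Matrix::Diagonal(2)
  # x = [2, 1], y = [2, 3]: 1'(x) - y'log(x) = 3 - 2 log 2
  expect_equal(poisson_nll(c(2, 1), sino, system = id2), 3 - 2 * log(2),
               tolerance = 1e-12)
  # stationary point at x = y: finite-difference gradient vanishes
  f <- function(x) poisson_nll(x, sino, system = id2)
  eps <- 1e-6
  g1 <- (f(c(2 + eps, 3)) - f(c(2 - eps, 3))) / (2 * eps)
  expect_lt(abs(g1), 1e-6)
  # with y = 0 the NLL is linear in r: doubling r doubles it
  s0 <- sinogram(matrix(0, 1, 2), 0, randoms_rate = 1)
  s1 <- sinogram(matrix(0, 1, 2), 0, randoms_rate = 2)
  expect_equal(2 * poisson_nll(c(0, 0), s0, system = id2),
               poisson_nll(c(0, 0), s1, system = id2))
  expect_error(poisson_nll(c(0, 1), sino, system = id2), "domain")
})

test_that("poisson_nll + TV is midpoint-convex along random segments", {
  sino <- sinogram(matrix(rpois(16, 8), 1, 16), 0, randoms_rate = 0.5)
  idm <- Matrix::Diagonal(16)
  set.seed(8)
  for (i in 1:100) {
    x1 <- matrix(runif(16, 0.1, 5), 4, 4)
    x2 <- matrix(runif(16, 0.1, 5), 4, 4)
    fval <- function(x) poisson_nll(x, sino, system = idm) + tv_value(x)
    expect_lte(fval((x1 + x2) / 2), (fval(x1) + fval(x2)) / 2 + 1e-9)
  }
})

test_that("edge-weighted coupling rewards aligned edges", {
  u <- matrix(0.1, 16, 16); u[, 9:16] <- 1         # step edge at column 9
  x_aligned <- matrix(0, 16, 16); x_aligned[, 9:16] <- 5
  x_shifted <- matrix(0, 16, 16); x_shifted[, 12:16] <- 5
  expect_equal(coupling_term(u, matrix(2, 16, 16))$value, 0)
  c_al <- coupling_term(u, x_aligned)$value
  c_sh <- coupling_term(u, x_shifted)$value
  expect_lt(c_al, c_sh)
  # eta -> Inf reduces to the unweighted total variation of x
  expect_equal(coupling_term(u, x_shifted, eta = Inf)$value,
               tv_value(x_shifted), tolerance = 1e-12)
})

test_that("Hankel projection preserves low-rank spectra and truncates rank", {
  n <- 32
  # single complex exponential per row: exactly rank-1 Hankel structure
  f <- exp(2i * pi * 0.23 * (0:(n - 1)))
  k <- rbind(f, 2 * f)
  proj <- hankel_project(k, patch = 8, rank = 1)
  expect_lt(max(Mod(proj - k)), 1e-8)
  # a rank-2 spectrum (two exponentials) passes through unchanged, and the
  # lifted matrix of the output stays numerically rank 2
  g2 <- f + 0.6 * exp(2i * pi * 0.41 * (0:(n - 1)))
  out <- hankel_project(rbind(g2), patch = 8, rank = 2)
  expect_lt(max(Mod(out - rbind(g2))), 1e-8)
  H <- sapply(1:(n - 8 + 1), function(j) out[1, j:(j + 7)])
  expect_lt(svd(H)$d[3] / svd(H)$d[1], 1e-10)
  # denoising: projection moves a noisy low-rank signal toward the truth
  clean <- rbind(f, f * exp(2i * pi * 0.11 * (0:(n - 1))))
  noisy2 <- clean + 0.1 * matrix(complex(real = rnorm(2 * n),
                                         imaginary = rnorm(2 * n)), 2, n)
  den <- hankel_project(noisy2, patch = 8, rank = 2)
  expect_lt(sum(Mod(den - clean)^2), sum(Mod(noisy2 - clean)^2))
  expect_error(hankel_project(k, patch = 8, rank = 9), "rank")
})

test_that("joint objective decouples exactly when the coupling weight is zero", {
  n <- 48
  ph <- test_phantom(seed = 504, grid = n)
  k <- fourier_encode(ph$mr_image, "forward")
  mask <- matrix(TRUE, n, n)
  sino <- simulate_counts(project(ph$pet_activity * 30, angles60), 0.5, 1)
  st <- list(u = ph$mr_image + 0i, x_pet = ph$pet_activity + 0.1)
  w0 <- recon_weights(lambda1 = 0.3, lambda2 = 0.4, lambda3 = 0)
  ob <- joint_objective(st, k, mask, sino, w0)
  mr_part <- ob$mr_fid + 0.3 * ob$tv_mr
  pet_part <- ob$pet_nll + 0.4 * ob$tv_pet
  expect_equal(ob$total, mr_part + pet_part, tolerance = 1e-10)
  expect_equal(ob$coupling, 0)
})

test_that("full noiseless data with no priors is recovered exactly", {
  n <- 48
  ph <- test_phantom(seed = 504, grid = n)
  k <- fourier_encode(ph$mr_image, "forward")
  mask <- line_sampling_mask(seq_len(n), n)
  sino <- simulate_counts(project(ph$pet_activity * 30, angles60), 0.5, 1)
  st <- solve_joint(k, mask, sino,
                    recon_weights(lambda1 = 0, lambda2 = 0, lambda3 = 0),
                    n_outer = 5)
  nrmse <- sqrt(mean(Mod(st$u - ph$mr_image)^2)) /
    sqrt(mean(ph$mr_image^2))
  expect_lt(nrmse, 1e-3)
  expect_true(all(st$x_pet >= 0))
})

test_that("objective trace is monotone up to small alternation transients", {
  n <- 48
  ph <- test_phantom(seed = 505, grid = n)
  meas <- topoacq:::simulate_full_measurements(ph, closed_loop_config(), 55)
  mask <- build_sampling_mask(n, 0.4, 1.0, seed = 5)
  y <- meas$kspace * mask$mask
  st <- solve_joint(y, mask, meas$sino, recon_weights(), n_outer = 12)
  tot <- st$objective_trace$total
  expect_true(all(diff(tot) <= 0.01 * abs(tot[-length(tot)])))
  expect_true(all(st$x_pet >= 0))
  expect_true(all(is.finite(tot)))
})

test_that("cross-modal coupling improves undersampled PET recovery", {
  n <- 64
  ph <- test_phantom(seed = 506, grid = n)
  meas <- topoacq:::simulate_full_measurements(ph, closed_loop_config(), 66)
  mask <- build_sampling_mask(n, 0.3, 1.0, seed = 6)
  y <- meas$kspace * mask$mask
  sino_c <- topoacq:::subset_sinogram(meas$sino,
                                      meas$angles[seq(1, 60, by = 4)])
  nrmse_x <- function(l3) {
    st <- solve_joint(y, mask, sino_c, recon_weights(lambda3 = l3),
                      n_outer = 12)
    xt <- ph$pet_activity / mean(ph$pet_activity)
    xs <- st$x_pet / mean(st$x_pet)
    sqrt(mean((xs - xt)^2))
  }
  expect_lt(nrmse_x(0.3), nrmse_x(0))
})

test_that("reconstruction magnitude is invariant to a global phase", {
  n <- 48
  ph <- test_phantom(seed = 504, grid = n)
  k <- fourier_encode(ph$mr_image, "forward")
  mask <- build_sampling_mask(n, 0.5, 1.0, seed = 7)
  sino <- simulate_counts(project(ph$pet_activity * 30, angles60), 0.5, 1)
  y <- k * mask$mask
  w <- recon_weights(lambda3 = 0)
  s1 <- solve_joint(y, mask, sino, w, n_outer = 8, conj_fill = FALSE)
  s2 <- solve_joint(y * exp(1i * 0.7), mask, sino, w, n_outer = 8,
                    conj_fill = FALSE)
  expect_lt(max(abs(Mod(s1$u) - Mod(s2$u))), 1e-6)
})
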