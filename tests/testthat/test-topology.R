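# Persistence diagrams, vascular graphs, Wasserstein distances.

test_that("diagram constructor enforces its invariants", {
  expect_error(as_persistence_diagram(1, 0.5, 0L), "death")
  expect_error(as_persistence_diagram(0, 1, 2L), "degrees")
  d <- as_persistence_diagram(c(0, 0.2), c(1, 0.9), c(0L, 1L))
  expect_s3_class(d, "persistence_diagram")
  expect_equal(nrow(empty_diagram()), 0)
})

test_that("image persistence matches analytic expectations", {
  # constant image: one essential component, no loops
  d <- persistence_diagram(matrix(0.4, 20, 20))
  expect_equal(sum(d$degree == 0), 1)
  expect_equal(sum(d$degree == 1), 0)
  # clean one-loop phantom: exactly one high-persistence loop
  ph <- test_phantom(seed = 502, grid = 128, n_loops = 1)
  d1 <- persistence_diagram(ph$mr_image)
  pers <- d1$death - d1$birth
  expect_equal(sum(d1$degree == 1 & pers > 0.5), 1)
  # intensity-stability on a clean ring image (one component, one loop,
  # no shallow junction features): perturbing intensities by eps creates
  # only points of persistence <= eps and moves existing points by <= eps
  # in the bottleneck sense
  base <- matrix(0.15, 64, 64)
  base[20:44, 20:44] <- 1; base[26:38, 26:38] <- 0.15
  d0 <- persistence_diagram(base)
  expect_equal(nrow(d0), 2)
  for (eps in c(0.01, 0.05)) {
    set.seed(31)
    noisy <- base + matrix(runif(length(base), -eps / 2, eps / 2),
                           nrow(base))
    dn <- persistence_diagram(noisy)
    new_pts <- dn[dn$death - dn$birth <= 0.5, ]
    expect_true(all(new_pts$death - new_pts$birth <= eps + 1e-12))
    # dominant features move by at most the perturbation amplitude
    for (k in 0:1) {
      big0 <- d0[d0$degree == k, ]
      bign <- dn[dn$degree == k & dn$death - dn$birth > 0.5, ]
      expect_equal(nrow(bign), 1)
      expect_lt(max(abs(c(bign$birth - big0$birth,
                          bign$death - big0$death))), eps / 2 + 1e-12)
    }
  }
})

test_that("graph extraction handles degenerate inputs and simple shapes", {
  g0 <- extract_graph(matrix(0, 32, 32))
  expect_equal(unname(betti_numbers(g0)), c(0, 0))
  expect_identical(attr(g0, "warning"), "empty segmentation")
  seg <- rasterize_phantom(
    vessel_tree(cbind(c(16, 48), c(32, 32)), rbind(c(1, 2)), 2.5, 64),
    texture_amplitude = 0)
  g1 <- extract_graph(seg$mr_image)
  expect_equal(unname(betti_numbers(g1)), c(1, 0))
  ph <- test_phantom(seed = 502, grid = 128, n_loops = 1)
  g2 <- extract_graph(ph$mr_image)
  b <- betti_numbers(g2)
  expect_equal(unname(b), c(1, 1))   # Euler-formula count of the one loop
})

test_that("Betti numbers follow the Euler formula on explicit graphs", {
  path <- topoacq:::new_vascular_graph(
    matrix(0, 3, 2), data.frame(from = c(1, 2), to = c(2, 3),
                                length = c(1, 1)), 1L)
  expect_equal(unname(betti_numbers(path)), c(1, 0))
  tri <- topoacq:::new_vascular_graph(
    matrix(0, 3, 2), data.frame(from = c(1, 2, 3), to = c(2, 3, 1),
                                length = c(1, 1, 1)), 1L)
  expect_equal(unname(betti_numbers(tri)), c(1, 1))
  two <- topoacq:::new_vascular_graph(
    matrix(0, 6, 2), data.frame(from = c(1, 2, 3, 4, 5),
                                to = c(2, 3, 1, 5, 6),
                                length = rep(1, 5)), 2L)
  expect_equal(unname(betti_numbers(two)), c(2, 1))   # 5 - 6 + 2
})

test_that("exact Wasserstein equals brute-force enumeration on all small diagrams", {
  # worked single-point examples first
  d1 <- as_persistence_diagram(0, 2, 0L)
  expect_equal(wasserstein_exact(d1, empty_diagram(), p = 1, degree = 0L), 1)
  da <- as_persistence_diagram(0, 1, 0L)
  db <- as_persistence_diagram(c(0, 0.4), c(1, 0.5), c(0L, 0L))
  expect_equal(wasserstein_exact(da, db, p = 1, degree = 0L), 0.05)
  # exhaustive: every size combination up to 4 points per side
  for (n1 in 0:4) for (n2 in 0:4) {
    for (rep in 1:3) {
      x <- random_diagram(n1, 0L, seed = 1000 + 17 * n1 + 3 * n2 + rep)
      y <- random_diagram(n2, 0L, seed = 2000 + 13 * n1 + 7 * n2 + rep)
      for (p in c(1, 2)) {
        expect_equal(wasserstein_exact(x, y, p = p, degree = 0L),
                     brute_force_wasserstein(x, y, p = p, degree = 0L),
                     tolerance = 1e-10)
      }
    }
  }
  # metric properties
  z <- random_diagram(4, 0L, seed = 77)
  expect_equal(wasserstein_exact(z, z, p = 2, degree = 0L), 0)
})

test_that("sliced Wasserstein is symmetric, exact on identity, and accurate", {
  x <- random_diagram(30, 0L, seed = 5)
  y <- random_diagram(40, 0L, seed = 6)
  expect_equal(wasserstein_sliced(x, x, seed = 1), 0)
  expect_equal(wasserstein_sliced(x, y, seed = 3),
               wasserstein_sliced(y, x, seed = 3), tolerance = 1e-12)
  # accuracy spot check (full benchmark lives in the acceptance suite)
  ex <- wasserstein_exact(x, y, p = 2, degree = 0L)
  sl <- wasserstein_sliced(x, y, p = 2, seed = 3)
  expect_lt(abs(sl - ex) / ex, 0.05)
  # the unrefined average is a valid (biased) lower estimate
  expect_lte(wasserstein_sliced(x, y, p = 2, seed = 3, refine = FALSE),
             ex * 1.05)
})

test_that("topological uncertainty is a weighted degree-wise distance", {
  d_ref <- as_persistence_diagram(c(0, 0.1), c(1, 0.9), c(0L, 1L))
  expect_equal(topological_uncertainty(d_ref, d_ref), 0)
  d_t <- as_persistence_diagram(c(0, 0.1), c(0.8, 0.5), c(0L, 1L))
  w1 <- uncertainty_weights(0.5, 0.5)
  w2 <- uncertainty_weights(1, 1)
  u1 <- topological_uncertainty(d_t, d_ref, w1)
  expect_equal(topological_uncertainty(d_t, d_ref, w2), 2 * u1)
  # masking: zero weight on the only differing degree zeroes the measure
  d_t2 <- as_persistence_diagram(c(0, 0.3), c(1, 0.35), c(0L, 1L))
  expect_equal(topological_uncertainty(
    d_t2, d_ref, uncertainty_weights(1, 0)), 0)
  expect_error(uncertainty_weights(0, 0), "w0")
})

test_that("normalized persistence deviation behaves as a percentage", {
  d_ref <- as_persistence_diagram(c(0, 0.1, 0.2, 0.3), c(1, 0.9, 0.3, 0.45),
                                  c(0L, 1L, 0L, 1L))
  expect_equal(normalized_persistence_deviation(d_ref, d_ref), 0)
  expect_equal(normalized_persistence_deviation(empty_diagram(), d_ref), 100)
  # dropping low-persistence points costs less than dropping dominant ones
  pers <- d_ref$death - d_ref$birth
  keep_high <- as_persistence_diagram(d_ref$birth[pers > 0.5],
                                      d_ref$death[pers > 0.5],
                                      d_ref$degree[pers > 0.5])
  keep_low <- as_persistence_diagram(d_ref$birth[pers <= 0.5],
                                     d_ref$death[pers <= 0.5],
                                     d_ref$degree[pers <= 0.5])
  expect_lt(normalized_persistence_deviation(keep_high, d_ref),
            normalized_persistence_deviation(keep_low, d_ref))
  expect_error(
    normalized_persistence_deviation(d_ref, empty_diagram()),
    "degenerate")
  # scale invariance under joint intensity rescaling
  sc <- 3.7
  d_acc <- as_persistence_diagram(c(0, 0.15), c(0.9, 0.8), c(0L, 1L))
  scale_d <- function(d) as_persistence_diagram(sc * d$birth, sc * d$death,
                                                d$degree)
  expect_equal(normalized_persistence_deviation(d_acc, d_ref, method = "exact"),
               normalized_persistence_deviation(scale_d(d_acc),
                                                scale_d(d_ref),
                                                method = "exact"),
               tolerance = 1e-10)
})

test_that("persistence and graph Betti counts agree on clean phantoms", {
  agree <- 0
  for (s in 1:50) {
    tr <- generate_vessel_tree(s, 4, 0.5, 96)
    ph <- rasterize_phantom(tr, seed = s)
    bd <- betti_from_diagram(persistence_diagram(ph$mr_image), 0.5)
    bg <- betti_numbers(extract_graph(ph$mr_image))
    agree <- agree + all(bd == bg)
    expect_equal(unname(bd["b1"]), tr$loop_count)
  }
  expect_equal(agree, 50)
})
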