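# Vessel-tree generation and phantom rasterization.

test_that("vessel tree generation is deterministic and validates inputs", {
  t1 <- generate_vessel_tree(42, 5, 0.5, 128)
  t2 <- generate_vessel_tree(42, 5, 0.5, 128)
  expect_identical(t1$nodes, t2$nodes)
  expect_identical(t1$edges, t2$edges)
  expect_error(generate_vessel_tree(1, 5, 0.5, 16), "grid_size")
  # trees without loops have first Betti number zero
  t0 <- generate_vessel_tree(7, 5, 0, 128)
  expect_identical(t0$loop_count, 0L)
  expect_equal(tree_betti1(t0), 0)
})

test_that("Euler formula beta1 = E - V + C on explicit graphs", {
  # V=6, E=6, one component -> beta1 = 1
  nodes <- cbind(c(20, 40, 60, 60, 40, 20), c(20, 20, 20, 40, 40, 40))
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 1))
  tr <- vessel_tree(nodes, edges, rep(2, 6), 96)
  expect_equal(tree_betti1(tr), 1)
  expect_equal(tr$loop_count, 1)
  # duplicate edges and invalid endpoints rejected
  expect_error(vessel_tree(nodes, rbind(c(1, 2), c(2, 1)), c(2, 2), 96),
               "duplicate")
  expect_error(vessel_tree(nodes, rbind(c(1, 9)), 2, 96), "valid nodes")
  expect_error(vessel_tree(nodes, rbind(c(1, 2)), -1, 96), "positive")
})

test_that("generated loop count always satisfies the Euler formula", {
  for (s in 1:200) {
    tr <- generate_vessel_tree(s, n_primary_branches = 4,
                               loop_probability = (s %% 4) / 4,
                               grid_size = 96)
    expect_equal(tree_betti1(tr), tr$loop_count)
    expect_true(all(tr$radii > 0))
    key <- paste(pmin(tr$edges[, 1], tr$edges[, 2]),
                 pmax(tr$edges[, 1], tr$edges[, 2]))
    expect_equal(anyDuplicated(key), 0L)
  }
})

test_that("rasterization handles degenerate and simple trees", {
  empty <- vessel_tree(matrix(numeric(), 0, 2), matrix(integer(), 0, 2),
                       numeric(), 64)
  ph <- rasterize_phantom(empty, grid_size = 64, background_level = 0.15,
                          texture_amplitude = 0)
  expect_true(all(ph$mr_image == 0.15))
  expect_true(all(ph$label_map == 0L))
  # single straight segment: one 8-connected component, no holes
  seg <- vessel_tree(cbind(c(16, 48), c(32, 32)), rbind(c(1, 2)), 2.5, 64)
  ph2 <- rasterize_phantom(seg, texture_amplitude = 0)
  expect_equal(count_components8(ph2$label_map), 1)
  expect_equal(flood_fill_holes(ph2$label_map), 0)
  expect_true(all(ph2$pet_activity >= 0))
  expect_equal(dim(ph2$mr_image), dim(ph2$pet_activity))
  # sub-pixel radii are a resolution error
  thin <- vessel_tree(cbind(c(16, 48), c(32, 32)), rbind(c(1, 2)), 0.5, 64)
  expect_error(rasterize_phantom(thin), "radius")
})

test_that("a one-loop phantom rasterizes to exactly one hole at 128^2", {
  ph <- test_phantom(seed = 502, grid = 128, n_loops = 1)
  expect_equal(tree_betti1(ph$tree), 1)
  expect_equal(flood_fill_holes(ph$label_map), 1)
  expect_equal(count_components8(ph$label_map), 1)
})

test_that("doubled resolution never decreases topology agreement", {
  for (s in c(601, 602, 603, 604)) {
    tr <- generate_vessel_tree(s, 4, 0.5, 96)
    agree <- function(g) {
      ph <- rasterize_phantom(tr, grid_size = g, texture_amplitude = 0)
      (flood_fill_holes(ph$label_map) == tr$loop_count) +
        (count_components8(ph$label_map) == 1)
    }
    expect_gte(agree(192), agree(96))
  }
})

test_that("ground-truth diagram reflects phantom topology deterministically", {
  flat <- rasterize_phantom(
    vessel_tree(matrix(numeric(), 0, 2), matrix(integer(), 0, 2),
                numeric(), 64),
    grid_size = 64, texture_amplitude = 0)
  d0 <- ground_truth_diagram(flat)
  expect_equal(sum(d0$degree == 0), 1)
  expect_equal(sum(d0$degree == 1), 0)
  ph <- test_phantom(seed = 502, grid = 128, n_loops = 1)
  d <- ground_truth_diagram(ph)
  high <- d[d$degree == 1 & (d$death - d$birth) > 0.5, ]
  expect_equal(nrow(high), 1)       # matches the flood-fill hole count above
  expect_identical(d, ground_truth_diagram(ph))
})

test_that("tree and diagram CSV round trips preserve content", {
  tr <- generate_vessel_tree(9, 4, 0.5, 96)
  f <- tempfile(fileext = ".csv")
  write_tree_csv(tr, f)
  df <- read.csv(f)
  expect_equal(nrow(df), nrow(tr$edges))
  expect_equal(df$radius, tr$radii)
  ph <- test_phantom()
  d <- ground_truth_diagram(ph)
  f2 <- tempfile(fileext = ".csv")
  write_diagram_csv(d, f2)
  expect_equal(read_diagram_csv(f2), d, ignore_attr = TRUE)
})
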