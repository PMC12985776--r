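# Independent brute-force oracles used across the suite.

angles60 <- seq(0, 177, by = 3)

# Exhaustive optimal partial matching between two small diagrams of one
# degree: every point may match a distinct point of the other diagram or its
# own diagonal projection. Returns the order-p Wasserstein distance.
brute_force_wasserstein <- function(d1, d2, p = 2, degree = 0L,
                                    ground = "linf") {
  pts <- function(d) {
    sel <- d$degree == degree
    cbind(d$birth[sel], d$death[sel])
  }
  a <- pts(d1); b <- pts(d2)
  gd <- function(x, y) {
    if (ground == "linf") max(abs(x[1] - y[1]), abs(x[2] - y[2]))
    else sqrt(sum((x - y)^2))
  }
  dg <- function(x) {
    if (ground == "linf") (x[2] - x[1]) / 2 else (x[2] - x[1]) / sqrt(2)
  }
  n <- nrow(a); m <- nrow(b)
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > n) {
      acc <- acc + sum(vapply(setdiff(seq_len(m), used),
                              function(j) dg(b[j, ])^p, numeric(1)))
      if (acc < best) best <<- acc
      return()
    }
    rec(i + 1, used, acc + dg(a[i, ])^p)            # diagonal
    for (j in setdiff(seq_len(m), used)) {
      rec(i + 1, c(used, j), acc + gd(a[i, ], b[j, ])^p)
    }
  }
  rec(1, integer(), 0)
  best^(1 / p)
}

# Hole count of a binary mask by flood fill of the complement:
# number of 4-connected background components not touching the border.
flood_fill_holes <- function(mask) {
  storage.mode(mask) <- "integer"
  bg <- topoacq:::label_components_cpp(1L - mask, 4L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  length(setdiff(unique(bg[bg > 0L]), border))
}

# 8-connected foreground component count.
count_components8 <- function(mask) {
  storage.mode(mask) <- "integer"
  max(topoacq:::label_components_cpp(mask, 8L))
}

# seeded random diagram with n points of one degree
random_diagram <- function(n, degree = 0L, seed = 1, max_pers = 0.5) {
  set.seed(seed)
  b <- runif(n)
  as_persistence_diagram(b, b + runif(n, 0, max_pers), rep(degree, n))
}

# small deterministic test phantom (cached per session)
test_phantom <- local({
  cache <- list()
  function(seed = 501, grid = 96, n_loops = 1) {
    key <- paste(seed, grid, n_loops)
    if (is.null(cache[[key]])) {
      tr <- generate_vessel_tree(seed, n_primary_branches = 4,
                                 loop_probability = 0.5, grid_size = grid,
                                 n_loops = n_loops)
      cache[[key]] <<- rasterize_phantom(tr, seed = seed)
    }
    cache[[key]]
  }
})
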