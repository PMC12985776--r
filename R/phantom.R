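# Synthetic 2D vascular phantoms with analytically known graph topology.
#
# A phantom pairs an MR intensity grid (vessels bright on a dim background)
# with a PET activity grid rasterized from the same ground-truth vessel
# graph, so that every downstream topology measurement can be checked
# against the Euler formula on the generating tree.

#' Generate a seeded random vessel tree
#'
#' Grows a connected arterial tree (trunk plus side branches) on a square
#' grid and optionally closes collateral loops between branches. The number
#' of independent cycles of the returned graph equals `loop_count` by the
#' Euler formula `b1 = E - V + C`.
#'
#' @param seed integer; all randomness derives from it (deterministic).
#' @param n_primary_branches number of side branches grown off the trunk.
#' @param loop_probability probability in `[0, 1]` that an eligible
#'   collateral connection is closed into a loop.
#' @param grid_size linear grid dimension in pixels; must be >= 32.
#' @param n_loops optional integer overriding the stochastic loop count:
#'   exactly this many eligible collaterals are closed (fewer if geometry
#'   does not permit).
#' @return A `vessel_tree`: list with `nodes` (n x 2 matrix of x/y grid
#'   coordinates), `edges` (m x 2 integer matrix of node indices), `radii`
#'   (per-edge vessel radius in pixels), `loop_count`, `grid_size`.
#' @export
generate_vessel_tree <- function(seed, n_primary_branches = 5,
                                 loop_probability = 0.3, grid_size = 128,
                                 n_loops = NULL) {
  if (grid_size < 32) stop("grid_size must be >= 32")
  stopifnot(loop_probability >= 0, loop_probability <= 1,
            n_primary_branches >= 1)
  with_seed(seed, {
    g <- grid_size
    lo <- 0.08 * g; hi <- 0.92 * g
    nodes <- matrix(c(lo + 2, 0.5 * g), 1, 2)
    edges <- matrix(integer(), 0, 2)
    edge_depth <- integer()
    in_box <- function(p) all(p >= lo) && all(p <= hi)
    # clearance of a proposed segment against all edges not touching
    # `skip` nodes; keeps tubes from crossing or fusing, so the raster
    # topology equals the graph topology
    clear_of <- function(p, q, skip, min_clear) {
      for (e in seq_len(nrow(edges))) {
        if (any(edges[e, ] %in% skip)) next
        if (segment_segment_dist(p, q, nodes[edges[e, 1], ],
                                 nodes[edges[e, 2], ]) < min_clear) {
          return(FALSE)
        }
      }
      TRUE
    }
    # angle separation from sibling segments at the shared node
    angle_ok <- function(src, dir) {
      for (e in seq_len(nrow(edges))) {
        other <- if (edges[e, 1] == src) edges[e, 2]
                 else if (edges[e, 2] == src) edges[e, 1] else next
        d2 <- nodes[other, ] - nodes[src, ]
        cosang <- sum(dir * d2) / sqrt(sum(dir^2) * sum(d2^2))
        if (cosang > cos(0.5)) return(FALSE)
      }
      TRUE
    }
    add_segment <- function(src, len, ang0, spread, depth, clear) {
      for (try in 1:25) {
        ang <- ang0 + runif(1, -spread, spread)
        dir <- len * c(cos(ang), sin(ang))
        p <- nodes[src, ] + dir
        if (!in_box(p)) next
        if (!angle_ok(src, dir)) next
        if (!clear_of(nodes[src, ], p, src, clear)) next
        nodes <<- rbind(nodes, p)
        edges <<- rbind(edges, c(src, nrow(nodes)))
        edge_depth <<- c(edge_depth, depth)
        return(list(node = nrow(nodes), ang = ang))
      }
      NULL
    }
    seg <- 0.16 * g
    clearance <- max(10, 0.09 * g)
    # trunk: rightward with angular jitter
    cur <- 1L; ang <- 0
    trunk_nodes <- cur
    for (i in 1:4) {
      res <- add_segment(cur, seg, ang, 0.35, 0L, clearance)
      if (is.null(res)) break
      cur <- res$node; ang <- res$ang
      trunk_nodes <- c(trunk_nodes, cur)
    }
    # primary branches: two segments each, off random trunk nodes
    for (b in seq_len(n_primary_branches)) {
      for (try in 1:10) {
        src <- if (length(trunk_nodes) > 1) sample(trunk_nodes[-1], 1) else 1L
        side <- sample(c(-1, 1), 1)
        res <- add_segment(src, 0.8 * seg, side * 1.0, 0.4, 1L, clearance)
        if (!is.null(res)) {
          add_segment(res$node, 0.7 * seg, res$ang, 0.5, 2L, clearance)
          break
        }
      }
    }
    # collateral loops: connect node pairs whose straight connector stays
    # clear of the rest of the tree, so the enclosed hole has interior and
    # survives rasterization
    loop_count <- 0L
    want <- if (is.null(n_loops)) NA_integer_ else as.integer(n_loops)
    try_loops <- function(relax) {
      cand <- utils::combn(nrow(nodes), 2)
      cand <- cand[, sample(ncol(cand)), drop = FALSE]
      for (ci in seq_len(ncol(cand))) {
        if (!is.na(want) && loop_count >= want) break
        a <- cand[1, ci]; b <- cand[2, ci]
        if (any((edges[, 1] == a & edges[, 2] == b) |
                (edges[, 1] == b & edges[, 2] == a))) next
        d_ab <- sqrt(sum((nodes[a, ] - nodes[b, ])^2))
        if (d_ab < 0.15 * g || d_ab > 0.55 * g) next
        if (!clear_of(nodes[a, ], nodes[b, ], c(a, b), relax * clearance)) next
        if (!angle_ok(a, nodes[b, ] - nodes[a, ])) next
        if (!angle_ok(b, nodes[a, ] - nodes[b, ])) next
        midp <- (nodes[a, ] + nodes[b, ]) / 2
        if (min_dist_to_edges(midp, nodes, edges) < relax * 0.08 * g) next
        take <- if (is.na(want)) runif(1) < loop_probability else TRUE
        if (!take) next
        edges <<- rbind(edges, c(a, b))
        edge_depth <<- c(edge_depth, 2L)
        loop_count <<- loop_count + 1L
      }
    }
    try_loops(0.8)
    if (!is.na(want) && loop_count < want) try_loops(0.65)
    radii <- pmax(1.3, 2.8 * 0.8^edge_depth)
    structure(list(nodes = nodes, edges = edges, radii = radii,
                   loop_count = loop_count, grid_size = g,
                   dimension = 2L, seed = as.integer(seed)),
              class = "vessel_tree")
  })
}

#' Construct a vessel tree from explicit nodes, edges and radii
#'
#' For user-supplied or degenerate (e.g. empty) trees; [generate_vessel_tree()]
#' is the usual entry point.
#'
#' @param nodes n x 2 matrix of x/y grid coordinates.
#' @param edges m x 2 integer matrix of node indices.
#' @param radii per-edge radius in pixels, all positive.
#' @param grid_size nominal grid the coordinates refer to.
#' @export
vessel_tree <- function(nodes, edges, radii, grid_size) {
  nodes <- matrix(as.numeric(nodes), ncol = 2)
  edges <- matrix(as.integer(edges), ncol = 2)
  stopifnot(nrow(edges) == length(radii))
  if (length(radii) && any(radii <= 0)) stop("radii must be positive")
  if (nrow(edges)) {
    if (any(edges < 1) || any(edges > nrow(nodes)))
      stop("edge endpoints must reference valid nodes")
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(key)) stop("duplicate edges")
  }
  tr <- structure(list(nodes = nodes, edges = edges, radii = as.numeric(radii),
                       loop_count = NA_integer_, grid_size = grid_size,
                       dimension = 2L, seed = NA_integer_),
                  class = "vessel_tree")
  tr$loop_count <- tree_betti1(tr)
  tr
}

min_dist_to_edges <- function(p, nodes, edges) {
  if (nrow(edges) == 0) return(Inf)
  d <- vapply(seq_len(nrow(edges)), function(e) {
    point_segment_dist(p, nodes[edges[e, 1], ], nodes[edges[e, 2], ])
  }, numeric(1))
  min(d)
}

point_segment_dist <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((p - a - t * ab)^2))
}

segment_segment_dist <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- orient(q1, q2, p1); d2 <- orient(q1, q2, p2)
  d3 <- orient(p1, p2, q1); d4 <- orient(p1, p2, q2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(0)
  min(point_segment_dist(p1, q1, q2), point_segment_dist(p2, q1, q2),
      point_segment_dist(q1, p1, p2), point_segment_dist(q2, p1, p2))
}

#' @export
print.vessel_tree <- function(x, ...) {
  v <- nrow(x$nodes); e <- nrow(x$edges)
  comp <- tree_components(x)
  cat(sprintf("Vessel tree: V=%d E=%d C=%d loops(b1)=%d on %dx%d grid\n",
              v, e, comp, e - v + comp, x$grid_size, x$grid_size))
  invisible(x)
}

# connected components of the tree graph (union-find)
tree_components <- function(tree) {
  n <- nrow(tree$nodes)
  parent <- seq_len(n)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (e in seq_len(nrow(tree$edges))) {
    a <- findp(tree$edges[e, 1]); b <- findp(tree$edges[e, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  length(unique(vapply(seq_len(n), findp, integer(1))))
}

#' First Betti number of a vessel tree by the Euler formula
#' @param tree a `vessel_tree`.
#' @return `E - V + C`.
#' @export
tree_betti1 <- function(tree) {
  nrow(tree$edges) - nrow(tree$nodes) + tree_components(tree)
}

#' Rasterize a vessel tree into an MR/PET phantom
#'
#' Vessels are drawn as tubes of width `2 * radius` with a flat core and a
#' one-pixel Gaussian edge feather (so total-variation priors stay
#' meaningful). The PET activity is 1.0 inside vessels over a 0.1 background,
#' later scaled to a count budget by the acquisition simulator. A gentle
#' seeded smooth background field (amplitude 0.02) avoids a degenerate
#' constant background.
#'
#' @param tree a `vessel_tree` whose nodes fit inside the grid.
#' @param grid_size output grid dimension (defaults to the tree's own).
#' @param background_level MR background intensity in `[0, 1)`.
#' @param seed integer seed for the smooth background field.
#' @param texture_amplitude amplitude of the seeded smooth background field;
#'   set to 0 for an exactly flat background.
#' @return A `phantom`: list with `mr_image` (in `[0,1]`), `pet_activity`
#'   (non-negative), `label_map` (binary vessel support), `tree`, `seed`.
#' @export
rasterize_phantom <- function(tree, grid_size = tree$grid_size,
                              background_level = 0.15, seed = 0,
                              texture_amplitude = 0.02) {
  stopifnot(inherits(tree, "vessel_tree"))
  g <- grid_size
  scale <- g / tree$grid_size
  nodes <- tree$nodes * scale
  radii <- tree$radii * scale
  if (nrow(nodes) && (any(nodes < 0.5) || any(nodes > g + 0.5)))
    stop("tree does not fit inside the grid")
  if (length(radii) && any(radii < 1))
    stop("vessel radius below 1 pixel after scaling; increase grid_size")
  xs <- matrix(rep(seq_len(g), each = g), g, g)   # column coordinate
  ys <- matrix(rep(seq_len(g), times = g), g, g)  # row coordinate
  profile <- matrix(0, g, g)
  label <- matrix(0L, g, g)
  for (e in seq_len(nrow(tree$edges))) {
    a <- nodes[tree$edges[e, 1], ]; b <- nodes[tree$edges[e, 2], ]
    r <- radii[e]
    abx <- b[1] - a[1]; aby <- b[2] - a[2]
    len2 <- abx^2 + aby^2
    t <- if (len2 == 0) 0 else pmin(pmax(((xs - a[1]) * abx + (ys - a[2]) * aby) / len2, 0), 1)
    dx <- xs - (a[1] + t * abx); dy <- ys - (a[2] + t * aby)
    d <- sqrt(dx^2 + dy^2)
    core <- r - 0.5
    prof <- ifelse(d <= core, 1, exp(-(d - core)^2 / (2 * 0.5^2)))
    profile <- pmax(profile, prof)
    label[d <= r] <- 1L
  }
  # junction discs: nodes are filled at the max incident radius so tube
  # overlaps cannot leave sub-resolution pinholes at branch points
  for (v in seq_len(nrow(nodes))) {
    inc <- which(tree$edges[, 1] == v | tree$edges[, 2] == v)
    if (!length(inc)) next
    r <- max(radii[inc])
    d <- sqrt((xs - nodes[v, 1])^2 + (ys - nodes[v, 2])^2)
    core <- r - 0.5
    prof <- ifelse(d <= core, 1, exp(-(d - core)^2 / (2 * 0.5^2)))
    profile <- pmax(profile, prof)
    label[d <= r] <- 1L
  }
  # close sub-resolution pinholes left by tube unions at shallow angles:
  # background cavities below the vessel-diameter scale are not lumina
  if (any(label == 1L)) {
    bgc <- label_components_cpp(1L - label, 4L)
    border_labs <- unique(c(bgc[1, ], bgc[g, ], bgc[, 1], bgc[, g]))
    tab <- tabulate(bgc[bgc > 0L])
    fill <- setdiff(which(tab < 9), border_labs)
    if (length(fill)) {
      sel <- bgc %in% fill
      label[sel] <- 1L
      profile[sel] <- 1
    }
  }
  bg <- with_seed(seed, smooth_background(g, amplitude = texture_amplitude))
  mr <- pmin(pmax(background_level + bg + (1 - background_level) * profile, 0), 1)
  pet <- 0.1 + 0.9 * label
  structure(list(mr_image = mr, pet_activity = pet, label_map = label,
                 tree = tree, seed = as.integer(seed),
                 background_level = background_level),
            class = "phantom")
}

smooth_background <- function(g, amplitude = 0.02, n_bumps = 3) {
  xs <- matrix(rep(seq_len(g), each = g), g, g)
  ys <- matrix(rep(seq_len(g), times = g), g, g)
  bg <- matrix(0, g, g)
  for (i in seq_len(n_bumps)) {
    cx <- runif(1, 0.2, 0.8) * g; cy <- runif(1, 0.2, 0.8) * g
    s <- runif(1, 0.25, 0.5) * g
    bg <- bg + runif(1, -1, 1) * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * s^2))
  }
  if (max(abs(bg)) > 0) bg <- bg / max(abs(bg)) * amplitude
  bg
}

#' @export
print.phantom <- function(x, ...) {
  g <- nrow(x$mr_image)
  cat(sprintf("Phantom %dx%d: %d vessel pixels, tree b1=%d\n",
              g, g, sum(x$label_map), tree_betti1(x$tree)))
  invisible(x)
}

#' @export
plot.phantom <- function(x, which = c("mr", "pet", "label"), ...) {
  which <- match.arg(which)
  img <- switch(which, mr = x$mr_image, pet = x$pet_activity,
                label = x$label_map + 0)
  graphics::image(t(img)[, nrow(img):1], col = grey.colors(128),
                  axes = FALSE, asp = 1, ...)
  invisible(x)
}

#' Ground-truth persistence diagram of a phantom
#'
#' Diagram of the noiseless MR image under the superlevel filtration; this is
#' the oracle reference diagram used by the closed-loop controller's
#' evaluation mode.
#'
#' @param phantom a `phantom`.
#' @param min_persistence noise floor passed to [persistence_diagram()].
#' @export
ground_truth_diagram <- function(phantom, min_persistence = 0) {
  stopifnot(inherits(phantom, "phantom"))
  persistence_diagram(phantom$mr_image, min_persistence = min_persistence)
}

#' Write a vessel tree as a CSV edge list
#' @param tree a `vessel_tree`; `path` file path.
#' @export
write_tree_csv <- function(tree, path) {
  write.csv(data.frame(node_id_a = tree$edges[, 1],
                       node_id_b = tree$edges[, 2],
                       radius = tree$radii),
            path, row.names = FALSE)
  invisible(path)
}
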