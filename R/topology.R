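# Topological descriptors of images: cubical persistence, centerline graph
# extraction, Betti numbers.

#' Persistence diagram of an image
#'
#' Cubical-complex persistence of the superlevel-set filtration of intensity
#' (vessels are bright): degree-0 features are connected components of the
#' bright structure, degree-1 features are loops. Foreground uses
#' 8-connectivity, the complement 4-connectivity. Diagrams are returned in the
#' flipped convention (sublevel sets of the negated image), so
#' `death >= birth` and `death - birth` is the feature's intensity lifetime.
#'
#' @param image numeric matrix of finite intensities.
#' @param min_persistence prune features with persistence at or below this
#'   noise floor (default 0: keep everything except exact ties).
#' @return A [as_persistence_diagram()] object.
#' @export
persistence_diagram <- function(image, min_persistence = 0) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  res <- cube_persistence_cpp(image, min_persistence)
  as_persistence_diagram(
    birth  = c(res$h0[, 1], res$h1[, 1]),
    death  = c(res$h0[, 2], res$h1[, 2]),
    degree = c(rep(0L, nrow(res$h0)), rep(1L, nrow(res$h1))))
}

#' Betti numbers implied by a persistence diagram
#'
#' Counts features whose persistence exceeds a noise floor.
#' @param d a `persistence_diagram`.
#' @param noise_floor persistence threshold separating signal from noise.
#' @return `c(b0 = ..., b1 = ...)`.
#' @export
betti_from_diagram <- function(d, noise_floor = 0.1) {
  pers <- d$death - d$birth
  c(b0 = sum(d$degree == 0 & pers > noise_floor),
    b1 = sum(d$degree == 1 & pers > noise_floor))
}

#' Otsu's threshold of an intensity image
#'
#' @param image numeric matrix.
#' @param n_bins histogram resolution.
#' @return scalar threshold maximizing between-class variance.
#' @export
otsu_threshold <- function(image, n_bins = 256) {
  v <- as.numeric(image)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = n_bins)
  w <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

#' Extract a vascular centerline graph from an image
#'
#' Binarizes the image (Otsu by default), skeletonizes the mask by
#' morphological thinning, and converts the skeleton into a graph whose
#' vertices are junction/endpoint pixel clusters and whose edges are
#' centerline chains (with pixel length). Deterministic.
#'
#' @param image numeric matrix, or a binary (0/1) mask when
#'   `threshold = "mask"`.
#' @param threshold `"auto"` (Otsu), `"mask"` (image already binary), or a
#'   numeric cutoff; pixels strictly above it are vessel.
#' @param min_hole_area background holes (4-connected, not touching the
#'   border) smaller than this many pixels are filled before
#'   skeletonization: holes below the vessel-diameter scale cannot be
#'   genuine lumina between vessels. Set 0 to disable.
#' @return A `vascular_graph`: list with `vertices` (k x 2 matrix of row/col
#'   coordinates), `edges` (data frame `from`, `to`, `length`), `components`.
#'   An empty segmentation yields a zero-vertex graph carrying a
#'   `"warning"` attribute rather than an error.
#' @export
extract_graph <- function(image, threshold = "auto", min_hole_area = 25) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  mask <- if (identical(threshold, "mask")) {
    image > 0
  } else if (identical(threshold, "auto")) {
    image > otsu_threshold(image)
  } else {
    image > as.numeric(threshold)
  }
  storage.mode(mask) <- "integer"
  if (min_hole_area > 0 && any(mask == 1L)) {
    bg <- label_components_cpp(1L - mask, 4L)
    border_labs <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    tab <- tabulate(bg[bg > 0L])
    fill <- setdiff(which(tab < min_hole_area), border_labs)
    if (length(fill)) mask[bg %in% fill] <- 1L
  }
  if (!any(mask == 1L)) {
    g <- new_vascular_graph(matrix(numeric(), 0, 2),
                            data.frame(from = integer(), to = integer(),
                                       length = numeric()), 0L)
    attr(g, "warning") <- "empty segmentation"
    return(g)
  }
  skel <- zhang_suen_thin_cpp(mask)
  skeleton_to_graph(skel)
}

new_vascular_graph <- function(vertices, edges, components) {
  structure(list(vertices = vertices, edges = edges,
                 components = as.integer(components)),
            class = "vascular_graph")
}

#' @export
print.vascular_graph <- function(x, ...) {
  b <- betti_numbers(x)
  cat(sprintf("Vascular graph: %d vertices, %d edges, %d component(s); b0=%d b1=%d\n",
              nrow(x$vertices), nrow(x$edges), x$components, b[1], b[2]))
  invisible(x)
}

#' Betti numbers of a vascular graph
#'
#' `b0` is the number of connected components; `b1 = E - V + b0` by the
#' Euler formula for graphs.
#' @param graph a `vascular_graph`.
#' @return `c(b0 = ..., b1 = ...)`.
#' @export
betti_numbers <- function(graph) {
  stopifnot(inherits(graph, "vascular_graph"))
  v <- nrow(graph$vertices)
  e <- nrow(graph$edges)
  c(b0 = graph$components, b1 = e - v + graph$components)
}

# Convert a thinned 0/1 skeleton matrix into a vascular_graph.
skeleton_to_graph <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  idx <- which(skel == 1L)
  npix <- length(idx)
  if (npix == 0) {
    return(new_vascular_graph(matrix(numeric(), 0, 2),
                              data.frame(from = integer(), to = integer(),
                                         length = numeric()), 0L))
  }
  pr <- ((idx - 1L) %% nr) + 1L
  pc <- ((idx - 1L) %/% nr) + 1L
  pix_id <- integer(nr * nc)          # grid index -> pixel number (1..npix)
  pix_id[idx] <- seq_len(npix)
  offs <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  at <- function(r, c) {
    ifelse(r >= 1L & r <= nr & c >= 1L & c <= nc,
           pix_id[pmax(r, 1L) + (pmax(c, 1L) - 1L) * nr], 0L)
  }
  nbrs <- vector("list", npix)
  for (i in seq_len(npix)) {
    ids <- integer()
    for (k in 1:8) {
      rr <- pr[i] + offs[k, 1]; cc <- pc[i] + offs[k, 2]
      id <- at(rr, cc)
      if (id == 0L) next
      if (k > 4L) {
        # skip redundant diagonal adjacency (staircase triangle) when an
        # orthogonal intermediate pixel carries the connection already
        if (at(pr[i] + offs[k, 1], pc[i]) > 0L ||
            at(pr[i], pc[i] + offs[k, 2]) > 0L) next
      }
      ids <- c(ids, id)
    }
    nbrs[[i]] <- ids
  }
  deg <- lengths(nbrs)
  is_vertex <- deg != 2L

  # cluster adjacent vertex pixels into single graph vertices
  cluster <- integer(npix)            # 0 = chain pixel
  n_clusters <- 0L
  for (i in seq_len(npix)) {
    if (!is_vertex[i] || cluster[i] != 0L) next
    n_clusters <- n_clusters + 1L
    queue <- i
    cluster[i] <- n_clusters
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in nbrs[[p]]) {
        if (is_vertex[q] && cluster[q] == 0L) {
          cluster[q] <- n_clusters
          queue <- c(queue, q)
        }
      }
    }
  }

  edges_from <- integer(); edges_to <- integer(); edges_len <- numeric()
  add_edge <- function(a, b, len) {
    edges_from <<- c(edges_from, a); edges_to <<- c(edges_to, b)
    edges_len <<- c(edges_len, len)
  }
  visited <- logical(npix)            # chain pixels consumed by a trace
  # trace chains emanating from vertex clusters
  for (p in which(is_vertex)) {
    for (q in nbrs[[p]]) {
      if (is_vertex[q] || visited[q]) next
      prev <- p; cur <- q; len <- 1
      repeat {
        visited[cur] <- TRUE
        nxt <- setdiff(nbrs[[cur]], prev)
        if (length(nxt) == 0) { nxt <- prev; }   # dead end back (shouldn't occur)
        nxt <- nxt[[1]]
        if (is_vertex[nxt]) {
          add_edge(cluster[p], cluster[nxt], len + 1)
          break
        }
        if (visited[nxt]) { add_edge(cluster[p], cluster[p], len + 1); break }
        prev <- cur; cur <- nxt; len <- len + 1
      }
    }
  }
  # direct vertex-cluster adjacencies (no chain in between)
  seen_pairs <- character()
  for (p in which(is_vertex)) {
    for (q in nbrs[[p]]) {
      if (!is_vertex[q]) next
      a <- cluster[p]; b <- cluster[q]
      if (a == b) next
      key <- paste(min(a, b), max(a, b))
      if (key %in% seen_pairs) next
      seen_pairs <- c(seen_pairs, key)
      add_edge(a, b, 1)
    }
  }
  # pure cycles: untouched chains with no vertex pixel anywhere on them
  for (s in seq_len(npix)) {
    if (is_vertex[s] || visited[s]) next
    n_clusters <- n_clusters + 1L
    cluster[s] <- n_clusters
    visited[s] <- TRUE
    prev <- s; cur <- nbrs[[s]][1]; len <- 1
    while (!visited[cur]) {
      visited[cur] <- TRUE
      nxt <- setdiff(nbrs[[cur]], prev)[1]
      prev <- cur; cur <- nxt; len <- len + 1
    }
    add_edge(n_clusters, n_clusters, len)
  }

  # vertex coordinates: centroid of each cluster's pixels
  verts <- matrix(0, n_clusters, 2)
  for (k in seq_len(n_clusters)) {
    sel <- cluster == k
    verts[k, ] <- c(mean(pr[sel]), mean(pc[sel]))
  }
  # connected components of the cluster graph
  parent <- seq_len(n_clusters)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (e in seq_along(edges_from)) {
    a <- findp(edges_from[e]); b <- findp(edges_to[e])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  comps <- length(unique(vapply(seq_len(n_clusters), findp, integer(1))))
  new_vascular_graph(verts,
                     data.frame(from = edges_from, to = edges_to,
                                length = edges_len),
                     comps)
}

#' Write a vascular graph as a CSV edge list
#' @param graph a `vascular_graph`; `path` file path.
#' @export
write_graph_csv <- function(graph, path) {
  write.csv(graph$edges, path, row.names = FALSE)
  invisible(path)
}
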