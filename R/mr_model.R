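# MR forward model: orthonormal centered 2D Fourier encoding, variable
# density Poisson-disc sampling masks under a partial-Fourier constraint,
# noisy acquisition and conjugate-symmetric filling.
#
# k-space is stored DC-centered (DC at row/col N/2 + 1); phase-encode
# lines are matrix rows.

circshift <- function(m, s1, s2 = s1) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[((seq_len(n1) - 1 - s1) %% n1) + 1, ((seq_len(n2) - 1 - s2) %% n2) + 1]
}

fftshift2 <- function(m) circshift(m, floor(nrow(m) / 2), floor(ncol(m) / 2))
ifftshift2 <- function(m) circshift(m, ceiling(nrow(m) / 2), ceiling(ncol(m) / 2))

#' Orthonormal centered 2D Fourier transform
#'
#' Maps a (real or complex) square image to DC-centered k-space and back.
#' The adjoint is the exact inverse on full data (unitary scaling 1/N).
#'
#' @param x square numeric or complex matrix (image for `"forward"`,
#'   k-space for `"adjoint"`).
#' @param direction `"forward"` (image to k-space) or `"adjoint"`.
#' @return complex matrix of the same shape.
#' @export
fourier_encode <- function(x, direction = c("forward", "adjoint")) {
  direction <- match.arg(direction)
  if (!is.matrix(x) || nrow(x) != ncol(x)) stop("square grid required")
  n <- nrow(x)
  if (direction == "forward") {
    fftshift2(stats::fft(ifftshift2(x))) / n
  } else {
    fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / n
  }
}

#' Variable-density Poisson-disc sampling mask with partial Fourier
#'
#' Dart-throwing in seeded random order with a radially increasing local
#' minimum-distance profile (denser near DC, radial power law). Rows beyond
#' the partial-Fourier extent are never acquired. The global scale of the
#' radius profile is calibrated by bisection so the acquired fraction is
#' within +/-10 percent (relative) of `target_fraction`. Deterministic per
#' seed.
#'
#' @param grid_size k-space grid dimension.
#' @param target_fraction fraction of k-space to acquire, in (0, 1].
#' @param partial_fourier_fraction acquired extent of phase-encode rows, in
#'   (0.5, 1]; rows beyond `ceiling(pf * N)` are excluded.
#' @param seed integer seed.
#' @param density_power exponent of the radial power-law density (default 2).
#' @return A `sampling_mask`: list with `mask` (logical matrix),
#'   `acquisition_order` (linear indices in acceptance order),
#'   `partial_fourier_fraction`, `radius_profile` (function of k-space
#'   radius), `grid_size`.
#' @export
build_sampling_mask <- function(grid_size, target_fraction,
                                partial_fourier_fraction = 1.0, seed = 1,
                                density_power = 2) {
  stopifnot(grid_size >= 8)
  if (target_fraction <= 0 || target_fraction > 1)
    stop("target_fraction must be in (0, 1]")
  if (partial_fourier_fraction <= 0.5 || partial_fourier_fraction > 1)
    stop("partial_fourier_fraction must be in (0.5, 1]")
  if (target_fraction > partial_fourier_fraction)
    stop("infeasible: target_fraction exceeds partial_fourier_fraction")
  n <- grid_size
  pf_rows <- ceiling(partial_fourier_fraction * n)
  ctr <- n / 2 + 1
  rows <- matrix(rep(seq_len(n), times = n), n, n)
  cols <- matrix(rep(seq_len(n), each = n), n, n)
  rho <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
  rho_max <- max(rho)
  allowed <- rows <= pf_rows
  profile_shape <- 1 + 4 * (rho / rho_max)^density_power

  if (target_fraction == 1 && partial_fourier_fraction == 1) {
    mask <- matrix(TRUE, n, n)
    return(new_sampling_mask(mask, which(mask), partial_fourier_fraction,
                             local({p <- density_power; rm <- rho_max
                                    function(r) 0 * r}), n))
  }

  cand <- with_seed(seed, sample(which(allowed)))
  throw <- function(r0) {
    racc <- matrix(FALSE, n, n)
    acc_order <- integer()
    for (p in cand) {
      pr <- ((p - 1) %% n) + 1; pc <- ((p - 1) %/% n) + 1
      r_local <- r0 * profile_shape[p]
      w <- ceiling(r_local)
      r1 <- max(1, pr - w); r2 <- min(n, pr + w)
      c1 <- max(1, pc - w); c2 <- min(n, pc + w)
      sub <- racc[r1:r2, c1:c2]
      ok <- TRUE
      if (any(sub)) {
        hit <- which(sub)
        hr <- ((hit - 1) %% (r2 - r1 + 1)) + r1
        hc <- ((hit - 1) %/% (r2 - r1 + 1)) + c1
        if (any((hr - pr)^2 + (hc - pc)^2 < r_local^2)) ok <- FALSE
      }
      if (ok) {
        racc[pr, pc] <- TRUE
        acc_order <- c(acc_order, p)
      }
    }
    list(mask = racc, order = acc_order)
  }
  target_n <- target_fraction * n * n
  lo <- 0.05; hi <- 8
  best <- NULL; r0_best <- NA_real_
  for (it in 1:12) {
    mid <- sqrt(lo * hi)
    res <- throw(mid)
    got <- length(res$order)
    if (is.null(best) || abs(got - target_n) < abs(length(best$order) - target_n)) {
      best <- res; r0_best <- mid
    }
    if (abs(got - target_n) / target_n < 0.05) { best <- res; r0_best <- mid; break }
    if (got > target_n) lo <- mid else hi <- mid
  }
  prof <- local({
    s <- r0_best; pw <- density_power; rm <- rho_max
    function(r) s * (1 + 4 * (r / rm)^pw)
  })
  new_sampling_mask(best$mask, best$order, partial_fourier_fraction, prof, n)
}

new_sampling_mask <- function(mask, order, pf, profile, grid_size) {
  structure(list(mask = mask, acquisition_order = order,
                 partial_fourier_fraction = pf,
                 min_distance_profile = profile,
                 grid_size = grid_size),
            class = "sampling_mask")
}

#' Build a line (phase-encode row) sampling mask
#'
#' The acquisition unit of the closed-loop controller is a whole row of
#' k-space; this constructs the corresponding mask.
#'
#' @param lines integer row indices to acquire.
#' @param grid_size k-space dimension.
#' @param partial_fourier_fraction rows beyond this extent are rejected.
#' @export
line_sampling_mask <- function(lines, grid_size,
                               partial_fourier_fraction = 1.0) {
  pf_rows <- ceiling(partial_fourier_fraction * grid_size)
  lines <- sort(unique(as.integer(lines)))
  if (length(lines) && (min(lines) < 1 || max(lines) > grid_size))
    stop("line indices out of range")
  if (any(lines > pf_rows))
    stop("lines beyond the partial-Fourier extent cannot be acquired")
  mask <- matrix(FALSE, grid_size, grid_size)
  mask[lines, ] <- TRUE
  new_sampling_mask(mask, lines, partial_fourier_fraction, NULL, grid_size)
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("Sampling mask %dx%d: %.1f%% acquired, partial Fourier %.3f\n",
              x$grid_size, x$grid_size, 100 * mean(x$mask),
              x$partial_fourier_fraction))
  invisible(x)
}

#' Read/write a sampling mask as CSV
#'
#' Point masks are stored as (row, col) pairs of acquired entries; line
#' masks as their row indices only.
#' @param mask a `sampling_mask`; `path` a file path.
#' @export
write_mask_csv <- function(mask, path) {
  idx <- which(mask$mask, arr.ind = TRUE)
  write.csv(data.frame(row = idx[, 1], col = idx[, 2]), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_mask_csv
#' @param grid_size k-space dimension of the stored mask.
#' @param partial_fourier_fraction declared partial-Fourier extent.
#' @export
read_mask_csv <- function(path, grid_size, partial_fourier_fraction = 1.0) {
  df <- read.csv(path)
  m <- matrix(FALSE, grid_size, grid_size)
  m[cbind(df$row, df$col)] <- TRUE
  new_sampling_mask(m, which(m), partial_fourier_fraction, NULL, grid_size)
}

#' Simulate noisy undersampled k-space acquisition
#'
#' `y = mask * (kspace_full + noise)` with complex white Gaussian noise of
#' total variance `noise_sigma^2` per sample; off-mask entries are exactly
#' zero. Deterministic per seed.
#'
#' @param kspace_full complex matrix (full k-space of the object).
#' @param mask a `sampling_mask` (or logical matrix) of the same shape.
#' @param noise_sigma standard deviation of the complex noise (>= 0).
#' @param seed integer seed.
#' @return complex matrix with zeros off-mask.
#' @export
acquire <- function(kspace_full, mask, noise_sigma = 0, seed = 1) {
  m <- if (inherits(mask, "sampling_mask")) mask$mask else mask
  if (!all(dim(m) == dim(kspace_full))) stop("shape mismatch")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  n <- length(kspace_full)
  noise <- if (noise_sigma > 0) {
    with_seed(seed, complex(real = rnorm(n, 0, noise_sigma / sqrt(2)),
                            imaginary = rnorm(n, 0, noise_sigma / sqrt(2))))
  } else 0
  y <- (kspace_full + noise) * m
  y[!m] <- 0
  y
}

#' Conjugate-symmetric (partial Fourier) filling of measured k-space
#'
#' Assuming a real-valued underlying image (zero phase), unacquired entries
#' whose Hermitian mirror was acquired are filled with the conjugate of the
#' mirrored sample; acquired entries are untouched.
#'
#' @param measured complex k-space with zeros off-mask.
#' @param mask a `sampling_mask` or logical matrix marking acquired entries.
#' @return complex matrix; attribute `"filled_mask"` marks all known entries.
#' @export
conjugate_fill <- function(measured, mask) {
  m <- if (inherits(mask, "sampling_mask")) mask$mask else mask
  n <- nrow(measured)
  stopifnot(ncol(measured) == n, all(dim(m) == n))
  idx <- seq_len(n)
  mir <- ((2 * (n %/% 2) - (idx - 1)) %% n) + 1   # mirror about DC at n/2+1
  mir_mat_r <- matrix(mir[rep(idx, times = n)], n, n)
  mir_mat_c <- matrix(mir[rep(idx, each = n)], n, n)
  mirror_lin <- mir_mat_r + (mir_mat_c - 1) * n
  fillable <- !m & matrix(m[mirror_lin], n, n)
  out <- measured
  out[fillable] <- Conj(measured[mirror_lin][fillable])
  attr(out, "filled_mask") <- m | fillable
  out
}
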