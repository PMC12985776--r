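# Coupled MR-PET variational reconstruction: least-squares k-space fidelity
# with isotropic TV and an optional structured Hankel low-rank projection on
# the MR side; Poisson likelihood with TV and an edge-weighted cross-modal
# coupling on the PET side. Solved by alternating proximal-gradient (MR) and
# one-step-late EM surrogate (PET) updates.

fdiff <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  dx <- rbind(m[-1, , drop = FALSE] - m[-n1, , drop = FALSE],
              matrix(0, 1, n2))
  dy <- cbind(m[, -1, drop = FALSE] - m[, -n2, drop = FALSE],
              matrix(0, n1, 1))
  list(dx = dx, dy = dy)
}

fdiv <- function(px, py) {
  # negative adjoint of fdiff: div(p) such that <grad u, p> = -<u, div p>
  n1 <- nrow(px); n2 <- ncol(px)
  dx <- px - rbind(matrix(0, 1, n2), px[-n1, , drop = FALSE])
  dx[n1, ] <- -px[n1 - 1, ]
  dx[1, ] <- px[1, ]
  dy <- py - cbind(matrix(0, n1, 1), py[, -n2, drop = FALSE])
  dy[, n2] <- -py[, n2 - 1]
  dy[, 1] <- py[, 1]
  dx + dy
}

#' Isotropic total variation of an image
#'
#' Forward differences with Neumann boundaries; for complex images the
#' per-pixel gradient magnitude uses complex moduli.
#' @param m numeric or complex matrix.
#' @export
tv_value <- function(m) {
  g <- fdiff(m)
  sum(sqrt(Mod(g$dx)^2 + Mod(g$dy)^2))
}

# smoothed isotropic TV gradient (for one-step-late EM)
tv_grad <- function(m, eps = 1e-6) {
  g <- fdiff(m)
  mag <- sqrt(g$dx^2 + g$dy^2 + eps^2)
  -fdiv(g$dx / mag, g$dy / mag)
}

# prox of lambda * TV via Chambolle's dual projection algorithm; the dual
# field inherits the input type (complex for complex images) and the
# projection is modulus-based, so the prox is equivariant under a global
# phase of the input
prox_tv <- function(v, lambda, n_iter = 10, tau = 0.249) {
  if (lambda <= 0) return(v)
  n1 <- nrow(v); n2 <- ncol(v)
  zero <- if (is.complex(v)) 0i else 0
  px <- matrix(zero, n1, n2); py <- matrix(zero, n1, n2)
  for (i in seq_len(n_iter)) {
    u <- fdiv(px, py) - v / lambda
    g <- fdiff(u)
    denom <- 1 + tau * sqrt(Mod(g$dx)^2 + Mod(g$dy)^2)
    px <- (px + tau * g$dx) / denom
    py <- (py + tau * g$dy) / denom
  }
  v - lambda * fdiv(px, py)
}

prox_tv_real <- function(v, lambda, n_iter = 10) prox_tv(v, lambda, n_iter)

#' Regularization weights of the joint reconstruction objective
#'
#' @param lambda1 MR TV prior weight in `[0, 1]`.
#' @param lambda2 PET TV prior weight in `[0, 1]`.
#' @param lambda3 cross-modal coupling weight in `[0, 1]`.
#' @param hankel_rank integer rank of the structured Hankel low-rank
#'   projection, or `NULL` to disable it.
#' @param hankel_weight relaxation weight (>= 0) of the Hankel projection.
#' @export
recon_weights <- function(lambda1 = 0.02, lambda2 = 0.05, lambda3 = 0.3,
                          hankel_rank = NULL, hankel_weight = 0) {
  stopifnot(lambda1 >= 0, lambda1 <= 1, lambda2 >= 0, lambda2 <= 1,
            lambda3 >= 0, lambda3 <= 1, hankel_weight >= 0)
  if (!is.null(hankel_rank) && hankel_rank < 1)
    stop("hankel_rank must be >= 1 when enabled")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 hankel_rank = hankel_rank, hankel_weight = hankel_weight),
            class = "recon_weights")
}

#' Negative Poisson log-likelihood of PET counts
#'
#' `1'(Ax + r) - y' log(Ax + r)`; convex in the activity `x`.
#'
#' @param x activity (matrix or vector).
#' @param sino a `sinogram`.
#' @param system optional system matrix overriding the parallel-beam
#'   operator (rows in angle-major bin order).
#' @export
poisson_nll <- function(x, sino, system = NULL) {
  stopifnot(inherits(sino, "sinogram"))
  A <- if (is.null(system)) {
    radon_operator(if (is.matrix(x)) nrow(x) else as.integer(sqrt(length(x))),
                   sino$angles, ncol(sino$counts))
  } else system
  lam <- as.numeric(A %*% as.numeric(x)) + sino$randoms_rate
  y <- as.numeric(t(sino$counts))
  if (any(lam <= 0 & y > 0))
    stop("domain error: zero expected counts where observed counts > 0")
  sum(lam) - sum(y[y > 0] * log(lam[y > 0]))
}

#' Edge-weighted cross-modal coupling term
#'
#' `sum_i w_i(u) * |grad x|_i` with weights `w_i = exp(-|grad u|_i / eta)`:
#' PET total variation discounted where the MR image has edges, so PET
#' gradients are encouraged to align with MR edges. Returns the value and
#' its (smoothed) gradient in `x`.
#'
#' @param u MR image (complex allowed; edges taken on the magnitude).
#' @param x_pet PET activity matrix of the same shape.
#' @param eta edge-weight bandwidth; default is the median nonzero MR
#'   gradient magnitude of the current iterate.
#' @param eps smoothing constant for the gradient.
#' @return list with `value`, `grad` (matrix), and the `eta` used.
#' @export
coupling_term <- function(u, x_pet, eta = NULL, eps = 1e-6) {
  stopifnot(all(dim(u) == dim(x_pet)))
  gu <- fdiff(Mod(u))
  gmag <- sqrt(gu$dx^2 + gu$dy^2)
  if (is.null(eta)) {
    nz <- gmag[gmag > 0]
    eta <- if (length(nz)) median(nz) else 1
  }
  w <- exp(-gmag / eta)
  gx <- fdiff(x_pet)
  mag <- sqrt(gx$dx^2 + gx$dy^2)
  value <- sum(w * mag)
  smag <- sqrt(gx$dx^2 + gx$dy^2 + eps^2)
  grad <- -fdiv(w * gx$dx / smag, w * gx$dy / smag)
  list(value = value, grad = grad, eta = eta)
}

#' Structured Hankel low-rank projection of k-space
#'
#' Each k-space row is lifted to a Hankel matrix with window `patch`, its SVD
#' truncated to `rank`, and the matrix mapped back by anti-diagonal
#' averaging. Idempotent (within tolerance) on already rank-deficient rows.
#'
#' @param kspace complex matrix.
#' @param patch Hankel window length (default `floor(ncol/4)`).
#' @param rank truncation rank; must not exceed the smaller Hankel dimension.
#' @export
hankel_project <- function(kspace, patch = NULL, rank = 8) {
  n <- ncol(kspace)
  if (is.null(patch)) patch <- max(2L, floor(n / 4))
  ncols <- n - patch + 1
  if (rank < 1 || rank > min(patch, ncols))
    stop("rank must be in [1, min Hankel dimension]")
  out <- kspace
  for (i in seq_len(nrow(kspace))) {
    v <- kspace[i, ]
    H <- matrix(0i, patch, ncols)
    for (k in seq_len(patch)) H[k, ] <- v[k:(k + ncols - 1)]
    sv <- svd(H)
    d <- sv$d
    d[-seq_len(min(rank, length(d)))] <- 0
    Hr <- sv$u %*% (d * Conj(t(sv$v)))
    rec <- rep(0i, n); cnt <- rep(0, n)
    for (k in seq_len(patch)) {
      pos <- k:(k + ncols - 1)
      rec[pos] <- rec[pos] + Hr[k, ]
      cnt[pos] <- cnt[pos] + 1
    }
    out[i, ] <- rec / cnt
  }
  out
}

#' Joint MR-PET objective value with per-term breakdown
#'
#' `||mask (F u) - y||^2 + lambda1 TV(u) + NLL_PET(x; y_PET) +
#'  lambda2 TV(x) + lambda3 C(u, x)`.
#'
#' @param state a `recon_state` or a list with elements `u` and `x_pet`.
#' @param y_mr measured k-space (zeros off-mask).
#' @param mask `sampling_mask` or logical matrix.
#' @param sino a `sinogram`.
#' @param weights a [recon_weights()] object.
#' @param system optional PET system matrix.
#' @param eta coupling bandwidth (default: median rule inside
#'   [coupling_term()]).
#' @return list of `total`, `mr_fid`, `tv_mr`, `pet_nll`, `tv_pet`,
#'   `coupling`.
#' @export
joint_objective <- function(state, y_mr, mask, sino, weights,
                            system = NULL, eta = NULL) {
  m <- if (inherits(mask, "sampling_mask")) mask$mask else mask
  u <- state$u; x <- state$x_pet
  resid <- (fourier_encode(u, "forward") - y_mr) * m
  mr_fid <- sum(Mod(resid)^2)
  tv_mr <- tv_value(u)
  nll <- poisson_nll(x, sino, system = system)
  tv_pet <- tv_value(x)
  cpl <- if (weights$lambda3 > 0) coupling_term(u, x, eta = eta)$value else 0
  total <- mr_fid + weights$lambda1 * tv_mr + nll +
    weights$lambda2 * tv_pet + weights$lambda3 * cpl
  list(total = total, mr_fid = mr_fid, tv_mr = tv_mr, pet_nll = nll,
       tv_pet = tv_pet, coupling = cpl)
}

#' Solve the joint MR-PET reconstruction problem
#'
#' Alternating scheme: proximal gradient on the MR image (data-consistency
#' gradient step, optional relaxed Hankel projection, TV prox) and a
#' one-step-late EM surrogate on the PET activity carrying the TV and
#' coupling gradients in its denominator (multiplicative, hence
#' non-negative). Conjugate-symmetric filling is applied to the measured
#' k-space first (phantoms are real-valued).
#'
#' @param y_mr measured complex k-space (zeros off-mask).
#' @param mask `sampling_mask` or logical matrix of acquired entries.
#' @param sino a `sinogram` of PET counts.
#' @param weights a [recon_weights()] object.
#' @param n_outer outer iterations.
#' @param seed integer seed (reserved; the solver itself is deterministic).
#' @param init optional list with starting `u` and/or `x_pet`.
#' @param conj_fill apply [conjugate_fill()] before reconstruction.
#' @param n_em_inner EM sub-iterations per outer iteration.
#' @param system optional PET system matrix.
#' @return A `recon_state`: `u` (complex image), `x_pet` (non-negative
#'   activity), `objective_trace` (data frame of per-iteration terms),
#'   `iteration`, `converged`.
#' @export
solve_joint <- function(y_mr, mask, sino, weights = recon_weights(),
                        n_outer = 20, seed = 0, init = NULL,
                        conj_fill = TRUE, n_em_inner = 1, system = NULL) {
  m <- if (inherits(mask, "sampling_mask")) mask$mask else mask
  n <- nrow(y_mr)
  stopifnot(ncol(y_mr) == n, all(dim(m) == dim(y_mr)))
  if (conj_fill) {
    y <- conjugate_fill(y_mr, m)
    known <- attr(y, "filled_mask")
    attr(y, "filled_mask") <- NULL
  } else {
    y <- y_mr; known <- m
  }
  A <- if (is.null(system)) radon_operator(n, sino$angles,
                                           ncol(sino$counts)) else system
  ycounts <- as.numeric(t(sino$counts))
  r <- sino$randoms_rate
  sens <- as.numeric(Matrix::crossprod(A, rep(1, nrow(A))))
  u <- if (!is.null(init$u)) init$u else fourier_encode(y, "adjoint")
  x <- if (!is.null(init$x_pet)) as.numeric(init$x_pet) else rep(1, n * n)
  x <- pmax(x, 1e-8)
  eps <- 1e-12
  trace <- vector("list", n_outer)
  for (it in seq_len(n_outer)) {
    # --- MR proximal-gradient step (Lipschitz constant 2, step 1/2) ---
    ku <- fourier_encode(u, "forward")
    u <- u - fourier_encode((ku - y) * known, "adjoint")
    if (!is.null(weights$hankel_rank) && weights$hankel_weight > 0) {
      ku <- fourier_encode(u, "forward")
      kh <- hankel_project(ku, rank = weights$hankel_rank)
      ku <- (1 - weights$hankel_weight) * ku + weights$hankel_weight * kh
      u <- fourier_encode(ku, "adjoint")
    }
    if (weights$lambda1 > 0) u <- prox_tv(u, 0.5 * weights$lambda1)
    # --- PET one-step-late EM with TV + coupling in the denominator ---
    xm <- matrix(x, n, n)
    pen <- 0
    if (weights$lambda2 > 0) pen <- pen + weights$lambda2 * tv_grad(xm)
    if (weights$lambda3 > 0)
      pen <- pen + weights$lambda3 * coupling_term(u, xm)$grad
    for (em in seq_len(n_em_inner)) {
      proj <- as.numeric(A %*% x) + r
      ratio <- ycounts / pmax(proj, eps)
      num <- as.numeric(Matrix::crossprod(A, ratio))
      denom <- sens + as.numeric(pen)
      denom <- pmax(denom, 0.1 * pmax(sens, eps))
      upd <- num / pmax(denom, eps)
      upd[sens <= eps] <- 1
      x <- pmax(x * upd, 0)
    }
    st <- list(u = u, x_pet = matrix(x, n, n))
    trace[[it]] <- joint_objective(st, y_mr, known, sino, weights,
                                   system = system)
    trace[[it]]$iteration <- it
  }
  tr <- do.call(rbind, lapply(trace, as.data.frame))
  tr <- tr[, c("iteration", "total", "mr_fid", "tv_mr", "pet_nll",
               "tv_pet", "coupling")]
  converged <- if (n_outer >= 2) {
    abs(tr$total[n_outer] - tr$total[n_outer - 1]) <=
      1e-3 * abs(tr$total[n_outer - 1])
  } else TRUE
  structure(list(u = u, x_pet = matrix(x, n, n), objective_trace = tr,
                 iteration = n_outer, converged = converged,
                 weights = weights),
            class = "recon_state")
}

#' @export
print.recon_state <- function(x, ...) {
  cat(sprintf("Joint reconstruction: %d iterations, objective %.4g (%s)\n",
              x$iteration, utils::tail(x$objective_trace$total, 1),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
plot.recon_state <- function(x, ...) {
  graphics::plot(x$objective_trace$iteration, x$objective_trace$total,
                 type = "b", xlab = "iteration", ylab = "objective", ...)
  invisible(x)
}

# Fast approximate MR reconstruction used for one-step look-ahead:
# zero-fill + conjugate fill + light TV smoothing of the magnitude.
cheap_recon <- function(y_mr, mask, tv_lambda = 0.02, n_iter = 5) {
  m <- if (inherits(mask, "sampling_mask")) mask$mask else mask
  y <- conjugate_fill(y_mr, m)
  attr(y, "filled_mask") <- NULL
  mag <- Mod(fourier_encode(y, "adjoint"))
  if (tv_lambda > 0) mag <- prox_tv_real(mag, tv_lambda, n_iter)
  mag
}
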