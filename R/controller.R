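# Closed-loop acquisition control: topological reward, action spaces over
# k-space line bundles and PET angle blocks, greedy one-step look-ahead,
# and a small actor-critic policy trained by temporal-difference learning.

#' Reward configuration for the closed-loop controller
#'
#' The immediate reward is
#' `R_t = -alpha * U_t - beta * T_t - gamma_smooth * ||x_t - x_prev||^2`,
#' trading off topological fidelity, cumulative acquisition time and
#' reconstruction stability. The smoothness weight is named `gamma_smooth`
#' to keep it distinct from the reinforcement-learning discount factor.
#'
#' @param alpha weight on topological uncertainty (>= 0).
#' @param beta weight on cumulative acquisition time (>= 0).
#' @param gamma_smooth weight on the squared inter-iteration image change.
#' @param time_per_line,time_per_angle cost of one phase-encode line / one
#'   projection angle, in fractions of the full acquisition.
#' @export
reward_config <- function(alpha = 1, beta = 0.1, gamma_smooth = 0.1,
                          time_per_line = NA, time_per_angle = NA) {
  stopifnot(alpha >= 0, beta >= 0, gamma_smooth >= 0)
  structure(list(alpha = alpha, beta = beta, gamma_smooth = gamma_smooth,
                 time_per_line = time_per_line,
                 time_per_angle = time_per_angle),
            class = "reward_config")
}

#' Immediate reward of the closed-loop controller
#'
#' @param u_t current topological uncertainty `U_t`.
#' @param t_cost cumulative acquisition time `T_t` (in budget fractions).
#' @param x_t,x_prev current and previous reconstruction (same shape).
#' @param cfg a [reward_config()].
#' @return scalar reward (non-positive for non-negative inputs).
#' @export
reward <- function(u_t, t_cost, x_t, x_prev, cfg = reward_config()) {
  stopifnot(all(dim(x_t) == dim(x_prev)))
  -cfg$alpha * u_t - cfg$beta * t_cost -
    cfg$gamma_smooth * sum(Mod(x_t - x_prev)^2)
}

#' Candidate action space over unacquired measurements
#'
#' MR candidates are disjoint bundles of consecutive unacquired phase-encode
#' lines (within the partial-Fourier extent); PET candidates are disjoint
#' blocks of consecutive unmeasured projection angles. Candidates never
#' overlap the visited set.
#'
#' @param acquired_lines integer row indices already acquired.
#' @param acquired_angles angles (degrees) already measured.
#' @param grid_size k-space dimension.
#' @param all_angles the full angle set of the scanner geometry.
#' @param partial_fourier_fraction rows beyond this extent are not
#'   candidates.
#' @param line_bundle,angle_block bundle/block sizes.
#' @return An `action_space`: list of `candidates` (each with `type`
#'   `"mr"` or `"pet"`, `id`, and the `lines` or `angles` it acquires) and
#'   the `visited` sets.
#' @export
build_action_space <- function(acquired_lines, acquired_angles, grid_size,
                               all_angles,
                               partial_fourier_fraction = 0.625,
                               line_bundle = 8, angle_block = 5) {
  pf_rows <- ceiling(partial_fourier_fraction * grid_size)
  free_lines <- setdiff(seq_len(pf_rows), acquired_lines)
  cands <- list()
  if (length(free_lines)) {
    grp <- split(free_lines, ceiling(seq_along(free_lines) / line_bundle))
    for (k in seq_along(grp)) {
      cands[[length(cands) + 1]] <-
        list(type = "mr", lines = grp[[k]])
    }
  }
  free_angles <- setdiff(all_angles, acquired_angles)
  if (length(free_angles)) {
    grp <- split(free_angles, ceiling(seq_along(free_angles) / angle_block))
    for (k in seq_along(grp)) {
      cands[[length(cands) + 1]] <-
        list(type = "pet", angles = grp[[k]])
    }
  }
  for (k in seq_along(cands)) cands[[k]]$id <- k
  structure(list(candidates = cands,
                 visited = list(lines = acquired_lines,
                                angles = acquired_angles),
                 grid_size = grid_size, all_angles = all_angles),
            class = "action_space")
}

#' Greedy one-step look-ahead action selection
#'
#' Evaluates every candidate with a cheap provisional reconstruction and
#' returns the candidate whose acquisition yields the smallest expected
#' topological uncertainty; ties are broken by lowest candidate index.
#'
#' @param state numeric state descriptor (see [controller_descriptor()]);
#'   its `U` entry is used as the no-improvement baseline for candidates
#'   that do not change the MR data.
#' @param actions an [build_action_space()] object with >= 1 candidate.
#' @param lookahead_recon function(candidate) returning the uncertainty
#'   after provisionally acquiring that candidate.
#' @return the selected candidate (list with `type`, `id`, ...), with the
#'   expected uncertainty in `$expected_u`.
#' @export
greedy_select <- function(state, actions, lookahead_recon) {
  cands <- actions$candidates
  if (!length(cands)) stop("empty candidate set")
  us <- vapply(cands, lookahead_recon, numeric(1))
  best <- which.min(us)               # which.min takes the first minimum
  out <- cands[[best]]
  out$expected_u <- us[best]
  out
}

#' Fixed-length controller state descriptor
#'
#' `(b0, b1, total persistence deg 0, total persistence deg 1, U_t,
#'   budget fraction used, fraction of lines acquired, fraction of angles
#'   acquired)` -- the numerical summary of the evolving image topology and
#'   acquisition status that conditions the policy.
#'
#' @param d_t current persistence diagram.
#' @param u_t current topological uncertainty.
#' @param budget_used,frac_lines,frac_angles acquisition status in `[0,1]`.
#' @param noise_floor persistence floor for Betti counting.
#' @export
controller_descriptor <- function(d_t, u_t, budget_used, frac_lines,
                                  frac_angles, noise_floor = 0.1) {
  b <- betti_from_diagram(d_t, noise_floor)
  pers <- d_t$death - d_t$birth
  c(b0 = unname(b[1]), b1 = unname(b[2]),
    pers0 = sum(pers[d_t$degree == 0]), pers1 = sum(pers[d_t$degree == 1]),
    u = u_t, budget = budget_used, lines = frac_lines, angles = frac_angles)
}

# ---------------------------------------------------------------------------
# Actor-critic policy: per-candidate scoring MLP (actor) + state-value MLP
# (critic), both single-hidden-layer tanh networks with hand-written
# gradients.
# ---------------------------------------------------------------------------

#' Initialize an actor-critic policy model
#'
#' The actor scores each candidate from the concatenation of the state
#' descriptor and a small candidate feature vector, and turns scores into a
#' categorical distribution by softmax; the critic predicts the state value
#' `V(s)`. Both are one-hidden-layer tanh perceptrons.
#'
#' @param state_dim length of the state descriptor.
#' @param cand_dim length of the candidate feature vector.
#' @param hidden hidden units.
#' @param discount_factor RL discount in `(0, 1]`.
#' @param seed integer seed for weight initialization.
#' @export
policy_model <- function(state_dim = 8, cand_dim = 4, hidden = 16,
                         discount_factor = 0.99, seed = 1) {
  stopifnot(discount_factor > 0, discount_factor <= 1)
  d <- state_dim + cand_dim
  with_seed(seed, {
    structure(list(
      W1 = matrix(rnorm(hidden * d, 0, 0.3 / sqrt(d)), hidden, d),
      b1 = rep(0, hidden),
      w2 = rnorm(hidden, 0, 0.3 / sqrt(hidden)),
      b2 = 0,
      Vw1 = matrix(rnorm(hidden * state_dim, 0, 0.3 / sqrt(state_dim)),
                   hidden, state_dim),
      Vb1 = rep(0, hidden),
      Vw2 = rnorm(hidden, 0, 0.3 / sqrt(hidden)),
      Vb2 = 0,
      state_dim = state_dim, cand_dim = cand_dim, hidden = hidden,
      discount_factor = discount_factor), class = "policy_model")
  })
}

# candidate features: type one-hot, normalized position, normalized size
candidate_features <- function(cand, grid_size, all_angles) {
  if (cand$type == "mr") {
    pos <- abs(mean(cand$lines) - (grid_size / 2 + 1)) / (grid_size / 2)
    c(1, 0, pos, length(cand$lines) / 8)
  } else {
    pos <- mean(cand$angles) / 180
    c(0, 1, pos, length(cand$angles) / 5)
  }
}

actor_scores <- function(policy, state, feats) {
  # feats: n_cand x cand_dim matrix
  n <- nrow(feats)
  X <- cbind(matrix(rep(state, each = n), n), feats)  # n x (sd + cd)
  H <- tanh(X %*% t(policy$W1) + rep(policy$b1, each = n))
  s <- as.numeric(H %*% policy$w2) + policy$b2
  list(scores = s, H = H, X = X)
}

#' Action probabilities of the policy for a candidate set
#'
#' @param policy a [policy_model()].
#' @param state numeric state descriptor.
#' @param feats matrix of per-candidate features (rows = candidates).
#' @return probability vector summing to one.
#' @export
policy_probs <- function(policy, state, feats) {
  s <- actor_scores(policy, state, feats)$scores
  e <- exp(s - max(s))
  e / sum(e)
}

critic_value <- function(policy, state) {
  h <- tanh(as.numeric(policy$Vw1 %*% state) + policy$Vb1)
  sum(policy$Vw2 * h) + policy$Vb2
}

# gradient of log pi(a | s) in the actor parameters
actor_logp_grad <- function(policy, state, feats, a) {
  fw <- actor_scores(policy, state, feats)
  s <- fw$scores
  e <- exp(s - max(s)); p <- e / sum(e)
  n <- nrow(feats)
  coef <- -p; coef[a] <- coef[a] + 1      # d logpi / d score_k
  dh <- 1 - fw$H^2                         # n x hidden
  gW1 <- matrix(0, policy$hidden, ncol(fw$X))
  gb1 <- rep(0, policy$hidden)
  gw2 <- rep(0, policy$hidden)
  gb2 <- sum(coef)
  for (k in seq_len(n)) {
    if (coef[k] == 0) next
    hk <- fw$H[k, ]; xk <- fw$X[k, ]
    gw2 <- gw2 + coef[k] * hk
    back <- coef[k] * policy$w2 * dh[k, ]
    gW1 <- gW1 + outer(back, xk)
    gb1 <- gb1 + back
  }
  list(W1 = gW1, b1 = gb1, w2 = gw2, b2 = gb2, probs = p)
}

#' One actor-critic update from a trajectory
#'
#' Temporal-difference learning: the critic is regressed toward the TD
#' target (reward plus discounted value of the next state), and the actor
#' ascends `grad log pi(a|s) * advantage` with the TD error as advantage
#' estimate.
#'
#' @param trajectory list of steps, each a list with `state` (descriptor),
#'   `feats` (candidate feature matrix), `action` (chosen index), `reward`,
#'   and optionally `next_state` (`NULL` for terminal).
#' @param policy a [policy_model()].
#' @param lr_actor,lr_critic learning rates.
#' @return list with the updated `policy`, mean squared TD error
#'   `critic_loss`, and mean `advantage`.
#' @export
actor_critic_update <- function(trajectory, policy, lr_actor = 1e-3,
                                lr_critic = 1e-2) {
  if (!length(trajectory)) stop("trajectory must be non-empty")
  gam <- policy$discount_factor
  td_errs <- numeric(length(trajectory))
  for (i in seq_along(trajectory)) {
    step <- trajectory[[i]]
    v <- critic_value(policy, step$state)
    vnext <- if (is.null(step$next_state)) 0
             else critic_value(policy, step$next_state)
    target <- step$reward + gam * vnext
    adv <- target - v
    td_errs[i] <- adv
    if (!is.finite(adv)) stop("non-finite TD error")
    # actor ascent
    if (adv != 0) {
      g <- actor_logp_grad(policy, step$state, step$feats, step$action)
      policy$W1 <- policy$W1 + lr_actor * adv * g$W1
      policy$b1 <- policy$b1 + lr_actor * adv * g$b1
      policy$w2 <- policy$w2 + lr_actor * adv * g$w2
      policy$b2 <- policy$b2 + lr_actor * adv * g$b2
    }
    # critic descent on squared TD error (semi-gradient)
    h <- tanh(as.numeric(policy$Vw1 %*% step$state) + policy$Vb1)
    dh <- 1 - h^2
    policy$Vw2 <- policy$Vw2 + lr_critic * adv * h
    policy$Vb2 <- policy$Vb2 + lr_critic * adv
    back <- adv * policy$Vw2 * dh
    policy$Vw1 <- policy$Vw1 + lr_critic * outer(back, step$state)
    policy$Vb1 <- policy$Vb1 + lr_critic * back
    if (any(!is.finite(policy$w2)) || any(!is.finite(policy$Vw2)))
      stop("non-finite policy parameters after update")
  }
  list(policy = policy, critic_loss = mean(td_errs^2),
       advantage = mean(td_errs))
}

#' Configuration of the closed acquisition-reconstruction loop
#'
#' Defaults define the simulated scanner: 60 projection angles (3-degree
#' spacing), k-space noise, count budget, warm-start coverage, bundle
#' sizes, reconstruction effort per step, and the topological uncertainty
#' metric (weights, Wasserstein order, sliced projections, persistence
#' noise floor).
#'
#' @param noise_sigma complex k-space noise standard deviation (image scale
#'   is `[0, 1]`).
#' @param total_counts expected total PET counts over the full angle set.
#' @param randoms_rate expected randoms/scatter counts per bin.
#' @param n_angles number of projection angles over `[0, 180)`.
#' @param partial_fourier_fraction acquired k-space row extent.
#' @param line_bundle,angle_block acquisition action sizes.
#' @param warm_center_fraction fraction of central k-space rows always
#'   acquired first.
#' @param warm_angle_every take every k-th angle in the warm start.
#' @param weights a [recon_weights()] for the joint reconstruction.
#' @param u_weights an [uncertainty_weights()] for `U_t`.
#' @param n_projections sliced-Wasserstein projections.
#' @param min_persistence diagram noise floor used in the loop.
#' @param n_outer_first,n_outer_step solver iterations for the first /
#'   subsequent reconstructions.
#' @param reward a [reward_config()].
#' @export
closed_loop_config <- function(noise_sigma = 0.01, total_counts = 3e5,
                               randoms_rate = 0.5, n_angles = 60,
                               partial_fourier_fraction = 0.625,
                               line_bundle = 8, angle_block = 5,
                               warm_center_fraction = 0.08,
                               warm_angle_every = 5,
                               weights = recon_weights(),
                               u_weights = uncertainty_weights(),
                               n_projections = 50,
                               min_persistence = 0.2,
                               n_outer_first = 15, n_outer_step = 8,
                               reward = reward_config()) {
  structure(as.list(environment()), class = "closed_loop_config")
}

# scale phantom activity so the expected full-sinogram total is
# `total_counts`, and simulate the complete measurement set once
simulate_full_measurements <- function(phantom, cfg, seed) {
  n <- nrow(phantom$mr_image)
  angles <- seq(0, 180 - 180 / cfg$n_angles, length.out = cfg$n_angles)
  kfull <- fourier_encode(phantom$mr_image, "forward")
  y_full <- acquire(kfull, matrix(TRUE, n, n), cfg$noise_sigma, seed)
  exp0 <- project(phantom$pet_activity, angles)
  scale <- cfg$total_counts / sum(exp0)
  expd <- exp0 * scale
  attr(expd, "angles") <- angles
  sino_full <- simulate_counts(expd, cfg$randoms_rate, seed + 1L)
  list(kspace = y_full, sino = sino_full, angles = angles,
       activity_scale = scale)
}

subset_sinogram <- function(sino_full, angles_sel) {
  keep <- which(sino_full$angles %in% angles_sel)
  sinogram(sino_full$counts[keep, , drop = FALSE],
           sino_full$angles[keep], sino_full$randoms_rate)
}

#' Run the closed acquisition-reconstruction loop on a phantom
#'
#' Alternates measurement selection, joint reconstruction, persistence
#' diagram extraction and uncertainty evaluation until the stopping rule
#' fires or the budget is exhausted. In `"greedy"` mode actions minimize
#' the one-step look-ahead uncertainty (cheap provisional reconstruction);
#' in `"policy"` mode they are sampled from an actor-critic policy; in
#' `"static"` mode a predetermined variable-density line order is followed
#' (the classic static compressed-sensing baseline).
#'
#' @param phantom a [rasterize_phantom()] object.
#' @param mode `"greedy"`, `"policy"`, or `"static"`.
#' @param budget maximum fraction of all measurement units (lines + angles)
#'   in `(0, 1]`.
#' @param stop_threshold stop when the oracle-referenced normalized
#'   persistence deviation (percent) is at or below this for
#'   `stop_patience` consecutive steps. Use `Inf` to stop immediately after
#'   the first reconstruction.
#' @param stop_patience consecutive sub-threshold steps required.
#' @param seed integer seed controlling all randomness of the episode.
#' @param config a [closed_loop_config()].
#' @param policy a [policy_model()] (required for `mode = "policy"`).
#' @param reference the reference diagram `D*` driving uncertainty and
#'   stopping: `"oracle"` (phantom ground-truth diagram), `"self"`
#'   (deviation between consecutive reconstructions, deployment mode), or a
#'   `persistence_diagram` object -- typically the diagram of a converged
#'   full-budget reconstruction, which is how fully sampled reference scans
#'   are compared against accelerated ones.
#' @param collect_trajectory also return the (state, candidates, action,
#'   reward) tuples needed for policy training.
#' @return A `closed_loop_trace`: per-step data frame `steps`, final
#'   reconstruction `u`/`x_pet`, acquired `lines` and `angles`, final
#'   diagram, sampling fraction and reduction, status flags.
#' @export
run_closed_loop <- function(phantom, mode = c("greedy", "policy", "static"),
                            budget = 1.0, stop_threshold = 3,
                            stop_patience = 2, seed = 1,
                            config = closed_loop_config(), policy = NULL,
                            reference = "oracle",
                            collect_trajectory = FALSE) {
  mode <- match.arg(mode)
  stopifnot(budget > 0, budget <= 1)
  if (mode == "policy" && is.null(policy))
    stop("policy mode requires a policy_model")
  cfg <- config
  n <- nrow(phantom$mr_image)
  meas <- simulate_full_measurements(phantom, cfg, seed)
  full_units <- n + cfg$n_angles
  pf_rows <- ceiling(cfg$partial_fourier_fraction * n)

  # warm start: central lines + coarse angle set
  n_center <- max(2, round(cfg$warm_center_fraction * n))
  ctr <- n %/% 2 + 1
  lines <- sort(unique(pmin(pmax(
    seq(ctr - n_center %/% 2, length.out = n_center), 1), pf_rows)))
  angle_idx <- seq(1, cfg$n_angles, by = cfg$warm_angle_every)
  angles <- meas$angles[angle_idx]

  d_ref <- if (inherits(reference, "persistence_diagram")) {
    reference
  } else if (identical(reference, "oracle")) {
    ground_truth_diagram(phantom, cfg$min_persistence)
  } else if (identical(reference, "self")) {
    NULL
  } else stop("reference must be 'oracle', 'self', or a persistence_diagram")

  static_order <- if (mode == "static") {
    static_line_order(n, pf_rows, lines, seed)
  } else NULL

  u_prev <- matrix(0, n, n)
  d_prev <- NULL
  recon <- NULL
  steps <- list()
  trajectory <- list()
  status <- "budget_exhausted"
  below <- 0L
  last_action <- list(type = "warm", id = NA_integer_)
  step_seed <- seed
  max_steps <- ceiling(full_units / min(cfg$line_bundle, cfg$angle_block)) + 2

  for (t in seq_len(max_steps)) {
    mask <- line_sampling_mask(lines, n, 1.0)  # lines already within pf extent
    y_t <- meas$kspace * mask$mask
    sino_t <- subset_sinogram(meas$sino, angles)
    recon <- solve_joint(y_t, mask, sino_t, cfg$weights,
                         n_outer = if (t == 1) cfg$n_outer_first
                                   else cfg$n_outer_step,
                         init = if (t == 1) NULL
                                else list(u = recon$u, x_pet = recon$x_pet))
    d_t <- persistence_diagram(Mod(recon$u), cfg$min_persistence)
    frac <- (length(lines) + length(angles)) / full_units
    if (!is.null(d_ref)) {
      u_t <- topological_uncertainty(d_t, d_ref, cfg$u_weights,
                                     n_projections = cfg$n_projections,
                                     seed = seed)
      dev_t <- normalized_persistence_deviation(d_t, d_ref, cfg$u_weights,
                                                n_projections = cfg$n_projections,
                                                seed = seed)
    } else {
      if (is.null(d_prev)) {
        u_t <- Inf; dev_t <- Inf
      } else {
        u_t <- topological_uncertainty(d_t, d_prev, cfg$u_weights,
                                       n_projections = cfg$n_projections,
                                       seed = seed)
        dev_t <- normalized_persistence_deviation(d_t, d_prev, cfg$u_weights,
                                                  n_projections = cfg$n_projections,
                                                  seed = seed)
      }
    }
    r_t <- reward(if (is.finite(u_t)) u_t else 0, frac, Mod(recon$u), u_prev,
                  cfg$reward)
    steps[[t]] <- data.frame(step = t, action_type = last_action$type,
                             action_id = last_action$id,
                             n_lines = length(lines),
                             n_angles = length(angles),
                             fraction = frac, U = u_t, deviation = dev_t,
                             reward = r_t,
                             failed = !all(is.finite(recon$u)))
    if (steps[[t]]$failed) { status <- "reconstruction_failed"; break }

    # stopping rule: deviation below threshold for `stop_patience` steps
    below <- if (is.finite(dev_t) && dev_t <= stop_threshold) below + 1L else 0L
    if (is.infinite(stop_threshold)) { status <- "stopped"; break }
    if (below >= stop_patience) { status <- "stopped"; break }
    if (frac >= budget) { status <- "budget_exhausted"; break }

    actions <- build_action_space(lines, angles, n, meas$angles,
                                  cfg$partial_fourier_fraction,
                                  cfg$line_bundle, cfg$angle_block)
    if (!length(actions$candidates)) { status <- "exhausted"; break }
    state <- controller_descriptor(d_t, if (is.finite(u_t)) u_t else 0,
                                   frac, length(lines) / n,
                                   length(angles) / cfg$n_angles)

    chosen <- if (mode == "greedy") {
      base_u <- lookahead_uncertainty(meas, lines, NULL, n, cfg, d_ref, d_t,
                                      seed)
      greedy_select(state, actions, function(cand) {
        if (cand$type == "mr") {
          lookahead_uncertainty(meas, lines, cand$lines, n, cfg, d_ref, d_t,
                                seed)
        } else base_u
      })
    } else if (mode == "static") {
      static_next(actions, static_order)
    } else {
      feats <- t(vapply(actions$candidates, candidate_features,
                        numeric(4), grid_size = n,
                        all_angles = meas$angles))
      pr <- policy_probs(policy, state, feats)
      step_seed <- step_seed + 1L
      a <- with_seed(step_seed, sample.int(length(pr), 1, prob = pr))
      ch <- actions$candidates[[a]]
      if (collect_trajectory) {
        trajectory[[length(trajectory) + 1]] <-
          list(state = state, feats = feats, action = a, reward = NA_real_)
      }
      ch
    }
    if (collect_trajectory && mode != "policy") {
      feats <- t(vapply(actions$candidates, candidate_features,
                        numeric(4), grid_size = n,
                        all_angles = meas$angles))
      trajectory[[length(trajectory) + 1]] <-
        list(state = state, feats = feats, action = chosen$id,
             reward = NA_real_)
    }
    if (chosen$type == "mr") {
      lines <- sort(union(lines, chosen$lines))
    } else {
      angles <- sort(union(angles, chosen$angles))
    }
    last_action <- chosen
    u_prev <- Mod(recon$u)
    d_prev <- d_t
  }

  steps <- do.call(rbind, steps)
  # per-step rewards feed back the next step's outcome for the trajectory
  if (length(trajectory)) {
    for (i in seq_along(trajectory)) {
      if (i + 1 <= nrow(steps)) {
        trajectory[[i]]$reward <- steps$reward[i + 1]
        trajectory[[i]]$next_state <- NULL
      }
    }
    # attach next states
    for (i in seq_along(trajectory)) {
      trajectory[[i]]$next_state <-
        if (i < length(trajectory)) trajectory[[i + 1]]$state else NULL
    }
  }
  fraction <- (length(lines) + length(angles)) / full_units
  out <- structure(list(
    steps = steps,
    u = recon$u, x_pet = recon$x_pet,
    lines = lines, angles = angles,
    diagram = persistence_diagram(Mod(recon$u), cfg$min_persistence),
    fraction = fraction,
    sampling_reduction = 100 * (1 - fraction),
    deviation_oracle = utils::tail(steps$deviation, 1),
    status = status, mode = mode, seed = seed,
    config = cfg, phantom_seed = phantom$tree$seed),
    class = "closed_loop_trace")
  if (collect_trajectory) out$trajectory <- trajectory
  out
}

# cheap provisional reconstruction -> uncertainty, for look-ahead
lookahead_uncertainty <- function(meas, lines, extra_lines, n, cfg, d_ref,
                                  d_t, seed) {
  lns <- if (is.null(extra_lines)) lines else sort(union(lines, extra_lines))
  mask <- line_sampling_mask(lns, n, 1.0)
  u_img <- cheap_recon(meas$kspace * mask$mask, mask)
  d_cand <- persistence_diagram(u_img, cfg$min_persistence)
  ref <- if (!is.null(d_ref)) d_ref else d_t
  topological_uncertainty(d_cand, ref, cfg$u_weights,
                          n_projections = cfg$n_projections, seed = seed)
}

# variable-density (center-out with seeded jitter) static line order
static_line_order <- function(n, pf_rows, warm_lines, seed) {
  remaining <- setdiff(seq_len(pf_rows), warm_lines)
  ctr <- n %/% 2 + 1
  with_seed(seed, {
    w <- 1 / (1 + (abs(remaining - ctr) / (n / 8))^2)
    sample(remaining, length(remaining), prob = w)
  })
}

static_next <- function(actions, static_order) {
  mr <- Filter(function(c) c$type == "mr", actions$candidates)
  if (!length(mr)) return(actions$candidates[[1]])
  # take the bundle containing the highest-priority remaining line
  for (ln in static_order) {
    for (cand in mr) if (ln %in% cand$lines) return(cand)
  }
  mr[[1]]
}

#' @export
print.closed_loop_trace <- function(x, ...) {
  cat(sprintf(
    "Closed-loop trace (%s): %d steps, %.1f%% sampled (reduction %.1f%%),\n  final deviation %.2f%%, status: %s\n",
    x$mode, nrow(x$steps), 100 * x$fraction, x$sampling_reduction,
    x$deviation_oracle, x$status))
  invisible(x)
}

#' @export
summary.closed_loop_trace <- function(object, ...) {
  print(object)
  print(object$steps)
  invisible(object$steps)
}

#' @export
plot.closed_loop_trace <- function(x, ...) {
  graphics::par(mfrow = c(1, 2))
  graphics::plot(x$steps$step, x$steps$deviation, type = "b",
                 xlab = "step", ylab = "normalized deviation (%)", ...)
  graphics::abline(h = 3, col = "grey")
  graphics::plot(x$steps$step, 100 * x$steps$fraction, type = "b",
                 xlab = "step", ylab = "sampling fraction (%)", ...)
  graphics::par(mfrow = c(1, 1))
  invisible(x)
}

#' Train the acquisition policy by episodic actor-critic updates
#'
#' Runs closed-loop episodes in policy mode on seeded phantoms, then applies
#' one [actor_critic_update()] per episode.
#'
#' @param n_episodes number of training episodes.
#' @param seed master seed; episode e uses phantom seed `seed * 1000 + e`.
#' @param grid_size phantom size used for training episodes.
#' @param config a [closed_loop_config()]; smaller reconstruction effort is
#'   advisable for training throughput.
#' @param policy starting [policy_model()] (fresh one by default).
#' @param lr_actor,lr_critic learning rates.
#' @param budget,stop_threshold episode termination controls.
#' @return list with the trained `policy` and per-episode `returns`.
#' @export
train_policy <- function(n_episodes = 50, seed = 1, grid_size = 64,
                         config = closed_loop_config(),
                         policy = policy_model(seed = seed),
                         lr_actor = 1e-3, lr_critic = 1e-2,
                         budget = 0.8, stop_threshold = 3) {
  returns <- numeric(n_episodes)
  for (e in seq_len(n_episodes)) {
    pseed <- seed * 1000 + e
    ph <- rasterize_phantom(
      generate_vessel_tree(pseed, 5, 0.5, grid_size), seed = pseed)
    tr <- run_closed_loop(ph, "policy", budget = budget,
                          stop_threshold = stop_threshold, seed = pseed,
                          config = config, policy = policy,
                          collect_trajectory = TRUE)
    traj <- Filter(function(s) is.finite(s$reward), tr$trajectory)
    returns[e] <- sum(tr$steps$reward)
    if (length(traj)) {
      upd <- actor_critic_update(traj, policy, lr_actor, lr_critic)
      policy <- upd$policy
    }
  }
  list(policy = policy, returns = returns)
}
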