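# Reward, action space, greedy selection, actor-critic, closed loop.

test_that("reward is the exact weighted sum and scales linearly", {
  x <- matrix(0, 4, 4)
  expect_equal(reward(0, 0, x, x), 0)
  expect_equal(reward(0.3, 0, x, x, reward_config(1, 0, 0)), -0.3)
  x2 <- x; x2[1, 1] <- sqrt(0.1)
  expect_equal(reward(0.5, 0.25, x2, x, reward_config(1, 2, 1)), -1.1,
               tolerance = 1e-10)
  # linearity in the weight vector
  cfg1 <- reward_config(0.7, 0.2, 0.4)
  cfg3 <- reward_config(3 * 0.7, 3 * 0.2, 3 * 0.4)
  expect_equal(reward(0.4, 0.6, x2, x, cfg3),
               3 * reward(0.4, 0.6, x2, x, cfg1), tolerance = 1e-12)
  expect_error(reward_config(-1), "alpha")
})

test_that("action space partitions unacquired measurements without overlap", {
  as1 <- build_action_space(acquired_lines = c(60:70),
                            acquired_angles = c(0, 30),
                            grid_size = 128, all_angles = angles60,
                            partial_fourier_fraction = 0.625,
                            line_bundle = 8, angle_block = 5)
  types <- vapply(as1$candidates, `[[`, character(1), "type")
  all_lines <- unlist(lapply(as1$candidates[types == "mr"], `[[`, "lines"))
  expect_equal(anyDuplicated(all_lines), 0L)
  expect_length(intersect(all_lines, 60:70), 0)
  expect_true(all(all_lines <= ceiling(0.625 * 128)))
  all_angles <- unlist(lapply(as1$candidates[types == "pet"], `[[`,
                              "angles"))
  expect_length(intersect(all_angles, c(0, 30)), 0)
  expect_equal(anyDuplicated(all_angles), 0L)
})

test_that("greedy selection returns the argmin with index tie-breaking", {
  asp <- build_action_space(integer(), numeric(), 32, c(0, 90),
                            line_bundle = 8, angle_block = 2)
  single <- build_action_space(1:12, numeric(), 32, c(0, 90),
                               partial_fourier_fraction = 0.625,
                               line_bundle = 20, angle_block = 2)
  expect_length(single$candidates, 2)   # one mr bundle + one pet block
  # brute-force ranking: candidate with the smaller evaluated U wins
  us <- c(0.5, 0.2, 0.9)
  got <- greedy_select(numeric(8), asp,
                       function(cand) us[min(cand$id, 3)])
  expect_equal(got$id, 2)
  # ties break toward the lowest index
  got2 <- greedy_select(numeric(8), asp, function(cand) 1)
  expect_equal(got2$id, 1)
  empty <- build_action_space(1:32, c(0, 90), 32, c(0, 90),
                              partial_fourier_fraction = 1)
  expect_error(greedy_select(numeric(8), empty, function(c) 0), "empty")
})

test_that("actor gradients match finite differences", {
  pol <- policy_model(state_dim = 3, cand_dim = 2, hidden = 5, seed = 21)
  state <- c(0.5, -0.2, 1.1)
  feats <- rbind(c(1, 0.3), c(0, 0.8), c(1, 0.1))
  g <- topoacq:::actor_logp_grad(pol, state, feats, 2L)
  logp <- function(p) {
    s <- topoacq:::actor_scores(p, state, feats)$scores
    s[2] - log(sum(exp(s)))
  }
  eps <- 1e-6
  for (nm in c("W1", "b1", "w2")) {
    par <- pol[[nm]]
    idx <- seq_along(par)
    for (i in idx[seq(1, length(idx), length.out = min(6, length(idx)))]) {
      p2 <- pol; p2[[nm]][i] <- p2[[nm]][i] + eps
      num <- (logp(p2) - logp(pol)) / eps
      ana <- g[[nm]][i]
      expect_lt(abs(num - ana) / max(abs(ana), 1e-4), 1e-3)
    }
  }
  # probabilities normalize
  expect_equal(sum(policy_probs(pol, state, feats)), 1)
})

test_that("zero advantage leaves the actor untouched", {
  pol <- policy_model(state_dim = 2, cand_dim = 2, hidden = 4, seed = 2)
  state <- c(1, 0); feats <- diag(2)
  v <- topoacq:::critic_value(pol, state)
  traj <- list(list(state = state, feats = feats, action = 1L,
                    reward = v, next_state = NULL))
  # reward chosen so TD target equals V(s): advantage exactly zero
  pol$discount_factor <- 1
  upd <- actor_critic_update(traj, pol)
  expect_identical(upd$policy$W1, pol$W1)
  expect_identical(upd$policy$w2, pol$w2)
  expect_equal(upd$critic_loss, 0)
})

test_that("actor-critic solves the two-armed bandit", {
  pol <- policy_model(state_dim = 2, cand_dim = 2, hidden = 8,
                      discount_factor = 0.9, seed = 3)
  state <- c(1, 0); feats <- rbind(c(1, 0), c(0, 1))
  set.seed(11)
  for (i in 1:500) {
    pr <- policy_probs(pol, state, feats)
    a <- sample.int(2, 1, prob = pr)
    r <- if (a == 1) 1 else -1
    upd <- actor_critic_update(
      list(list(state = state, feats = feats, action = a, reward = r,
                next_state = NULL)),
      pol, lr_actor = 0.05, lr_critic = 0.05)
    pol <- upd$policy
  }
  expect_gt(policy_probs(pol, state, feats)[1], 0.9)
})

test_that("critic converges to the discounted constant-reward value", {
  pol <- policy_model(state_dim = 2, cand_dim = 2, hidden = 8,
                      discount_factor = 0.9, seed = 4)
  state <- c(1, 0); feats <- diag(2)
  for (i in 1:3000) {
    upd <- actor_critic_update(
      list(list(state = state, feats = feats, action = 1L, reward = 1,
                next_state = state)),
      pol, lr_actor = 0, lr_critic = 0.05)
    pol <- upd$policy
  }
  expect_lt(abs(topoacq:::critic_value(pol, state) - 10) / 10, 0.05)
})

test_that("closed loop respects degenerate budgets and stopping rules", {
  ph <- test_phantom(seed = 507, grid = 64, n_loops = 1)
  cfg <- closed_loop_config(n_outer_first = 6, n_outer_step = 4)
  # budget so small that only the warm start fits: single-step trace
  tr <- run_closed_loop(ph, "greedy", budget = 0.05, seed = 1, config = cfg)
  expect_equal(nrow(tr$steps), 1)
  expect_equal(tr$status, "budget_exhausted")
  expect_true(is.finite(tr$sampling_reduction))
  # infinite stopping threshold: stop at the first evaluation
  tr2 <- run_closed_loop(ph, "greedy", budget = 1, stop_threshold = Inf,
                         seed = 1, config = cfg)
  expect_equal(nrow(tr2$steps), 1)
  expect_equal(tr2$status, "stopped")
  expect_error(run_closed_loop(ph, "policy", seed = 1, config = cfg),
               "policy")
})

test_that("closed loop is reproducible and never re-acquires a measurement", {
  ph <- test_phantom(seed = 508, grid = 64, n_loops = 1)
  cfg <- closed_loop_config(n_outer_first = 6, n_outer_step = 4)
  tr <- run_closed_loop(ph, "greedy", budget = 0.5, stop_threshold = 3,
                        seed = 9, config = cfg)
  tr2 <- run_closed_loop(ph, "greedy", budget = 0.5, stop_threshold = 3,
                         seed = 9, config = cfg)
  expect_identical(tr$steps, tr2$steps)
  expect_identical(tr$lines, tr2$lines)
  # acquisition counters strictly account for every unit exactly once
  expect_equal(anyDuplicated(tr$lines), 0L)
  expect_equal(anyDuplicated(tr$angles), 0L)
  expect_true(all(diff(tr$steps$n_lines + tr$steps$n_angles) > 0))
  # sampling fraction is non-decreasing along the trace
  expect_true(all(diff(tr$steps$fraction) >= 0))
})

test_that("policy mode runs and a trained policy improves its return", {
  cfg <- closed_loop_config(n_outer_first = 4, n_outer_step = 3)
  eval_policy <- function(pol, seeds) {
    vapply(seeds, function(s) {
      ph <- test_phantom(seed = s, grid = 64, n_loops = 1)
      tr <- run_closed_loop(ph, "policy", budget = 0.45,
                            stop_threshold = 3, seed = s, config = cfg,
                            policy = pol)
      sum(tr$steps$reward)
    }, numeric(1))
  }
  untrained <- policy_model(seed = 5)
  trained <- train_policy(n_episodes = 100, seed = 3, grid_size = 64,
                          config = cfg, policy = untrained,
                          lr_actor = 5e-3, lr_critic = 1e-2,
                          budget = 0.45)$policy
  seeds <- 701:720
  expect_gt(mean(eval_policy(trained, seeds)),
            mean(eval_policy(untrained, seeds)))
})
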