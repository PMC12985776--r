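# Tier-I evaluation harness: topology-preservation experiments on seeded
# phantoms, plus the small statistics utilities used for reporting
# (Betti deviation, sampling reduction, pooled Cohen's d, two-arm sample
# size, Bland-Altman limits).

#' Percent deviation between reference and accelerated Betti counts
#'
#' `|accelerated - reference| / reference * 100`, reported at 0.1 precision
#' (round-half-even).
#' @param ref_count reference count (> 0).
#' @param acc_count accelerated count.
#' @export
betti_deviation <- function(ref_count, acc_count) {
  if (any(ref_count <= 0)) stop("reference count must be > 0")
  round(abs(acc_count - ref_count) / ref_count * 100, 1)
}

#' Signed sampling change from a retained percentage
#'
#' A protocol that retains `retained` percent of full sampling changes the
#' sampling density by `retained - 100` percent (negative = reduction);
#' the absolute reduction is `100 - retained`.
#' @param retained_fraction percent of full sampling retained, in `[0,100]`.
#' @return list with `change` (signed) and `reduction` (absolute).
#' @export
sampling_reduction <- function(retained_fraction) {
  stopifnot(retained_fraction >= 0, retained_fraction <= 100)
  list(change = retained_fraction - 100,
       reduction = 100 - retained_fraction)
}

#' Pooled-variance Cohen's d
#'
#' `(mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)`.
#' @param mean1,sd1,mean2,sd2 group summaries; both SDs must be positive.
#' @export
cohens_d_pooled <- function(mean1, sd1, mean2, sd2) {
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be > 0")
  (mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)
}

#' Two-arm sample size for a standardized effect
#'
#' `n = 2 (z_{1-alpha/2} + z_{1-beta})^2 / d^2` per arm (normal
#' approximation to the two-sample t test).
#' @param alpha two-sided type-I error rate in (0, 1).
#' @param power target power `1 - beta` in (0, 1).
#' @param d standardized effect size (> 0).
#' @export
sample_size_two_arm <- function(alpha, power, d) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  if (d <= 0) stop("effect size must be > 0")
  2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 / d^2
}

#' Bland-Altman mean difference and limits of agreement
#'
#' @param x,y paired measurements.
#' @return list with `mean_difference`, `lower`, `upper` (mean +/- 1.96 SD).
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  list(mean_difference = mean(d),
       lower = mean(d) - 1.96 * sd(d),
       upper = mean(d) + 1.96 * sd(d))
}

#' Run the simulation-based topology-preservation experiment
#'
#' For each seeded realization: generate a vascular phantom (1-3 collateral
#' loops), reconstruct from full sampling (reference), run the closed loop
#' in the requested mode, and score the accelerated against the reference
#' reconstruction -- Betti deviations of the extracted graphs and the
#' normalized Wasserstein-weighted persistence deviation of the diagrams --
#' plus the retained sampling fraction.
#'
#' @param n_realizations number of seeded phantoms.
#' @param mode `"greedy"` or `"static"` (passed to [run_closed_loop()]).
#' @param seed master seed; realization i uses `seed * 1000 + i`.
#' @param grid_size phantom size.
#' @param config a [closed_loop_config()].
#' @param budget,stop_threshold,stop_patience closed-loop controls.
#' @param fixed_fraction for `mode = "static"`: acquire up to this fraction
#'   with no topological stopping (matched-fraction baseline); `NULL` uses
#'   the stopping rule.
#' @param out_dir optional directory to write `tier1_report.csv`,
#'   `summary.json` and `summary.md`.
#' @return A `tier1_report`: data frame `realizations` (one row per
#'   non-failed realization), `summary` (means and SDs), failure count.
#' @export
run_tier1_experiment <- function(n_realizations = 50, mode = "greedy",
                                 seed = 7, grid_size = 128,
                                 config = closed_loop_config(),
                                 budget = 1.0, stop_threshold = 3,
                                 stop_patience = 2, fixed_fraction = NULL,
                                 out_dir = NULL) {
  stopifnot(n_realizations >= 1)
  rows <- list()
  failures <- 0L
  for (i in seq_len(n_realizations)) {
    rseed <- seed * 1000 + i
    res <- tryCatch(
      tier1_realization(rseed, mode, grid_size, config, budget,
                        stop_threshold, stop_patience, fixed_fraction),
      error = function(e) e)
    if (inherits(res, "error") || isTRUE(res$failed)) {
      failures <- failures + 1L
      next
    }
    rows[[length(rows) + 1]] <- res$row
  }
  realizations <- do.call(rbind, rows)
  rownames(realizations) <- NULL
  num <- realizations[, c("retained_pct", "reduction_pct", "delta_b0_pct",
                          "delta_b1_pct", "persistence_deviation_pct")]
  summary <- data.frame(metric = names(num),
                        mean = vapply(num, mean, numeric(1)),
                        sd = vapply(num, sd, numeric(1)),
                        row.names = NULL)
  report <- structure(list(realizations = realizations, summary = summary,
                           n_requested = n_realizations,
                           failures = failures, mode = mode, seed = seed,
                           grid_size = grid_size),
                      class = "tier1_report")
  if (!is.null(out_dir)) write_tier1_report(report, out_dir)
  report
}

tier1_realization <- function(rseed, mode, grid_size, config, budget,
                              stop_threshold, stop_patience,
                              fixed_fraction) {
  n_loops <- 1 + (rseed %% 3)          # 1-3 collateral loops
  tree <- generate_vessel_tree(rseed, n_primary_branches = 5,
                               loop_probability = 0.5,
                               grid_size = grid_size, n_loops = n_loops)
  ph <- rasterize_phantom(tree, seed = rseed)
  cfg <- config
  n <- grid_size
  # reference: full sampling, both modalities
  meas <- simulate_full_measurements(ph, cfg, rseed)
  full_mask <- line_sampling_mask(seq_len(n), n, 1.0)
  ref <- solve_joint(meas$kspace, full_mask, meas$sino, cfg$weights,
                     n_outer = cfg$n_outer_first)
  d_ref <- persistence_diagram(Mod(ref$u), cfg$min_persistence)
  g_ref <- extract_graph(Mod(ref$u))
  b_ref <- betti_numbers(g_ref)
  # accelerated: closed loop, referenced to the full-budget scan's topology
  tr <- run_closed_loop(ph, mode,
                        budget = if (is.null(fixed_fraction)) budget
                                 else fixed_fraction,
                        stop_threshold = if (is.null(fixed_fraction))
                                           stop_threshold else -Inf,
                        stop_patience = stop_patience,
                        seed = rseed, config = cfg, reference = d_ref)
  if (tr$status == "reconstruction_failed")
    return(list(failed = TRUE))
  g_acc <- extract_graph(Mod(tr$u))
  b_acc <- betti_numbers(g_acc)
  dev <- normalized_persistence_deviation(tr$diagram, d_ref, cfg$u_weights,
                                          n_projections = cfg$n_projections,
                                          seed = rseed)
  retained <- 100 * tr$fraction
  list(failed = FALSE, row = data.frame(
    seed = rseed,
    retained_pct = retained,
    reduction_pct = 100 - retained,
    delta_b0_pct = betti_deviation(max(b_ref[1], 1), b_acc[1]),
    delta_b1_pct = if (b_ref[2] > 0) betti_deviation(b_ref[2], b_acc[2])
                   else abs(b_acc[2] - b_ref[2]) * 100,
    persistence_deviation_pct = dev,
    status = tr$status))
}

#' @export
print.tier1_report <- function(x, ...) {
  cat(sprintf("Topology-preservation report: %d/%d realizations (%s mode, %dx%d)\n",
              nrow(x$realizations), x$n_requested, x$mode,
              x$grid_size, x$grid_size))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-28s %6.1f%% +/- %.1f%%\n", s$metric[i], s$mean[i],
                s$sd[i]))
  }
  if (x$failures) cat("  failures excluded:", x$failures, "\n")
  invisible(x)
}

write_tier1_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$realizations, file.path(out_dir, "tier1_report.csv"),
            row.names = FALSE)
  s <- report$summary
  js <- as.list(stats::setNames(s$mean, paste0("mean_", s$metric)))
  js <- c(js, as.list(stats::setNames(s$sd, paste0("sd_", s$metric))),
          list(n = nrow(report$realizations), failures = report$failures,
               mode = report$mode, seed = report$seed))
  jsonlite::write_json(js, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  md <- c("| Metric | Reference | Accelerated |",
          "|---|---|---|",
          sprintf("| Sampling density | 100%% | %.1f%% ± %.1f%% |",
                  s$mean[s$metric == "retained_pct"],
                  s$sd[s$metric == "retained_pct"]),
          sprintf("| Δβ0 (raw) | – | %.1f%% ± %.1f%% |",
                  s$mean[s$metric == "delta_b0_pct"],
                  s$sd[s$metric == "delta_b0_pct"]),
          sprintf("| Δβ1 (raw) | – | %.1f%% ± %.1f%% |",
                  s$mean[s$metric == "delta_b1_pct"],
                  s$sd[s$metric == "delta_b1_pct"]),
          sprintf("| Wasserstein persistence deviation | 0%% | %.1f%% ± %.1f%% |",
                  s$mean[s$metric == "persistence_deviation_pct"],
                  s$sd[s$metric == "persistence_deviation_pct"]))
  writeLines(md, file.path(out_dir, "summary.md"))
  invisible(out_dir)
}

#' Benchmark the sliced against the exact Wasserstein distance
#'
#' Draws seeded random diagram pairs (births uniform on `[0, 1]`,
#' persistences uniform on `[0, 0.5]`, 10-100 points per diagram), computes
#' the exact order-`p` distance by linear assignment and the sliced
#' approximation, and reports the relative errors.
#'
#' @param n_pairs number of diagram pairs.
#' @param n_projections sliced projections.
#' @param p Wasserstein order.
#' @param seed master seed.
#' @return list with `mean_relative_error_pct`, `max_relative_error_pct`,
#'   and the per-pair data frame `pairs`.
#' @export
benchmark_sliced_wasserstein <- function(n_pairs = 50, n_projections = 50,
                                         p = 2, seed = 1) {
  rel <- numeric(n_pairs)
  exacts <- numeric(n_pairs); sliceds <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    pair <- with_seed(seed * 100 + i, {
      n1 <- sample(10:100, 1); n2 <- sample(10:100, 1)
      b1 <- runif(n1); b2 <- runif(n2)
      list(d1 = as_persistence_diagram(b1, b1 + runif(n1, 0, 0.5),
                                       rep(0L, n1)),
           d2 = as_persistence_diagram(b2, b2 + runif(n2, 0, 0.5),
                                       rep(0L, n2)))
    })
    ex <- wasserstein_exact(pair$d1, pair$d2, p = p, degree = 0L)
    sl <- wasserstein_sliced(pair$d1, pair$d2, p = p,
                             n_projections = n_projections,
                             seed = seed * 100 + i, degree = 0L)
    exacts[i] <- ex; sliceds[i] <- sl
    rel[i] <- abs(sl - ex) / ex
  }
  list(mean_relative_error_pct = 100 * mean(rel),
       max_relative_error_pct = 100 * max(rel),
       pairs = data.frame(exact = exacts, sliced = sliceds,
                          rel_error = rel))
}
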