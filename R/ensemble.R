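#' Run a Monte-Carlo ensemble of trajectories
#'
#' Simulates `n_runs` independent trajectories of the stochastic recurrence
#' and aggregates their absorption behaviour. Trajectory i uses seed
#' `base_seed + i`, so the ensemble is deterministic given `base_seed` and
#' each trajectory is independently reproducible.
#'
#' @param params A [model_params()] object.
#' @param n_runs Number of trajectories (>= 1).
#' @param max_steps Maximum steps per trajectory.
#' @param base_seed Integer base seed.
#' @param keep_trajectories Keep the individual trajectory objects in the
#'   result (memory grows with `n_runs * max_steps`); default `FALSE`.
#' @return An object of class `"ensemble_summary"`: counts per absorbing
#'   branch (`n_absorbed_one`, `n_absorbed_zero`, `n_unabsorbed`),
#'   absorption-step summary statistics (min, q25, median, q75, max over
#'   absorbed runs), `params`, `base_seed`, `constrained = FALSE`, and the
#'   per-trajectory vectors `branch` and `absorption_steps`.
#' @examples
#' run_ensemble(model_params(n_observers = 2), n_runs = 8,
#'              max_steps = 200, base_seed = 42)
#' @export
run_ensemble <- function(params, n_runs, max_steps = 200L, base_seed = 1L,
                         keep_trajectories = FALSE) {
  stopifnot(n_runs >= 1, n_runs == as.integer(n_runs))
  trajs <- lapply(seq_len(n_runs), function(i) {
    simulate_trajectory(params, max_steps, seed = as.integer(base_seed) + i)
  })
  summarize_ensemble(trajs, params, base_seed,
                     constrained = FALSE, n_discarded = 0L,
                     keep_trajectories = keep_trajectories)
}

summarize_ensemble <- function(trajs, params, base_seed, constrained,
                               n_discarded, keep_trajectories = FALSE) {
  branch <- vapply(trajs, function(t) t$absorbed_at, character(1))
  steps <- vapply(trajs, function(t) t$absorption_step, integer(1))
  absorbed <- branch != "none"
  step_stats <- if (any(absorbed)) {
    s <- steps[absorbed]
    c(min = min(s), q25 = unname(stats::quantile(s, 0.25)),
      median = stats::median(s),
      q75 = unname(stats::quantile(s, 0.75)), max = max(s))
  } else {
    c(min = NA_real_, q25 = NA_real_, median = NA_real_,
      q75 = NA_real_, max = NA_real_)
  }
  structure(list(n_runs = length(trajs),
                 n_absorbed_one = sum(branch == "one"),
                 n_absorbed_zero = sum(branch == "zero"),
                 n_unabsorbed = sum(branch == "none"),
                 absorption_step_stats = step_stats,
                 branch = branch,
                 absorption_steps = steps,
                 params = params,
                 base_seed = as.integer(base_seed),
                 constrained = constrained,
                 n_discarded = n_discarded,
                 trajectories = if (keep_trajectories) trajs else NULL,
                 degenerate = length(trajs) == 0L),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("Ensemble of ", x$n_runs, " trajectories (N = ",
      x$params$n_observers, ", base seed = ", x$base_seed,
      if (x$constrained) ", control-constrained" else "", ")\n", sep = "")
  if (x$degenerate) {
    cat("  DEGENERATE: no surviving trajectories\n")
    return(invisible(x))
  }
  cat("  absorbed at 1: ", x$n_absorbed_one,
      "   absorbed at 0: ", x$n_absorbed_zero,
      "   unabsorbed: ", x$n_unabsorbed, "\n", sep = "")
  if (x$constrained) {
    cat("  discarded (branch #2): ", x$n_discarded, "\n", sep = "")
  }
  s <- x$absorption_step_stats
  if (!is.na(s[["median"]])) {
    cat("  absorption steps: min ", s[["min"]], ", median ", s[["median"]],
        ", max ", s[["max"]], "\n", sep = "")
  }
  invisible(x)
}

#' Exact binomial test of branch symmetry
#'
#' Tests whether the two absorbing branches are chosen with equal
#' probability, against the null of a fair 1/2 split. The two-sided exact
#' binomial p-value is computed from first principles as the sum of all
#' binomial point masses not exceeding the observed one, and the 95%
#' confidence interval for the branch-one proportion by inverting the exact
#' test (Clopper-Pearson).
#'
#' @param summary An unconstrained, fully absorbed `"ensemble_summary"`.
#' @return A list of class `"branch_symmetry_test"`: `n`, `n_one`,
#'   `proportion`, `p_value`, `conf_int` (95% Clopper-Pearson).
#' @examples
#' es <- run_ensemble(model_params(n_observers = 2), 50, 200, base_seed = 7)
#' branch_symmetry_test(es)
#' @export
branch_symmetry_test <- function(summary) {
  stopifnot(inherits(summary, "ensemble_summary"))
  if (summary$constrained) {
    stop("branch symmetry is only meaningful for unconstrained ensembles",
         call. = FALSE)
  }
  if (summary$n_unabsorbed > 0) {
    stop("ensemble contains unabsorbed runs; extend max_steps", call. = FALSE)
  }
  n <- summary$n_runs
  k <- summary$n_absorbed_one
  structure(list(n = n, n_one = k, proportion = k / n,
                 p_value = exact_binom_p(k, n, 0.5),
                 conf_int = clopper_pearson(k, n, 0.95)),
            class = "branch_symmetry_test")
}

# two-sided exact binomial p-value: sum of point masses <= observed mass
# (with the customary relative tolerance guarding ties in floating point)
exact_binom_p <- function(k, n, p0) {
  masses <- exp(lchoose(n, 0:n) + (0:n) * log(p0) + (n - 0:n) * log1p(-p0))
  obs <- masses[k + 1L]
  min(1, sum(masses[masses <= obs * (1 + 1e-7)]))
}

clopper_pearson <- function(k, n, level) {
  alpha <- 1 - level
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lo, upper = hi)
}

#' @export
print.branch_symmetry_test <- function(x, ...) {
  cat("Exact binomial branch-symmetry test (null: proportion = 1/2)\n")
  cat("  branch one: ", x$n_one, " / ", x$n,
      "  (proportion ", format(x$proportion), ")\n", sep = "")
  cat("  two-sided p-value: ", format(x$p_value), "\n", sep = "")
  cat("  95% CI: [", format(x$conf_int[["lower"]]), ", ",
      format(x$conf_int[["upper"]]), "]\n", sep = "")
  invisible(x)
}

#' Apply the control-designation constraint
#'
#' When the label Pcb0 is designated as the control, stable position #2
#' (probability 0 of the direct relationship) eliminates itself: Pcb0
#' cannot be associated both with biological change and with no change.
#' The minimal reading of this self-elimination is post-selection: the
#' trajectories absorbed at 0 are discarded and the surviving ensemble has
#' empirical Prob(direct) = 1.
#'
#' @param trajectories A list of `"placebo_trajectory"` objects simulated
#'   with identical parameters.
#' @return A constrained `"ensemble_summary"`. If no trajectory survives,
#'   the summary carries `degenerate = TRUE` rather than erroring.
#' @examples
#' ps <- model_params(n_observers = 2)
#' trajs <- lapply(1:10, function(i) simulate_trajectory(ps, 200, seed = i))
#' apply_control_constraint(trajs)
#' @export
apply_control_constraint <- function(trajectories) {
  stopifnot(length(trajectories) > 0,
            all(vapply(trajectories, inherits, logical(1),
                       "placebo_trajectory")))
  params <- trajectories[[1L]]$params
  same <- vapply(trajectories, function(t) identical(t$params, params),
                 logical(1))
  if (!all(same)) {
    stop("all trajectories must share identical model parameters",
         call. = FALSE)
  }
  keep <- vapply(trajectories, function(t) t$absorbed_at != "zero",
                 logical(1))
  survivors <- trajectories[keep]
  summarize_ensemble(survivors, params,
                     base_seed = trajectories[[1L]]$seed,
                     constrained = TRUE,
                     n_discarded = sum(!keep))
}

#' Sweep median absorption step over N and fluctuation width
#'
#' Grid experiment over the number of observers and the fluctuation
#' half-width: for each cell, `n_runs_per_cell` trajectories are simulated
#' and the median absorption step recorded. Larger N or larger fluctuations
#' amplify deviations from the metastable point faster, so medians decrease
#' along both axes. Cells with N < 2 are reported as no-transition
#' (`NA` median, `frac_absorbed = 0`).
#'
#' @param n_values Integer vector of observer counts.
#' @param widths Numeric vector of fluctuation half-widths.
#' @param n_runs_per_cell Trajectories per grid cell.
#' @param base_seed Integer base seed; each cell uses an offset block of
#'   seeds so cells are independent.
#' @param max_steps Maximum steps per trajectory.
#' @return A data.frame with columns `N`, `half_width`, `n_runs`,
#'   `median_step`, `q25`, `q75`, `frac_absorbed`.
#' @examples
#' sweep_absorption(c(2, 4), c(0.5e-15, 1e-5), n_runs_per_cell = 20,
#'                  base_seed = 1)
#' @export
sweep_absorption <- function(n_values, widths, n_runs_per_cell = 200L,
                             base_seed = 1L, max_steps = 500L) {
  stopifnot(n_runs_per_cell >= 1)
  grid <- expand.grid(N = n_values, half_width = widths,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    N <- grid$N[i]; w <- grid$half_width[i]
    cell_seed <- as.integer(base_seed) + (i - 1L) * as.integer(n_runs_per_cell)
    if (N < 2) {
      rows[[i]] <- data.frame(N = N, half_width = w,
                              n_runs = n_runs_per_cell,
                              median_step = NA_real_, q25 = NA_real_,
                              q75 = NA_real_, frac_absorbed = 0)
      next
    }
    params <- model_params(n_observers = N,
                           fluct = fluctuation_spec("uniform", w))
    es <- run_ensemble(params, n_runs_per_cell, max_steps,
                       base_seed = cell_seed)
    s <- es$absorption_step_stats
    rows[[i]] <- data.frame(N = N, half_width = w,
                            n_runs = n_runs_per_cell,
                            median_step = s[["median"]],
                            q25 = s[["q25"]], q75 = s[["q75"]],
                            frac_absorbed =
                              1 - es$n_unabsorbed / es$n_runs)
  }
  do.call(rbind, rows)
}
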