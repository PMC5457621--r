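#' One step of the stochastic recurrence
#'
#' Applies the agreement map to a fluctuation-perturbed probability:
#' \deqn{p_{n+1} = \frac{1}{1 + \left(\frac{1}{p_n + \epsilon_{n+1}} - 1
#' \right)^N}.}
#' The perturbed value `p + eps` is clamped to `[0, 1]` before the map is
#' applied: outside values are only reachable in the immediate neighbourhood
#' of the absorbing boundaries, where the state is already decided, and the
#' nearer boundary is absorbing.
#'
#' At the exact metastable point, `step_prob(0.5, 0, N) == 0.5` for every N;
#' any non-zero fluctuation is amplified by the local derivative N, which is
#' the engine of the metastability-to-absorption transition.
#'
#' @param p Current probability in `[0, 1]`.
#' @param eps Fluctuation, `|eps| < 1`, finite.
#' @param n_observers Non-negative integer N.
#' @return The updated probability.
#' @examples
#' step_prob(0.5, 0, 2)        # exactly 0.5
#' step_prob(0.5, 1e-9, 2)     # about 0.5 + 2e-9
#' @export
step_prob <- function(p, eps, n_observers) {
  check_prob(p, "p")
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) ||
      abs(eps) >= 1) {
    stop("eps must be a finite fluctuation with |eps| < 1", call. = FALSE)
  }
  x <- min(max(p + eps, 0), 1)
  agreement_prob(x, n_observers)
}

#' Simulate one trajectory of the recurrence
#'
#' Iterates [step_prob()] from `p0`, drawing a fresh fluctuation at every
#' step, until absorption or `max_steps`. A trajectory is absorbed when the
#' iterate comes within `atol` of a boundary; the final value is then
#' snapped to exactly 0 or 1 (the iterates approach the boundary
#' quadratically, and both boundaries are exact fixed points of the map).
#' The first step at which `|p - 1/2|` exceeds `transition_threshold` is
#' recorded as the transition step.
#'
#' The simulation is fully reproducible: the RNG is seeded with `seed`
#' before the first draw, so identical `(params, max_steps, seed)` give a
#' bit-identical trajectory.
#'
#' @param params A [model_params()] object.
#' @param max_steps Maximum number of recurrence steps (>= 1).
#' @param seed Integer seed for the fluctuation stream.
#' @param atol Absorption tolerance (distance to a boundary below which the
#'   trajectory is declared absorbed).
#' @param transition_threshold Deviation from 1/2 that counts as the
#'   transition out of the metastable region; default 0.25, halfway between
#'   the metastable point and either boundary.
#' @return An object of class `"placebo_trajectory"`: list with `values`
#'   (p0 ... pT), `eps_applied` (fluctuation used at each step),
#'   `absorbed_at` (`"zero"`, `"one"` or `"none"`), `absorption_step`,
#'   `transition_step` (NA if never), `seed`, `params`.
#' @examples
#' tr <- simulate_trajectory(model_params(n_observers = 2), 200, seed = 1)
#' tr$absorbed_at
#' @export
simulate_trajectory <- function(params, max_steps, seed, atol = 1e-12,
                                transition_threshold = 0.25) {
  stopifnot(inherits(params, "model_params"),
            length(max_steps) == 1L, max_steps >= 1,
            max_steps == as.integer(max_steps))
  stopifnot(transition_threshold > 0, transition_threshold < 0.5)
  set.seed(as.integer(seed))
  N <- params$n_observers
  values <- numeric(max_steps + 1L)
  eps_applied <- rep(NA_real_, max_steps)
  values[1L] <- params$p0
  absorbed_at <- "none"
  absorption_step <- NA_integer_
  transition_step <- if (abs(params$p0 - 0.5) > transition_threshold) 0L
                     else NA_integer_
  p <- params$p0
  n_done <- 0L
  for (i in seq_len(max_steps)) {
    eps <- draw_fluctuations(params$fluct, 1L)
    p <- step_prob(p, eps, N)
    eps_applied[i] <- eps
    values[i + 1L] <- p
    n_done <- i
    if (is.na(transition_step) && abs(p - 0.5) > transition_threshold) {
      transition_step <- i
    }
    if (p <= atol || p >= 1 - atol) {
      absorbed_at <- if (p >= 0.5) "one" else "zero"
      p <- if (p >= 0.5) 1 else 0
      values[i + 1L] <- p
      absorption_step <- i
      break
    }
  }
  structure(list(values = values[seq_len(n_done + 1L)],
                 eps_applied = eps_applied[seq_len(n_done)],
                 absorbed_at = absorbed_at,
                 absorption_step = absorption_step,
                 transition_step = transition_step,
                 seed = as.integer(seed),
                 params = params),
            class = "placebo_trajectory")
}

#' First transition step of a trajectory
#'
#' First index n (1-based step count; the initial value is step 0) with
#' `|p_n - 1/2| > threshold`, or `NA` if the trajectory never leaves the
#' metastable region.
#'
#' @param traj A `"placebo_trajectory"`.
#' @param threshold Deviation threshold in (0, 0.5).
#' @return Integer step index, or `NA_integer_`.
#' @export
transition_step <- function(traj, threshold = 0.25) {
  stopifnot(inherits(traj, "placebo_trajectory"),
            threshold > 0, threshold < 0.5)
  idx <- which(abs(traj$values - 0.5) > threshold)
  if (length(idx) == 0L) return(NA_integer_)
  as.integer(idx[1L] - 1L)
}

#' @export
print.placebo_trajectory <- function(x, ...) {
  n <- length(x$values) - 1L
  cat("Recurrence trajectory (N = ", x$params$n_observers,
      ", p0 = ", format(x$params$p0), ", seed = ", x$seed, ")\n", sep = "")
  cat("  steps simulated:  ", n, "\n")
  cat("  absorbed at:      ", x$absorbed_at,
      if (!is.na(x$absorption_step))
        paste0(" (step ", x$absorption_step, ")") else "", "\n", sep = "")
  cat("  transition step:  ",
      if (is.na(x$transition_step)) "none" else x$transition_step,
      "\n", sep = "")
  cat("  final value:      ", format(x$values[length(x$values)]), "\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.placebo_trajectory <- function(x, ...) {
  data.frame(step = seq_along(x$values) - 1L,
             p = x$values,
             eps_applied = c(NA_real_, x$eps_applied))
}

#' Write a trajectory to CSV
#'
#' Long format with columns `step`, `p`, `eps_applied` (the fluctuation
#' that produced each value; `NA` for the initial value). Full decimal
#' precision, RFC-4180 dialect with a header row.
#'
#' @param traj A `"placebo_trajectory"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  df$p <- format_full(df$p)
  df$eps_applied <- format_full(df$eps_applied)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# locale-independent full-precision decimal formatting
format_full <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}
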