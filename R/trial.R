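#' Virtual two-placebo trial configuration
#'
#' Settings for a simulated experiment comparing two inert placebos that
#' differ only by their labels (Pcb0, designated control, and Pcb1), with
#' a binary biological outcome per sample: no change ("down") or change
#' ("up").
#'
#' @param n_per_arm Samples per label arm (>= 1).
#' @param assessment `"local"` (correlations first assessed inside the
#'   experiment: label-outcome correlations emerge, the constrained stable
#'   position) or `"remote"` (first assessed by an outside supervisor:
#'   biological changes land at random places, no correlation).
#' @param background_rate Probability of a spontaneous "up" outcome in the
#'   untreated state; default 0. An extension for power curves, not part of
#'   the core model.
#' @param flip_noise Probability that an outcome is misclassified; default
#'   0. Likewise an extension for power curves.
#' @param remote_style `"permute"` (default: the local-mode outcome totals
#'   are redistributed uniformly at random over all samples, preserving both
#'   margins) or `"bernoulli"` (each sample changes independently with
#'   probability 1/2).
#' @param seed Integer seed.
#' @return An object of class `"trial_config"`.
#' @examples
#' trial_config(20, "local", seed = 7)
#' @export
trial_config <- function(n_per_arm, assessment = c("local", "remote"),
                         background_rate = 0, flip_noise = 0,
                         remote_style = c("permute", "bernoulli"),
                         seed = 1L) {
  assessment <- match.arg(assessment)
  remote_style <- match.arg(remote_style)
  stopifnot(length(n_per_arm) == 1L, n_per_arm >= 1,
            n_per_arm == as.integer(n_per_arm))
  check_prob(background_rate, "background_rate")
  check_prob(flip_noise, "flip_noise")
  structure(list(n_per_arm = as.integer(n_per_arm),
                 assessment = assessment,
                 background_rate = background_rate,
                 flip_noise = flip_noise,
                 remote_style = remote_style,
                 seed = as.integer(seed)),
            class = "trial_config")
}

#' Simulate a two-placebo trial
#'
#' Generates a label-by-outcome 2x2 contingency table under the model's
#' prediction for the chosen assessment mode and tests it for association.
#'
#' Local mode realizes the constrained stable position #1: every Pcb1
#' sample shows a change ("up"), every Pcb0 sample none ("down"); then the
#' `background_rate` and `flip_noise` perturbations are applied per sample.
#' Remote mode keeps the same total number of "up" outcomes but assigns
#' them uniformly at random over all samples irrespective of label (the
#' margin-preserving permutation; or independent Bernoulli(1/2) outcomes
#' when `remote_style = "bernoulli"`).
#'
#' @param config A [trial_config()].
#' @param alpha Significance level used to call a relationship; default
#'   0.05.
#' @return An object of class `"trial_result"`: `table` (2x2 counts, rows
#'   `Pcb0`/`Pcb1`, columns `down`/`up`), `assessment`, `p_value` (exact
#'   two-sided test of the null Prob(up | Pcb0) = Prob(up | Pcb1)),
#'   `odds_ratio` (cross-product, orientated so that a direct relationship
#'   gives a large value), `relationship_called` (`"direct"`, `"reverse"`
#'   or `"none"`), `config`.
#' @examples
#' simulate_trial(trial_config(20, "local", seed = 7))
#' simulate_trial(trial_config(20, "remote", seed = 7))
#' @export
simulate_trial <- function(config, alpha = 0.05) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed)
  n <- config$n_per_arm
  label <- rep(c("Pcb0", "Pcb1"), each = n)
  # stable position #1: perfect direct relationship
  up <- c(rep(FALSE, n), rep(TRUE, n))
  if (config$background_rate > 0) {
    spont <- stats::runif(2L * n) < config$background_rate
    up <- up | spont
  }
  if (config$flip_noise > 0) {
    flip <- stats::runif(2L * n) < config$flip_noise
    up <- xor(up, flip)
  }
  if (config$assessment == "remote") {
    up <- switch(config$remote_style,
                 permute = sample(up),
                 bernoulli = stats::runif(2L * n) < 0.5)
  }
  tab <- matrix(c(sum(label == "Pcb0" & !up), sum(label == "Pcb0" & up),
                  sum(label == "Pcb1" & !up), sum(label == "Pcb1" & up)),
                nrow = 2, byrow = TRUE,
                dimnames = list(label = c("Pcb0", "Pcb1"),
                                outcome = c("down", "up")))
  pval <- exact_test_2x2(tab)
  or <- trial_odds_ratio(tab)
  called <- if (pval >= alpha || is.nan(or)) "none"
            else if (or > 1) "direct" else "reverse"
  structure(list(table = tab, assessment = config$assessment,
                 p_value = pval, odds_ratio = or,
                 relationship_called = called, config = config),
            class = "trial_result")
}

# cross-product ratio orientated so that the direct relationship
# (Pcb0 -> down, Pcb1 -> up) yields values > 1
trial_odds_ratio <- function(tab) {
  num <- tab["Pcb0", "down"] * tab["Pcb1", "up"]
  den <- tab["Pcb0", "up"] * tab["Pcb1", "down"]
  if (den == 0 && num == 0) return(NaN)
  if (den == 0) return(Inf)
  num / den
}

#' @export
print.trial_result <- function(x, ...) {
  cat("Two-placebo trial,", x$assessment, "assessment\n")
  print(x$table)
  cat("  exact two-sided p-value: ", format(x$p_value), "\n", sep = "")
  cat("  odds ratio (direct orientation): ", format(x$odds_ratio), "\n",
      sep = "")
  cat("  relationship called: ", x$relationship_called, "\n", sep = "")
  invisible(x)
}

#' Exact two-sided test of a 2x2 contingency table
#'
#' Tests the null hypothesis of no label-outcome association,
#' Prob(up | Pcb0) = Prob(up | Pcb1), conditioning on both margins: the
#' hypergeometric point probabilities of all tables with the observed
#' margins are computed from log-factorials and those no more probable than
#' the observed table are summed. This is the fixed-margin exact test
#' appropriate for arbitrarily small arms.
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value. An all-zero table returns 1 (degenerate:
#'   no data, no evidence of association).
#' @examples
#' exact_test_2x2(matrix(c(20, 0, 0, 20), 2, 2))
#' exact_test_2x2(matrix(c(10, 10, 10, 10), 2, 2))
#' @export
exact_test_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2L, 2L)))
  x <- as.vector(table)
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x))) {
    stop("table must contain non-negative integer counts", call. = FALSE)
  }
  n <- sum(x)
  if (n == 0) return(1)
  r1 <- sum(table[1L, ]); r2 <- sum(table[2L, ])
  c1 <- sum(table[, 1L])
  # free cell a = table[1,1]; hypergeometric support
  lo <- max(0L, c1 - r2)
  hi <- min(r1, c1)
  a_obs <- table[1L, 1L]
  lp <- vapply(lo:hi, function(a) {
    lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1)
  }, numeric(1))
  probs <- exp(lp)
  obs <- probs[a_obs - lo + 1L]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

#' Monte-Carlo power of the trial contrast
#'
#' Estimates the rejection rate of the exact association test at level
#' `alpha` under each assessment mode over `n_sims` simulated trials, and
#' the gap between them. With no noise, local mode produces the perfectly
#' separated table every time (rejection rate 1 for n_per_arm >= 4), while
#' remote mode satisfies the test's null, so its rate is the type-I error
#' (at most `alpha`; the exact test is conservative).
#'
#' @param config A [trial_config()]; its `assessment` field is ignored —
#'   both modes are run.
#' @param n_sims Number of simulated trials per mode.
#' @param alpha Significance level.
#' @return A list of class `"trial_power"`: `rejection_rate_local`,
#'   `rejection_rate_remote`, `interaction_gap` (local minus remote),
#'   `n_sims`, `alpha`.
#' @examples
#' trial_power(trial_config(20, seed = 1), n_sims = 50)
#' @export
trial_power <- function(config, n_sims = 500L, alpha = 0.05) {
  stopifnot(inherits(config, "trial_config"), n_sims >= 1)
  rates <- vapply(c("local", "remote"), function(mode) {
    rej <- vapply(seq_len(n_sims), function(i) {
      cfg <- config
      cfg$assessment <- mode
      cfg$seed <- config$seed + i
      simulate_trial(cfg, alpha = alpha)$p_value < alpha
    }, logical(1))
    mean(rej)
  }, numeric(1))
  structure(list(rejection_rate_local = rates[["local"]],
                 rejection_rate_remote = rates[["remote"]],
                 interaction_gap = rates[["local"]] - rates[["remote"]],
                 n_sims = as.integer(n_sims), alpha = alpha),
            class = "trial_power")
}

#' @export
print.trial_power <- function(x, ...) {
  cat("Trial-contrast power (", x$n_sims, " sims/mode, alpha = ", x$alpha,
      ")\n", sep = "")
  cat("  local rejection rate:  ", format(x$rejection_rate_local), "\n")
  cat("  remote rejection rate: ", format(x$rejection_rate_remote), "\n")
  cat("  interaction gap:       ", format(x$interaction_gap), "\n")
  invisible(x)
}
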