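#' N-observer agreement probability
#'
#' Probability that a team of N interacting observers, each independently
#' expecting a direct relationship with probability p, agrees on a direct
#' relationship once disagreeing joint configurations are discarded and the
#' agreeing ones renormalized (the intersubjective-agreement constraint seen
#' from an uninvolved standpoint):
#' \deqn{\mathrm{Prob}(direct) = \frac{1}{1 + (1/p - 1)^N}
#'       = \frac{p^N}{p^N + q^N}, \quad q = 1 - p.}
#'
#' Boundary values are defined by continuity: at `p = 0` the result is 0 and
#' at `p = 1` it is 1 (for N >= 1), so the absorbing states remain evaluable.
#' With no observers (`N = 0`) the probability is 1/2 for every p.
#'
#' @param p Probability (vectorized) in `[0, 1]`.
#' @param n_observers Non-negative integer N.
#' @return Probability vector, same length as `p`.
#' @examples
#' agreement_prob(2/3, 2)       # 0.8
#' agreement_prob(0.42, 0)      # 1/2 regardless of p
#' @seealso [agreement_prob_d()] for the two-observer d-interpolation.
#' @export
agreement_prob <- function(p, n_observers) {
  check_prob(p, "p")
  stopifnot(length(n_observers) == 1L, is.finite(n_observers),
            n_observers >= 0, n_observers == as.integer(n_observers))
  N <- as.integer(n_observers)
  if (N == 0L) return(rep(0.5, length(p)))
  q <- 1 - p
  # Algebraically p^N / (p^N + q^N), computed in deviation form
  #   1/2 + (p - q) s / (2 (p^N + q^N)),  s = sum_{k} p^k q^{N-1-k},
  # because p^N - q^N = (p - q) s. Near p = 1/2 the direct ratio cancels
  # catastrophically, while here p - q is exact and the deviation keeps
  # full relative precision -- essential when iterating on 1e-15-scale
  # deviations from the metastable point.
  # p - q = 2 (p - 1/2); p - 1/2 is exact in floating point (Sterbenz),
  # whereas 1 - p can round by half an ulp for p just below 1/2
  s <- numeric(length(p))
  for (k in 0:(N - 1L)) s <- s + p^k * q^(N - 1L - k)
  dev <- (p - 0.5) * s / (p^N + q^N)
  out <- ifelse(p <= 0, 0, ifelse(p >= 1, 1, 0.5 + dev))
  pmin(pmax(as.numeric(out), 0), 1)
}

#' Two-observer agreement probability with independence parameter d
#'
#' Interpolates between the fully independent two-observer agreement
#' probability (d = 0) and classical probability (d = pq):
#' \deqn{\mathrm{Prob}(direct) = \frac{p^2 + d}{p^2 + q^2 + 2d},
#'       \quad 0 \le d \le pq.}
#' d acts as a covariance-like offset on the joint expectations of the two
#' observers; it can be read as how far the team's attention is drawn away
#' from the experiment (d = 0: fully committed; d = pq: fully distracted,
#' classical behaviour).
#'
#' @param p Probability (vectorized) in `[0, 1]`.
#' @param d Independence parameter, in `[0, p(1-p)]` elementwise.
#' @return Probability vector.
#' @examples
#' agreement_prob_d(0.3, 0.21)  # d = pq: classical, returns p = 0.3
#' agreement_prob_d(2/3, 0)     # d = 0: equals agreement_prob(2/3, 2) = 0.8
#' @export
agreement_prob_d <- function(p, d) {
  check_prob(p, "p")
  q <- 1 - p
  pq <- p * q
  if (!is.numeric(d) || any(!is.finite(d)) || any(d < 0) ||
      any(d > pq + 1e-12)) {
    stop("d must lie in [0, p*(1-p)]; the joint outcome table requires ",
         "pq - d >= 0", call. = FALSE)
  }
  (p^2 + d) / (p^2 + q^2 + 2 * d)
}

#' Joint outcome table for two observers
#'
#' Weights of the four joint observer outcomes for a pair of observers with
#' independence parameter d. The diagonal (agreeing) cells carry
#' \eqn{p^2 + d} and \eqn{q^2 + d}; the off-diagonal (disagreeing) cells
#' carry \eqn{pq - d} each, which is why d may not exceed pq. The weights
#' sum to 1, and renormalizing the agreement diagonal reproduces
#' [agreement_prob_d()] — the table is the model behind that formula.
#'
#' @param p Probability in `[0, 1]` (scalar).
#' @param d Independence parameter in `[0, p(1-p)]`.
#' @return A 2x2 numeric matrix with dimnames
#'   `list(observer1 = c("direct","reverse"), observer2 = c("direct","reverse"))`.
#' @examples
#' joint_outcome_table(0.5, 0)     # four cells of 0.25
#' joint_outcome_table(0.5, 0.25)  # perfectly correlated observers
#' @export
joint_outcome_table <- function(p, d) {
  stopifnot(length(p) == 1L, length(d) == 1L)
  check_prob(p, "p")
  q <- 1 - p
  if (!is.finite(d) || d < 0 || d > p * q + 1e-12) {
    stop("d must lie in [0, p*(1-p)]", call. = FALSE)
  }
  matrix(c(p^2 + d, p * q - d,
           p * q - d, q^2 + d),
         nrow = 2, byrow = TRUE,
         dimnames = list(observer1 = c("direct", "reverse"),
                         observer2 = c("direct", "reverse")))
}

#' Amplitude pair
#'
#' A pair of real probability amplitudes (a, b) with a^2 the probability of
#' the label Pcb0 and b^2 the probability of Pcb1. Amplitudes are real by
#' construction of the model; complex amplitudes are not supported.
#'
#' @param a,b Finite real amplitudes.
#' @return An object of class `"amplitude_pair"`.
#' @examples
#' amplitude_pair(1 / sqrt(2), 1 / sqrt(2))
#' @export
amplitude_pair <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L,
            is.finite(a), is.finite(b))
  structure(list(a = a, b = b), class = "amplitude_pair")
}

#' @export
print.amplitude_pair <- function(x, ...) {
  cat("Amplitude pair: a = ", format(x$a), " (a^2 = ", format(x$a^2),
      "), b = ", format(x$b), " (b^2 = ", format(x$b^2), ")\n", sep = "")
  invisible(x)
}

as_amplitude_pair <- function(amps) {
  if (inherits(amps, "amplitude_pair")) return(amps)
  if (is.numeric(amps) && length(amps) == 2L) {
    return(amplitude_pair(amps[[1L]], amps[[2L]]))
  }
  stop("expected an amplitude_pair or a numeric vector c(a, b)",
       call. = FALSE)
}

#' Coherent (square-of-sum) path probabilities
#'
#' Path calculus without a remote supervisor: the two paths leading to a
#' direct relationship are indistinguishable, so their amplitudes are summed
#' before squaring,
#' \deqn{\mathrm{Prob}(direct) = (a\,a + b\,b)^2, \qquad
#'       \mathrm{Prob}(reverse) = (b\,a - a\,b)^2 = 0.}
#' The reverse component vanishes identically — a destructive interference —
#' so with normalized amplitudes the result is (1, 0).
#'
#' @param amps An [amplitude_pair()] or numeric `c(a, b)`.
#' @return Named numeric vector `c(direct = ..., reverse = ...)`.
#' @examples
#' coherent_path_probs(amplitude_pair(1/sqrt(2), 1/sqrt(2)))  # c(1, 0)
#' @export
coherent_path_probs <- function(amps) {
  amps <- as_amplitude_pair(amps)
  a <- amps$a; b <- amps$b
  c(direct = (a * a + b * b)^2,
    reverse = (b * a - a * b)^2)
}

#' Classical (sum-of-squares) path probabilities
#'
#' Path calculus with a remote supervisor: each path is distinguishable, so
#' each amplitude is squared first and the probabilities are summed,
#' \deqn{\mathrm{Prob}(direct) = (a\,a)^2 + (b\,b)^2, \qquad
#'       \mathrm{Prob}(reverse) = (b\,a)^2 + (a\,b)^2 = 2(ab)^2.}
#' The two components sum to \eqn{(a^2 + b^2)^2}, i.e. to 1 for normalized
#' amplitudes. The difference from [coherent_path_probs()] in the direct
#' component is the interference term \eqn{-2(ab)^2}.
#'
#' @inheritParams coherent_path_probs
#' @return Named numeric vector `c(direct = ..., reverse = ...)`.
#' @examples
#' classical_path_probs(amplitude_pair(1/sqrt(2), 1/sqrt(2)))  # c(0.5, 0.5)
#' @export
classical_path_probs <- function(amps) {
  amps <- as_amplitude_pair(amps)
  a <- amps$a; b <- amps$b
  c(direct = (a * a)^2 + (b * b)^2,
    reverse = (b * a)^2 + (a * b)^2)
}

#' Predicted probability of a direct relationship under an assessment mode
#'
#' The model's headline prediction for a two-placebo experiment with
#' symmetric amplitudes (a = b = 1/sqrt(2)): with *local* assessment
#' (open-label or local blind; correlations first assessed inside the
#' experiment) the coherent path calculus applies and the probability of a
#' direct relationship is 1; with *remote* assessment (centralized blind;
#' correlations first assessed by an outside supervisor) the classical path
#' calculus applies and the probability is 1/2.
#'
#' @param mode `"local"` or `"remote"`.
#' @return A single probability.
#' @examples
#' assessment_prediction("local")   # 1
#' assessment_prediction("remote")  # 0.5
#' @export
assessment_prediction <- function(mode = c("local", "remote")) {
  mode <- match.arg(mode)
  # a = b = 1/sqrt(2), worked with the exact squared amplitudes
  # a^2 = b^2 = 1/2 so the analytic predictions are exact in floating point
  a2 <- 0.5
  b2 <- 0.5
  switch(mode,
         local  = (a2 + b2)^2,   # square of the summed amplitudes
         remote = a2^2 + b2^2)   # sum of the squared path probabilities
}

#' Total probability of a direct relationship under unstructured perception
#'
#' When the experimenters perceive the two sub-events (outcome given label
#' Pcb0, outcome given label Pcb1) separately instead of as one structured
#' whole, the probability of a direct relationship is given by the law of
#' total probability over the labels:
#' \deqn{\mathrm{Prob}(direct) = \mathrm{Prob}(Pcb_0)\,
#'   \mathrm{Prob}(direct \mid Pcb_0) + \mathrm{Prob}(Pcb_1)\,
#'   \mathrm{Prob}(direct \mid Pcb_1).}
#' With equal priors and the two conditional stable positions (1 and 0) this
#' is 1/2 — no transition occurs, the "Gestalt" ingredient is missing.
#'
#' @param prior_pcb0 Probability of the label Pcb0 (Pcb1 gets the
#'   complement).
#' @param cond_direct_given_pcb0,cond_direct_given_pcb1 Conditional
#'   probabilities of a direct relationship given each label.
#' @return A single probability.
#' @examples
#' total_prob_unstructured(0.5, 1, 0)  # 0.5
#' @export
total_prob_unstructured <- function(prior_pcb0, cond_direct_given_pcb0,
                                    cond_direct_given_pcb1) {
  check_prob(prior_pcb0, "prior_pcb0")
  check_prob(cond_direct_given_pcb0, "cond_direct_given_pcb0")
  check_prob(cond_direct_given_pcb1, "cond_direct_given_pcb1")
  prior_pcb0 * cond_direct_given_pcb0 +
    (1 - prior_pcb0) * cond_direct_given_pcb1
}
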