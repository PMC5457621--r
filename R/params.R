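#' Fluctuation specification
#'
#' Describes the law of the elementary random probability fluctuations
#' \eqn{\epsilon_i} injected at every step of the stochastic recurrence.
#' The default emulates the published simulation conditions: fluctuations
#' drawn uniformly on \eqn{[-0.5\times 10^{-15}, +0.5\times 10^{-15}]}.
#'
#' @param distribution `"uniform"` (on `[-half_width, +half_width]`) or
#'   `"gaussian"` (mean 0, standard deviation `half_width`).
#' @param half_width Positive scale of the fluctuations (half-width of the
#'   uniform law, or standard deviation of the gaussian law). Must be much
#'   smaller than 1; a warning is issued above `1e-3`.
#'
#' @return An object of class `"fluctuation_spec"`.
#' @examples
#' fluctuation_spec()
#' fluctuation_spec("gaussian", 1e-10)
#' @export
fluctuation_spec <- function(distribution = c("uniform", "gaussian"),
                             half_width = 0.5e-15) {
  distribution <- match.arg(distribution)
  stopifnot(is.numeric(half_width), length(half_width) == 1L,
            is.finite(half_width), half_width > 0)
  if (half_width > 1e-3) {
    warning("fluctuation half_width = ", half_width,
            " is not small compared to 1; the model assumes |eps| << 1",
            call. = FALSE)
  }
  structure(list(distribution = distribution, half_width = half_width),
            class = "fluctuation_spec")
}

#' @export
print.fluctuation_spec <- function(x, ...) {
  cat("Fluctuation spec: ", x$distribution,
      ", half-width/sd = ", format(x$half_width), "\n", sep = "")
  invisible(x)
}

# draw n fluctuations from the spec using the current RNG state
draw_fluctuations <- function(spec, n) {
  switch(spec$distribution,
         uniform  = stats::runif(n, -spec$half_width, spec$half_width),
         gaussian = stats::rnorm(n, 0, spec$half_width))
}

#' Model parameterization
#'
#' Bundles the full parameterization of the observer-agreement model: the
#' number of interacting observers N, the elementary probability p of a
#' direct relationship (q = 1 - p is derived), the independence parameter d
#' interpolating between fully independent observer expectations (d = 0) and
#' classical probability (d = p*q), the initial probability p0 of the
#' recurrence, and the fluctuation law.
#'
#' @param n_observers Non-negative integer N.
#' @param p_direct Elementary probability p of a direct relationship, in
#'   `[0, 1]`. Default 0.5 (two indistinguishable placebos).
#' @param d_param Independence parameter d, in `[0, p(1-p)]`. Default 0
#'   (fully committed observers, the quantum-like regime). Only meaningful
#'   for the two-observer calculus; see [agreement_prob_d()].
#' @param p0 Initial probability of the recurrence, default 1/2 (the
#'   no-observer value, a metastable point of the map).
#' @param fluct A [fluctuation_spec()].
#'
#' @return An object of class `"model_params"`.
#' @examples
#' model_params(n_observers = 2)
#' @export
model_params <- function(n_observers = 2L, p_direct = 0.5, d_param = 0,
                         p0 = 0.5, fluct = fluctuation_spec()) {
  stopifnot(length(n_observers) == 1L, is.finite(n_observers),
            n_observers >= 0, n_observers == as.integer(n_observers))
  check_prob(p_direct, "p_direct")
  check_prob(p0, "p0")
  pq <- p_direct * (1 - p_direct)
  if (!is.numeric(d_param) || length(d_param) != 1L || !is.finite(d_param) ||
      d_param < 0 || d_param > pq + 1e-12) {
    stop("d_param must lie in [0, p_direct * (1 - p_direct)] = [0, ",
         format(pq), "]; got ", format(d_param), call. = FALSE)
  }
  if (!inherits(fluct, "fluctuation_spec")) {
    stop("fluct must be a fluctuation_spec object", call. = FALSE)
  }
  structure(list(n_observers = as.integer(n_observers),
                 p_direct = p_direct,
                 d_param = d_param,
                 p0 = p0,
                 fluct = fluct),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Observer-agreement model parameters\n")
  cat("  N (observers):        ", x$n_observers, "\n")
  cat("  p (direct), q:        ", format(x$p_direct), ", ",
      format(1 - x$p_direct), "\n", sep = "")
  cat("  d (independence):     ", format(x$d_param), "\n")
  cat("  p0 (initial):         ", format(x$p0), "\n")
  cat("  fluctuations:          ", x$fluct$distribution, ", half-width ",
      format(x$fluct$half_width), "\n", sep = "")
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(name, " must be a probability in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
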