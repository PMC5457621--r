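#' Fixed points of the N-observer agreement map
#'
#' Locates the fixed points of \eqn{f(p) = 1/(1 + (1/p - 1)^N)} on `[0, 1]`
#' and classifies their stability from the numerically estimated derivative:
#' attracting if |f'(p*)| < 1, repelling if > 1, neutral within tolerance
#' of 1. For any N >= 2 there are exactly three fixed points, 0, 1/2 and 1:
#' the metastable initial position 1/2 (repelling, with |f'(1/2)| = N) and
#' the two absorbing stable positions 1 (position #1) and 0 (position #2).
#' For N = 1 the map is the identity: every p is a fixed point and the
#' result carries an `identity_map` flag with neutral stability.
#'
#' Roots are found by a dense-grid sign-change scan of f(p) - p followed by
#' bisection refinement, so the analysis generalizes to any N without
#' symbolic algebra; the boundary points 0 and 1 are checked directly (they
#' are exact by the continuity convention of [agreement_prob()]).
#'
#' @param n_observers Integer N >= 1.
#' @param grid_n Number of interior grid points for the sign-change scan.
#' @param tol Bisection tolerance on p.
#' @param neutral_tol Stability tolerance: |derivative - 1| below this is
#'   classified neutral.
#' @return An object of class `"fixed_point_result"`: a list with a
#'   data.frame `points` (columns `p_star`, `derivative_magnitude`,
#'   `stability`), the flag `identity_map`, and `n_observers`.
#' @examples
#' fixed_points(2)   # 0 and 1 attracting, 1/2 repelling with |f'| = 2
#' fixed_points(1)   # identity map
#' @export
fixed_points <- function(n_observers, grid_n = 2001L, tol = 1e-12,
                         neutral_tol = 1e-9) {
  stopifnot(length(n_observers) == 1L, is.finite(n_observers),
            n_observers == as.integer(n_observers))
  if (n_observers < 1) {
    stop("n_observers must be >= 1 (the N = 0 map is constant at 1/2, ",
         "every point maps there and none is fixed except 1/2 trivially)",
         call. = FALSE)
  }
  N <- as.integer(n_observers)
  f <- function(p) agreement_prob(p, N)

  if (N == 1L) {
    pts <- data.frame(p_star = c(0, 0.5, 1),
                      derivative_magnitude = c(1, 1, 1),
                      stability = "neutral",
                      stringsAsFactors = FALSE)
    return(structure(list(points = pts, identity_map = TRUE,
                          n_observers = N),
                     class = "fixed_point_result"))
  }

  # boundary fixed points are exact by construction
  roots <- c(0, 1)
  # interior roots: sign-change scan of g(p) = f(p) - p, then bisection
  grid <- seq(tol, 1 - tol, length.out = grid_n)
  g <- f(grid) - grid
  sign_change <- which(g[-length(g)] * g[-1] < 0)
  exact_zero <- which(g == 0)
  for (i in sign_change) {
    lo <- grid[i]; hi <- grid[i + 1]
    glo <- g[i]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      gm <- f(mid) - mid
      if (gm == 0) { lo <- mid; hi <- mid; break }
      if (sign(gm) == sign(glo)) { lo <- mid; glo <- gm } else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  roots <- c(roots, grid[exact_zero])
  # de-duplicate (snap near-half roots onto 1/2, which is exact for all N)
  roots[abs(roots - 0.5) < 1e-8] <- 0.5
  roots <- sort(unique(round(roots / tol) * tol))

  deriv <- vapply(roots, map_derivative, numeric(1), N = N)
  stability <- ifelse(abs(deriv - 1) < neutral_tol, "neutral",
                      ifelse(deriv < 1, "attracting", "repelling"))
  pts <- data.frame(p_star = roots,
                    derivative_magnitude = deriv,
                    stability = stability,
                    stringsAsFactors = FALSE)
  structure(list(points = pts, identity_map = FALSE, n_observers = N),
            class = "fixed_point_result")
}

# |f'(p)| by finite difference: central in the interior, one-sided at the
# boundaries (where f is only defined on [0,1])
map_derivative <- function(p, N, h = 1e-6) {
  f <- function(x) agreement_prob(x, N)
  if (p < h) {
    abs(f(p + h) - f(p)) / h
  } else if (p > 1 - h) {
    abs(f(p) - f(p - h)) / h
  } else {
    abs(f(p + h) - f(p - h)) / (2 * h)
  }
}

#' @export
print.fixed_point_result <- function(x, ...) {
  cat("Fixed points of the agreement map, N =", x$n_observers, "\n")
  if (x$identity_map) {
    cat("  Map is the identity: every p in [0, 1] is a (neutral) fixed",
        "point.\n  Representative points:\n")
  }
  print(x$points, row.names = FALSE)
  invisible(x)
}
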