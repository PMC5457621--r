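# Independent oracles used to cross-check the closed-form implementations.
# These deliberately avoid the code paths they validate.

# Brute-force enumeration of all 2^N observer-outcome configurations:
# each observer sees "direct" with probability p independently; keep the
# all-agree configurations (all direct or all reverse), renormalize, and
# return the direct share.
enum_agreement <- function(p, N) {
  stopifnot(N >= 1)
  cfg <- expand.grid(rep(list(c(TRUE, FALSE)), N))
  w <- apply(cfg, 1, function(r) prod(ifelse(r, p, 1 - p)))
  all_direct <- apply(cfg, 1, all)
  all_reverse <- apply(cfg, 1, function(r) all(!r))
  sum(w[all_direct]) / sum(w[all_direct | all_reverse])
}

# Renormalized agreement diagonal of the two-observer joint table: the
# independent route to the d-interpolated agreement probability.
table_agreement <- function(p, d) {
  tab <- joint_outcome_table(p, d)
  tab["direct", "direct"] /
    (tab["direct", "direct"] + tab["reverse", "reverse"])
}

# shared grid for property-style checks
p_grid <- function(n = 99) seq(1 / (n + 1), n / (n + 1), length.out = n)
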