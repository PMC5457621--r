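test_that("agreement probability matches the enumeration oracle and its closed-form examples", {
  # no observers: 1/2 regardless of p
  expect_equal(agreement_prob(c(0.1, 0.42, 0.9), 0), rep(0.5, 3))
  # symmetry fixed point
  expect_equal(agreement_prob(0.5, 2), 0.5)
  # two observers at p = 2/3: four joint outcomes weighted p^2, pq, qp, q^2;
  # discarding disagreements and renormalizing gives 0.8
  expect_equal(agreement_prob(2 / 3, 2), enum_agreement(2 / 3, 2))
  expect_equal(agreement_prob(2 / 3, 2), 0.8)
  # full grid equivalence against the 2^N-configuration enumeration
  grid <- p_grid(99)
  for (N in 1:6) {
    oracle <- vapply(grid, enum_agreement, numeric(1), N = N)
    expect_lt(max(abs(agreement_prob(grid, N) - oracle)), 1e-12)
  }
})

test_that("agreement probability handles boundaries by continuity and rejects bad input", {
  expect_equal(agreement_prob(0, 3), 0)
  expect_equal(agreement_prob(1, 3), 1)
  expect_error(agreement_prob(-0.1, 2), "probability")
  expect_error(agreement_prob(1.1, 2), "probability")
})

test_that("agreement probability is strictly increasing in p for N >= 1", {
  grid <- p_grid(99)
  for (N in 1:4) {
    expect_true(all(diff(agreement_prob(grid, N)) > 0))
  }
})

test_that("d-interpolated agreement reproduces its endpoints and the joint-table oracle", {
  # d = pq: classical probability, returns p itself
  expect_equal(agreement_prob_d(0.3, 0.3 * 0.7), 0.3)
  # p = q: numerator is half the denominator whatever d
  expect_equal(agreement_prob_d(0.5, 0.1), 0.5)
  # d = 0: coincides with the two-observer agreement probability
  expect_equal(agreement_prob_d(2 / 3, 0), agreement_prob(2 / 3, 2))
  expect_equal(agreement_prob_d(2 / 3, 0), 0.8)
  grid <- p_grid(99)
  expect_lt(max(abs(agreement_prob_d(grid, 0) - agreement_prob(grid, 2))),
            1e-12)
  expect_lt(max(abs(agreement_prob_d(grid, grid * (1 - grid)) - grid)),
            1e-12)
  # joint-table diagonal renormalization is the independent route
  for (p in c(0.2, 0.5, 2 / 3, 0.9)) {
    for (d in c(0, 0.3 * p * (1 - p), p * (1 - p))) {
      expect_equal(agreement_prob_d(p, d), table_agreement(p, d),
                   tolerance = 1e-12)
    }
  }
})

test_that("the joint outcome table is a valid distribution with the stated cells", {
  # independent fair events
  expect_equal(unname(joint_outcome_table(0.5, 0)),
               matrix(0.25, 2, 2))
  # d = pq: perfectly correlated observers
  expect_equal(unname(joint_outcome_table(0.5, 0.25)),
               matrix(c(0.5, 0, 0, 0.5), 2, byrow = TRUE))
  for (p in c(0.2, 0.5, 0.8)) {
    for (d in c(0, 0.5 * p * (1 - p))) {
      tab <- joint_outcome_table(p, d)
      expect_equal(sum(tab), 1)
      expect_true(all(tab >= 0))
      expect_equal(tab["direct", "reverse"], tab["reverse", "direct"])
    }
  }
  # d beyond pq would make the off-diagonal weights negative
  expect_error(joint_outcome_table(0.5, 0.3), "d must lie")
  expect_error(agreement_prob_d(0.3, 0.22), "d must lie")
})

test_that("coherent and classical path calculi give the predicted probabilities", {
  sym <- amplitude_pair(1 / sqrt(2), 1 / sqrt(2))
  expect_equal(coherent_path_probs(sym), c(direct = 1, reverse = 0))
  expect_equal(classical_path_probs(sym), c(direct = 0.5, reverse = 0.5))
  # single path: coherent = classical
  one <- amplitude_pair(1, 0)
  expect_equal(coherent_path_probs(one), c(direct = 1, reverse = 0))
  expect_equal(classical_path_probs(one), c(direct = 1, reverse = 0))
  # normalized non-symmetric amplitudes
  ab <- amplitude_pair(0.6, 0.8)
  expect_equal(coherent_path_probs(ab), c(direct = 1, reverse = 0))
  expect_equal(classical_path_probs(ab),
               c(direct = 0.36^2 + 0.64^2, reverse = 2 * (0.6 * 0.8)^2))
  expect_equal(unname(classical_path_probs(ab)), c(0.5392, 0.4608))
})

test_that("path-calculus conservation and interference identities hold over random amplitudes", {
  set.seed(11)
  for (i in 1:50) {
    theta <- runif(1, 0, 2 * pi)
    amps <- amplitude_pair(cos(theta), sin(theta))  # a^2 + b^2 = 1
    coh <- coherent_path_probs(amps)
    cla <- classical_path_probs(amps)
    expect_true(all(coh >= 0) && all(cla >= 0))
    expect_equal(unname(sum(coh)), 1, tolerance = 1e-12)
    expect_equal(unname(sum(cla)), 1, tolerance = 1e-12)
    # interference term: classical direct minus coherent direct = -2(ab)^2
    expect_lt(abs((cla[["direct"]] - coh[["direct"]]) +
                    2 * (amps$a * amps$b)^2), 1e-12)
  }
  # unnormalized amplitudes: components still sum to (a^2 + b^2)^2 each way
  ab <- amplitude_pair(1.5, -0.7)
  norm2 <- (1.5^2 + 0.7^2)^2
  expect_equal(unname(sum(coherent_path_probs(ab))), norm2)
  expect_equal(unname(sum(classical_path_probs(ab))), norm2)
})

test_that("assessment mode predicts certainty locally and chance remotely", {
  expect_identical(assessment_prediction("local"), 1)
  expect_identical(assessment_prediction("remote"), 0.5)
  expect_error(assessment_prediction("sideways"))
})

test_that("unstructured perception yields the total-probability value with no transition", {
  # equal priors, the two conditional stable positions: stays at 1/2
  expect_equal(total_prob_unstructured(0.5, 1, 0), 0.5)
  # degenerate prior
  expect_equal(total_prob_unstructured(1, 1, 0.37), 1)
  expect_equal(total_prob_unstructured(0.3, 1, 0), 0.3)
  expect_error(total_prob_unstructured(1.5, 1, 0), "probability")
})

test_that("model parameter validation enforces the probability and d domains", {
  expect_error(model_params(n_observers = -1))
  expect_error(model_params(p_direct = 1.2), "probability")
  expect_error(model_params(p_direct = 0.3, d_param = 0.25), "d_param")
  ok <- model_params(n_observers = 3, p_direct = 0.3, d_param = 0.21)
  expect_s3_class(ok, "model_params")
  expect_warning(fluctuation_spec("uniform", 0.01), "not small")
})
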