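paper_ensemble <- function(n_runs, base_seed = 100, N = 2,
                           max_steps = 200) {
  run_ensemble(model_params(n_observers = N,
                            fluct = fluctuation_spec("uniform", 0.5e-15)),
               n_runs, max_steps, base_seed = base_seed)
}

test_that("ensembles are reproducible and their counts partition the runs", {
  a <- paper_ensemble(20)
  b <- paper_ensemble(20)
  expect_identical(a, b)
  expect_equal(a$n_absorbed_one + a$n_absorbed_zero + a$n_unabsorbed,
               a$n_runs)
  # eight runs at the published conditions: all absorbed at 0 or 1
  e8 <- paper_ensemble(8)
  expect_equal(e8$n_unabsorbed, 0)
  expect_equal(e8$n_absorbed_one + e8$n_absorbed_zero, 8)
  expect_lte(e8$absorption_step_stats[["max"]], 200)
  # no observers: nothing ever absorbs
  e0 <- paper_ensemble(10, N = 0, max_steps = 100)
  expect_equal(e0$n_unabsorbed, 10)
})

test_that("the absorbing branch is chosen symmetrically", {
  es <- paper_ensemble(2000, base_seed = 2000)
  expect_equal(es$n_unabsorbed, 0)
  prop <- es$n_absorbed_one / es$n_runs
  # exact binomial 99% interval around 1/2 for n = 2000
  lo <- qbinom(0.005, 2000, 0.5) / 2000
  hi <- qbinom(0.995, 2000, 0.5) / 2000
  expect_gte(prop, lo)
  expect_lte(prop, hi)
  bt <- branch_symmetry_test(es)
  expect_gte(bt$conf_int[["lower"]], 0)
  expect_true(bt$conf_int[["lower"]] <= 0.5 &&
                bt$conf_int[["upper"]] >= 0.5)
})

test_that("the exact binomial branch test reproduces first-principles tail arithmetic", {
  mk <- function(n_one, n_zero) {
    es <- paper_ensemble(n_one + n_zero)
    es$n_absorbed_one <- n_one
    es$n_absorbed_zero <- n_zero
    es$n_runs <- n_one + n_zero
    es$n_unabsorbed <- 0L
    es
  }
  # perfectly balanced: p = 1
  expect_equal(branch_symmetry_test(mk(4, 4))$p_value, 1)
  # all eight on one branch: p = 2 * (1/2)^8
  expect_equal(branch_symmetry_test(mk(8, 0))$p_value, 2 * (1 / 2)^8)
  expect_equal(branch_symmetry_test(mk(8, 0))$p_value, 0.0078125)
  # cross-check against the independent implementation in stats
  for (k in c(3, 10, 17)) {
    ours <- branch_symmetry_test(mk(k, 20 - k))$p_value
    ref <- stats::binom.test(k, 20, 0.5)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("the branch test refuses constrained or incomplete ensembles", {
  es <- paper_ensemble(10)
  es$n_unabsorbed <- 1L
  expect_error(branch_symmetry_test(es), "unabsorbed")
  es2 <- paper_ensemble(10)
  es2$constrained <- TRUE
  expect_error(branch_symmetry_test(es2), "unconstrained")
})

test_that("the control-designation constraint post-selects the direct branch", {
  params <- model_params(n_observers = 2,
                         fluct = fluctuation_spec("uniform", 0.5e-15))
  trajs <- lapply(1:100, function(i) {
    simulate_trajectory(params, 200, seed = 300 + i)
  })
  con <- apply_control_constraint(trajs)
  expect_true(con$constrained)
  expect_equal(con$n_absorbed_zero, 0)
  expect_equal(con$n_runs + con$n_discarded, 100)
  # surviving fraction near 1/2 by branch symmetry
  expect_gt(con$n_runs, 30)
  expect_lt(con$n_runs, 70)
  # survivors all sit at probability 1: empirical Prob(direct) = 1
  expect_equal(con$n_absorbed_one, con$n_runs)
  # filter semantics on a hand-picked subset
  one_idx <- which(vapply(trajs, function(t) t$absorbed_at, "") == "one")
  zero_idx <- which(vapply(trajs, function(t) t$absorbed_at, "") == "zero")
  mix <- trajs[c(one_idx[1:2], zero_idx[1:2], one_idx[3])]
  con_mix <- apply_control_constraint(mix)
  expect_equal(con_mix$n_runs, 3)
  expect_equal(con_mix$n_discarded, 2)
  # an all-zero ensemble is flagged degenerate, not an error
  con_deg <- apply_control_constraint(trajs[zero_idx[1:3]])
  expect_true(con_deg$degenerate)
  expect_equal(con_deg$n_runs, 0)
})

test_that("absorption accelerates with more observers and larger fluctuations", {
  tab <- sweep_absorption(c(2, 3, 4), c(0.5e-15, 1e-10, 1e-5),
                          n_runs_per_cell = 50, base_seed = 77,
                          max_steps = 300)
  expect_equal(nrow(tab), 9L)
  expect_true(all(tab$frac_absorbed == 1))
  # medians non-increasing in N at each width
  for (w in unique(tab$half_width)) {
    med <- tab$median_step[tab$half_width == w][order(tab$N[tab$half_width == w])]
    expect_true(all(diff(med) <= 0))
  }
  # medians non-increasing in width at each N
  for (N in unique(tab$N)) {
    sub <- tab[tab$N == N, ]
    med <- sub$median_step[order(sub$half_width)]
    expect_true(all(diff(med) <= 0))
  }
  # cells below two observers are reported as no-transition
  tab1 <- sweep_absorption(1, 1e-5, n_runs_per_cell = 5, base_seed = 1)
  expect_true(is.na(tab1$median_step))
  expect_equal(tab1$frac_absorbed, 0)
})
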