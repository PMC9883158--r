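test_that("the five constrained models forbid the documented transitions", {
  expect_setequal(rownames(build_rate_model("strong_differentiation")$mask),
                  c("q02", "q03", "q13"))
  expect_setequal(rownames(build_rate_model("weak_differentiation")$mask),
                  c("q02", "q03"))
  expect_setequal(rownames(build_rate_model("strong_unification")$mask),
                  c("q01", "q02", "q31"))
  expect_setequal(rownames(build_rate_model("weak_unification")$mask),
                  c("q01", "q02"))
  full <- build_rate_model("full")
  expect_length(full$free, 12)
  expect_equal(nrow(full$mask), 0)
  expect_error(build_rate_model("nope"), "unknown")
  # rows sum to zero, masked entries exactly zero
  md <- build_rate_model("strong_unification", rates = c(q10 = 2))
  expect_equal(rowSums(md$Q), rep(0, 4), ignore_attr = TRUE)
  expect_identical(md$Q[1, 2], 0)  # q01
  expect_identical(md$Q[4, 2], 0)  # q31
  expect_equal(md$Q[2, 1], 2)      # q10 passed through
})

test_that("transition probabilities are stochastic and match the two-state
           closed form", {
  md <- build_rate_model("full")
  expect_equal(transition_probabilities(md, 0), diag(4))
  P <- transition_probabilities(md, 0.7)
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12)
  expect_true(all(P >= 0))
  # embedded 2-state chain
  q01 <- 1.3; q10 <- 0.6
  Q2 <- matrix(0, 4, 4)
  Q2[1, 2] <- q01; Q2[2, 1] <- q10
  diag(Q2) <- -rowSums(Q2)
  for (t in c(0.2, 1, 4)) {
    P <- transition_probabilities(Q2, t)
    p01 <- (q01 / (q01 + q10)) * (1 - exp(-(q01 + q10) * t))
    expect_equal(P[1, 2], p01, tolerance = 1e-10)
  }
})

test_that("pruning likelihood equals exhaustive enumeration", {
  # single tip: log root frequency
  one <- list(edge = matrix(c(2, 1), 1), tip.label = "A", Nnode = 1L,
              edge.length = 0.3)
  class(one) <- "phylo"
  expect_equal(pruning_loglik(one, c(A = 2), build_rate_model("full")),
               log(0.25), tolerance = 1e-12)

  # two-tip direct summation
  two <- ape::read.tree(text = "(A:0.4,B:0.9);")
  md <- build_rate_model("weak_differentiation")
  st2 <- c(A = 1L, B = 3L)
  P1 <- transition_probabilities(md, 0.4)
  P2 <- transition_probabilities(md, 0.9)
  direct <- log(sum(0.25 * P1[, 2] * P2[, 4]))
  expect_equal(pruning_loglik(two, st2, md), direct, tolerance = 1e-12)

  # random instances vs brute force
  set.seed(10)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    tr <- random_tree(n)
    mdr <- build_rate_model(sample(names(coevauth:::ms_masks), 1),
                            rates = stats::setNames(stats::rexp(12),
                                                    rownames(coevauth:::ms_pair_names())))
    str <- stats::setNames(sample(0:3, n, replace = TRUE), tr$tip.label)
    expect_equal(pruning_loglik(tr, str, mdr),
                 brute_force_ctmc_loglik(tr, str, mdr$Q), tolerance = 1e-10)
  }
  # missing states as ambiguous
  st <- c(A = 1L, B = NA)
  val <- pruning_loglik(two, st, md)
  direct_na <- log(sum(0.25 * P1[, 2] * rowSums(P2)))
  expect_equal(val, direct_na, tolerance = 1e-12)
  expect_error(pruning_loglik(two, c(A = 5L, B = 1L), md), "0..3")
})

test_that("masked rates are structurally zero in the likelihood", {
  set.seed(11)
  tr <- random_tree(8)
  st <- stats::setNames(sample(0:3, 8, replace = TRUE), tr$tip.label)
  r1 <- c(q01 = 1.2, q10 = 0.7, q12 = 0.9, q21 = 0.5, q23 = 1.1, q32 = 0.4,
          q20 = 0.3, q30 = 0.2, q31 = 0.6)
  md1 <- build_rate_model("strong_differentiation", rates = r1)
  # supplying values for masked pairs must not change anything
  md2 <- build_rate_model("strong_differentiation",
                          rates = c(r1, q02 = 5, q03 = 9, q13 = 2))
  expect_identical(md1$Q, md2$Q)
  expect_equal(pruning_loglik(tr, st, md1), pruning_loglik(tr, st, md2))
})

test_that("MCMC fit is reproducible and respects prior dominance", {
  tr <- simulate_tree(40, seed = 21)
  md <- default_ctmc_truth()
  st <- simulate_multistate(tr, md, seed = 22)
  cfg <- list(n_iter = 4000, chains = 2, thin = 4)
  fit <- fit_multistate_mcmc(tr, st, "strong_differentiation", config = cfg,
                             seed = 3)
  fit2 <- fit_multistate_mcmc(tr, st, "strong_differentiation", config = cfg,
                              seed = 3)
  expect_identical(fit$summary, fit2$summary)
  expect_true(all(fit$summary$median > 0))
  expect_error(fit_multistate_mcmc(tr, stats::setNames(rep(1L, 40), tr$tip.label),
                                   "full"), "distinct")

  # near-constant data: posteriors of exit rates sit low (no transitions
  # observed), far below the prior upper range
  st_const <- stats::setNames(c(rep(1L, 38), 0L, 2L), tr$tip.label)
  fit_c <- fit_multistate_mcmc(tr, st_const, "full",
                               config = list(n_iter = 4000, chains = 2,
                                             thin = 4), seed = 4)
  expect_lt(stats::median(fit_c$summary$median), 1)
})

test_that("model comparison doubles log-ML differences and labels them", {
  cmp <- compare_models(c(m1 = -100, m2 = -100, m3 = -104, m4 = -95))
  expect_equal(cmp$bf2ln["m1", "m2"], 0)
  expect_equal(cmp$bf2ln["m1", "m3"], 8)
  expect_equal(cmp$bf2ln, -t(cmp$bf2ln))
  expect_equal(unname(cmp$labels["m1", "m2"]),
               "not worth more than a bare mention")
  expect_equal(unname(cmp$labels["m1", "m3"]), "strong evidence")
  expect_equal(unname(cmp$labels["m1", "m4"]), "very strong evidence")
  expect_error(compare_models(c(a = 1)), "2 models")
})

test_that("maximum-likelihood rates are optimal and deterministic", {
  tr <- simulate_tree(60, seed = 31)
  md <- default_ctmc_truth()
  st <- simulate_multistate(tr, md, seed = 32)
  ml <- max_likelihood_fit(tr, st, "strong_differentiation", attempts = 20,
                           seed = 5)
  ml2 <- max_likelihood_fit(tr, st, "strong_differentiation", attempts = 20,
                            seed = 5)
  expect_identical(ml$rates, ml2$rates)
  # optimum at least as good as the truth
  expect_gte(ml$logL, pruning_loglik(tr, st, md) - 1e-6)
  # two identical tips: exit-rate MLE at the lower bound
  two <- ape::read.tree(text = "(A:1,B:1);")
  ml0 <- max_likelihood_fit(two, c(A = 1L, B = 1L), "full", attempts = 10,
                            seed = 6)
  expect_lt(max(ml0$rates[c("q10", "q12", "q13")]), 1e-6)
  expect_error(max_likelihood_fit(two, c(A = 1L, B = 1L), "full",
                                  attempts = 0), "attempts")
})
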