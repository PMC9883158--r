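test_that("birth-death trees are ultrametric, sized and reproducible", {
  tr <- simulate_tree(10, seed = 3)
  expect_length(tr$tip.label, 10)
  depths <- ape::node.depth.edgelength(tr)[1:10]
  expect_lt(max(abs(depths - 1)), 1e-9)
  expect_identical(write_trees(simulate_tree(10, seed = 3)),
                   write_trees(tr))
  # different seed differs
  expect_false(identical(write_trees(simulate_tree(10, seed = 4)),
                         write_trees(tr)))
  expect_error(simulate_tree(3), "n_tips")
  expect_error(simulate_tree(10, birth_rate = 0.5, death_rate = 0.6),
               "birth_rate")
  # death > 0 still conditions on n surviving tips
  trd <- simulate_tree(12, birth_rate = 1, death_rate = 0.4, seed = 9)
  expect_length(trd$tip.label, 12)
})

test_that("coordinates land in the box and wrap the antimeridian", {
  co <- simulate_coords(97, c(-45, 25, 95, 230), seed = 2)
  expect_true(all(co[, "lat"] >= -45 & co[, "lat"] <= 25))
  expect_true(all(co[, "lon"] >= -180 & co[, "lon"] <= 180))
  expect_identical(simulate_coords(97, c(-45, 25, 95, 230), seed = 2), co)
  co0 <- simulate_coords(5, c(10, 10, 20, 20), seed = 1)
  expect_true(all(co0[, "lat"] == 10) && all(co0[, "lon"] == 20))
  expect_error(simulate_coords(5, c(10, 5, 0, 1)), "degenerate")
})

test_that("ordinalize thresholds and probit-noise probabilities are correct", {
  expect_equal(ordinalize(-5, c(-1, 0, 1), "none"), 0L)
  expect_equal(ordinalize(c(-2, -0.5, 0.5, 2), c(-1, 0, 1), "none"),
               c(0L, 1L, 2L, 3L))
  # monotone in the latent
  x <- sort(stats::rnorm(100, 0, 2))
  k <- ordinalize(x, c(-1, 0, 1), "none")
  expect_true(all(diff(k) >= 0))
  expect_error(ordinalize(0, c(1, 0, -1)), "increasing")
  # probit category probability against the normal CDF
  set.seed(6)
  k <- ordinalize(rep(0, 1e5), c(-1, 0, 1), "probit")
  p1 <- mean(k == 1)
  expect_equal(p1, stats::pnorm(0) - stats::pnorm(-1), tolerance = 0.006)
  expect_true(all(k %in% 0:3))
})

test_that("coevolution simulator matches OU theory", {
  # independence: no cross-selection, no GP, deep star tree
  star <- ape::stree(400, "star"); star$edge.length <- rep(50, 400)
  p_ind <- ou_params(diag(c(-1, -1)), cutpoints = list(c(-1, 0, 1), c(-1, 0, 1)))
  sim <- simulate_coevolution(star, p_ind, seed = 8)
  r <- stats::cor(sim$latents[, 1], sim$latents[, 2])
  expect_lt(abs(r), 3 / sqrt(400))
  expect_true(all(sim$ordinal %in% 0:3))

  # long branches: tip covariance approaches the stationary solution
  p2 <- ou_params(matrix(c(-1, 0.4, 0.5, -1), 2, 2),
                  cutpoints = list(c(-1, 0, 1), c(-1, 0, 1)))
  sim2 <- simulate_coevolution(star, p2, seed = 9)
  Vhat <- stats::cov(sim2$latents)
  Vinf <- stationary_moments(p2)$V_inf
  expect_lt(max(abs(Vhat - Vinf)), 4 * max(Vinf) / sqrt(400) * 3)

  # degenerate cutpoints below all latents give a constant column
  p3 <- ou_params(diag(c(-1, -1)),
                  cutpoints = list(c(-60, -55, -50), c(-60, -55, -50)))
  sim3 <- simulate_coevolution(ape::rcoal(20), p3, seed = 10)
  expect_true(all(sim3$ordinal == 3L))

  # reproducibility
  expect_identical(simulate_coevolution(star, p2, seed = 9)$latents,
                   sim2$latents)
})

test_that("multistate simulator respects the mask and exp(Qt)", {
  md <- build_rate_model("strong_differentiation",
                         rates = c(q01 = 3, q12 = 3, q23 = 3, q10 = 1,
                                   q21 = 1, q32 = 1, q20 = 1, q30 = 1,
                                   q31 = 1))
  # zero rate matrix keeps the root state
  q0 <- matrix(0, 4, 4)
  tr <- simulate_tree(10, seed = 1)
  s0 <- simulate_multistate(tr, q0, root_freq = c(0, 0, 1, 0), seed = 2)
  expect_true(all(s0 == 2L))

  # forbidden transitions never realized: many single-branch replicates
  two <- ape::read.tree(text = "(A:0.5,B:0.5);")
  from0 <- replicate(400, {
    s <- simulate_multistate(two, md, root_freq = c(1, 0, 0, 0),
                             seed = sample.int(1e6, 1))
    s
  })
  # single-jump resolution is not observable from tips alone, so check via
  # dense Gillespie: states reachable from 0 in one branch can be anything,
  # but direct 0->2 / 0->3 jumps are impossible; verify with jump counting
  # on a chain with only the forbidden moves disabled
  expect_true(all(from0 %in% 0:3))
  set.seed(77)
  violations <- 0L
  for (i in 1:500) {
    s <- 0L; t_left <- 0.08
    repeat {
      rate <- -md$Q[s + 1, s + 1]
      if (rate <= 0) break
      dt <- stats::rexp(1, rate)
      if (dt > t_left) break
      t_left <- t_left - dt
      pr <- md$Q[s + 1, ]; pr[s + 1] <- 0
      s_new <- sample.int(4, 1, prob = pr) - 1L
      if ((s == 0L && s_new %in% c(2L, 3L)) || (s == 1L && s_new == 3L)) {
        violations <- violations + 1L
      }
      s <- s_new
    }
  }
  expect_identical(violations, 0L)

  # single branch: empirical state frequencies match exp(Qt) row
  t_br <- 0.4
  two2 <- ape::read.tree(text = "(A:0.0000001,B:0.4);")
  set.seed(12)
  nrep <- 4000
  reps <- vapply(1:nrep, function(i) {
    simulate_multistate(two2, md, root_freq = c(1, 0, 0, 0),
                        seed = sample.int(1e7, 1))[["B"]]
  }, 1L)
  emp <- tabulate(reps + 1L, 4) / nrep
  theo <- transition_probabilities(md, t_br)[1, ]
  se <- sqrt(theo * (1 - theo) / nrep)
  expect_true(all(abs(emp - theo) <= 3 * se + 1e-9))
})

test_that("signal-data generator hits its nominal lambda construction", {
  tree <- simulate_tree(40, seed = 4)
  sim <- simulate_signal_data(tree, sigma2 = c(1.5, 1.5), seed = 4)
  expect_equal(sim$lambda_true, c(0.6, 0.6))
  expect_true(all(sim$ordinal %in% 0:3))
  expect_identical(simulate_signal_data(tree, seed = 4)$ordinal, sim$ordinal)
})

test_that("synthetic dataset bundles traits, tree and manifest", {
  ds <- synthetic_dataset(n_tips = 30, seed = 5)
  expect_s3_class(ds, "synthetic_dataset")
  expect_equal(nrow(ds$society_table), 30)
  expect_setequal(ds$society_table$taxon, ds$tree$tip.label)
  expect_true(all(ds$society_table$political_authority %in% 0:3))
  expect_true(all(ds$society_table$authority_structure %in% 0:3))
  d <- tempfile()
  paths <- write_synthetic_dataset(ds, d)
  expect_true(all(file.exists(paths)))
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(man$seed, 5)
  tab <- utils::read.csv(file.path(d, "society_table.csv"))
  expect_equal(nrow(tab), 30)
  # reproducibility end to end
  ds2 <- synthetic_dataset(n_tips = 30, seed = 5)
  expect_identical(ds2$society_table, ds$society_table)
})
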