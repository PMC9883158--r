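test_that("lambda is the liability-scale variance partition", {
  expect_equal(lambda_from_variance(0), 0)
  expect_equal(lambda_from_variance(1), 0.5)
  expect_equal(lambda_from_variance(4), 0.8)
  expect_error(lambda_from_variance(-1), "nonnegative")
})

test_that("bivariate rectangle probabilities match Monte Carlo", {
  set.seed(1)
  for (rho in c(-0.7, 0, 0.45)) {
    z1 <- stats::rnorm(4e5)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(4e5)
    mc <- mean(z1 > -0.5 & z1 <= 1 & z2 > 0 & z2 <= 2)
    q <- coevauth:::binorm_rect(-0.5, 1, 0, 2, rho)
    expect_lt(abs(q - mc), 4 * sqrt(mc * (1 - mc) / 4e5) + 1e-4)
  }
  # degenerate and infinite bounds
  expect_equal(coevauth:::binorm_rect(-Inf, Inf, -Inf, Inf, 0.3), 1,
               tolerance = 1e-8)
})

test_that("signal log-likelihood collapses to independent probits and
           matches numerical integration", {
  set.seed(2)
  tr <- parse_trees("((A:1,B:1):1,C:2);")[[1]]
  tab <- data.frame(taxon = c("A", "B", "C"),
                    political_authority = c(0L, 2L, 3L),
                    religious_authority = c(1L, 1L, 2L))
  cps <- list(c(-1, 0, 1), c(-0.8, 0.1, 1.2))
  # collapse: no phylo variance, no residual correlation
  p0 <- signal_model_params(c(0, 0), 0, 0, cps)
  a0 <- matrix(0, 3, 2)
  ll <- signal_loglik(tab, tr, p0, a0)
  direct <- 0
  for (i in 1:3) for (d in 1:2) {
    y <- tab[i, 1 + d]
    bnd <- c(-Inf, cps[[d]], Inf)
    direct <- direct + log(stats::pnorm(bnd[y + 2]) - stats::pnorm(bnd[y + 1]))
  }
  expect_equal(ll, direct, tolerance = 1e-9)

  # permuting tip order leaves the value unchanged
  p1 <- signal_model_params(c(0.8, 1.3), 0.6, 0.25, cps)
  a1 <- matrix(stats::rnorm(6, 0, 0.5), 3, 2,
               dimnames = list(c("A", "B", "C"), NULL))
  perm <- c(3, 1, 2)
  expect_equal(signal_loglik(tab, tr, p1, a1),
               signal_loglik(tab[perm, ], tr, p1, a1), tolerance = 1e-9)

  # Monte-Carlo oracle for the full density on the 3-tip tree:
  # p(y, a) estimated by integrating the ordinal part over residuals
  set.seed(3)
  M <- 2e5
  R <- matrix(c(1, 0.25, 0.25, 1), 2, 2)
  e <- matrix(stats::rnorm(2 * M), M, 2) %*% chol(R)
  ll_obs_mc <- 0
  for (i in 1:3) {
    z1 <- a1[i, 1] + e[, 1]; z2 <- a1[i, 2] + e[, 2]
    y1 <- tab$political_authority[i]; y2 <- tab$religious_authority[i]
    b1 <- c(-Inf, cps[[1]], Inf); b2 <- c(-Inf, cps[[2]], Inf)
    pr <- mean(z1 > b1[y1 + 1] & z1 <= b1[y1 + 2] &
                 z2 > b2[y2 + 1] & z2 <= b2[y2 + 2])
    ll_obs_mc <- ll_obs_mc + log(pr)
  }
  C <- coevauth:::phylo_corr(tr)[tab$taxon, tab$taxon]
  B <- matrix(c(0.8, sqrt(0.8 * 1.3) * 0.6, sqrt(0.8 * 1.3) * 0.6, 1.3), 2, 2)
  ll_phy <- coevauth:::dmvnorm_log(c(a1[, 1], a1[, 2]), rep(0, 6),
                                   kronecker(B, C) + diag(1e-10, 6))
  expect_equal(signal_loglik(tab, tr, p1, a1), ll_obs_mc + ll_phy,
               tolerance = 1e-2)
})

test_that("lambda is invariant to common branch-length rescaling", {
  tree <- simulate_tree(40, seed = 7)
  sim <- simulate_signal_data(tree, seed = 7)
  tab <- make_society_table(tree, sim$ordinal)
  # the tree covariance is normalized to its maximum diagonal before use, so
  # the likelihood itself is scale-free
  p <- signal_model_params(c(0.9, 1.4), 0.5, 0.2,
                           list(c(-1, 0, 1), c(-1, 0, 1)))
  a <- matrix(stats::rnorm(80, 0, 0.5), 40, 2,
              dimnames = list(tree$tip.label, NULL))
  tree_s <- tree; tree_s$edge.length <- tree_s$edge.length * 37.5
  expect_equal(signal_loglik(tab, tree, p, a),
               signal_loglik(tab, tree_s, p, a), tolerance = 1e-8)
  # power-of-two rescaling is floating-point exact, so the whole seeded
  # posterior is bit-identical
  cfg <- list(n_trees = 1, n_iter = 800, burn = 300)
  fit1 <- fit_signal_model(tab, tree, config = cfg, seed = 8)
  tree2 <- tree; tree2$edge.length <- tree2$edge.length * 32
  fit2 <- fit_signal_model(tab, tree2, config = cfg, seed = 8)
  expect_equal(fit1$summary$median, fit2$summary$median, tolerance = 1e-12)
})

test_that("the sampler reproduces the exact posterior on iid data", {
  # On a star tree the marginal posterior of the phylogenetic SD can be
  # computed by importance sampling over cutpoints (likelihood depends only
  # on the per-tip cell probabilities). Uses a univariate reduction: the
  # political trait with rho ridge profiled out is well approximated by
  # running the sampler with near-independent traits.
  star <- ape::stree(90, "star"); star$edge.length <- rep(1, 90)
  sim <- simulate_signal_data(star, sigma2 = c(0, 0), rho_phylo = 0,
                              rho_resid = 0, seed = 17)
  tab <- make_society_table(star, sim$ordinal)
  fit <- fit_signal_model(tab, star, config = list(n_trees = 1,
                                                   n_iter = 4000,
                                                   burn = 1500),
                          seed = 18)
  # oracle: grid over sigma, importance sampling over ordered N(0,2)
  # cutpoints, for trait 1 alone (traits are independent here)
  nk <- tabulate(sim$ordinal[, 1] + 1, 4)
  loglik_sc <- function(sig, cps) {
    s <- sqrt(sig^2 + 1)
    p <- diff(c(0, stats::pnorm(cps / s), 1))
    sum(nk * log(pmax(p, 1e-300)))
  }
  sig_grid <- seq(0.01, 4, length.out = 60)
  set.seed(19)
  cps_draws <- t(apply(matrix(stats::rnorm(3 * 5000, 0, 2), 5000, 3), 1, sort))
  llmat <- vapply(sig_grid, function(sig) {
    apply(cps_draws, 1, function(cc) loglik_sc(sig, cc))
  }, numeric(nrow(cps_draws)))
  mx <- max(llmat)
  post <- colMeans(exp(llmat - mx)) * stats::dnorm(sig_grid)
  post <- post / sum(post)
  med_sig <- sig_grid[which(cumsum(post) >= 0.5)[1]]
  oracle_lambda <- med_sig^2 / (med_sig^2 + 1)
  sampled_lambda <- stats::median(fit$draws$lambda_pol)
  expect_lt(abs(sampled_lambda - oracle_lambda), 0.12)
})

test_that("the signal model recovers simulated signal and correlation", {
  tree <- simulate_tree(120, seed = 11)
  sim <- simulate_signal_data(tree, sigma2 = c(1.5, 1.5), rho_phylo = 0.8,
                              rho_resid = 0.2, seed = 42)
  tab <- make_society_table(tree, sim$ordinal)
  fit <- fit_signal_model(tab, tree, config = list(n_trees = 1,
                                                   n_iter = 2500,
                                                   burn = 800), seed = 5)
  s <- fit$summary
  lam <- s[s$parameter == "lambda_pol", ]
  expect_true(lam$hpdi_low <= 0.6 && 0.6 <= lam$hpdi_high)
  rp <- s[s$parameter == "rho_phylo", ]
  expect_gt(rp$median, 0)
  expect_s3_class(fit, "coevauth_signal_fit")
  expect_output(print(fit), "signal")
  expect_named(coef(fit))
})

test_that("posterior pooling across trees brackets single-tree centres", {
  tree <- simulate_tree(50, seed = 23)
  trees <- c(tree, tree, tree)
  class(trees) <- "multiPhylo"
  sim <- simulate_signal_data(tree, seed = 23)
  tab <- make_society_table(tree, sim$ordinal)
  pooled <- fit_signal_model(tab, trees, config = list(n_trees = 3,
                                                       n_iter = 900,
                                                       burn = 300), seed = 2)
  single <- fit_signal_model(tab, tree, config = list(n_trees = 1,
                                                      n_iter = 900,
                                                      burn = 300), seed = 2)
  centre <- single$summary$median
  inside <- mean(centre >= pooled$summary$hpdi_low &
                   centre <= pooled$summary$hpdi_high)
  expect_gte(inside, 0.9)
})
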