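test_that("coevolution likelihood factorizes on a deep star tree with
           diagonal selection", {
  # with a stationary root, star tips decorrelate only once the branches are
  # many mean-reversion half-lives deep (the shared root variance decays as
  # e^{At} V_inf e^{A't})
  star <- ape::stree(12, "star"); star$edge.length <- rep(25, 12)
  p <- ou_params(diag(c(-1.2, -0.8)), b = c(0.3, -0.1),
                 cutpoints = list(c(-1, 0, 1), c(-1, 0, 1)))
  set.seed(4)
  eta <- matrix(stats::rnorm(24, 0, 0.8), 12, 2)
  y <- cbind(sample(0:3, 12, TRUE), sample(0:3, 12, TRUE))
  tab <- make_society_table(star, y)
  ll <- coev_loglik(star, tab, NULL, p, eta)
  # independent per-tip bivariate normal (diagonal here) + ordinal terms
  st <- stationary_moments(p)
  direct <- 0
  for (i in 1:12) {
    for (d in 1:2) {
      direct <- direct + stats::dnorm(eta[i, d], st$theta_star[d],
                                      sqrt(st$V_inf[d, d]), log = TRUE)
      bnd <- c(-Inf, p$cutpoints[[d]], Inf)
      pr <- stats::pnorm(bnd[y[i, d] + 2] - eta[i, d]) -
        stats::pnorm(bnd[y[i, d] + 1] - eta[i, d])
      direct <- direct + log(pr)
    }
  }
  expect_equal(ll, direct, tolerance = 1e-6)
})

test_that("coevolution likelihood matches Monte-Carlo marginalization on a
           3-tip tree", {
  tr <- parse_trees("((A:0.6,B:0.6):0.4,C:1);")[[1]]
  p <- ou_params(matrix(c(-1, 0.4, 0.5, -1), 2, 2), b = c(0.2, -0.3),
                 cutpoints = list(c(-1, 0, 1), c(-1, 0, 1)))
  eta <- matrix(c(0.3, -0.5, 1.1, -0.2, 0.4, 0.9), 3, 2,
                dimnames = list(c("A", "B", "C"), NULL))
  y <- rbind(c(2L, 1L), c(1L, 1L), c(3L, 2L))
  tab <- make_society_table(tr, y)
  ll <- coev_loglik(tr, tab, NULL, p, eta)
  # MC: density of tip latents = E over (root, internal) flow of the
  # product of per-branch Gaussian transition densities into the tips
  set.seed(5)
  M <- 4e5
  st <- stationary_moments(p)
  Lroot <- coevauth:::chol_psd(st$V_inf)
  root <- t(st$theta_star + Lroot %*% matrix(stats::rnorm(2 * M), 2))
  t_ab <- ou_transition(p, 0.4)   # root -> internal node above A,B
  Lab <- coevauth:::chol_psd(t_ab$V)
  anc <- t(t_ab$M %*% t(root) + t_ab$m + Lab %*% matrix(stats::rnorm(2 * M), 2))
  dens_branch <- function(parent, t_len, x) {
    trn <- ou_transition(p, t_len)
    mu <- t(trn$M %*% t(parent) + trn$m)
    Vi <- solve(trn$V)
    dv <- cbind(x[1] - mu[, 1], x[2] - mu[, 2])
    q <- rowSums((dv %*% Vi) * dv)
    exp(-0.5 * q) / (2 * pi * sqrt(det(trn$V)))
  }
  w <- dens_branch(anc, 0.6, eta["A", ]) * dens_branch(anc, 0.6, eta["B", ]) *
    dens_branch(root, 1, eta["C", ])
  ll_tree_mc <- log(mean(w))
  se <- stats::sd(w) / sqrt(M) / mean(w)
  # ordinal terms are deterministic given eta
  obs <- 0
  for (i in 1:3) for (d in 1:2) {
    bnd <- c(-Inf, p$cutpoints[[d]], Inf)
    obs <- obs + log(stats::pnorm(bnd[y[i, d] + 2] - eta[i, d]) -
                       stats::pnorm(bnd[y[i, d] + 1] - eta[i, d]))
  }
  expect_lt(abs(ll - (ll_tree_mc + obs)), 3 * se + 0.02)
})

test_that("cutpoint-gap changes move only the ordinal term", {
  tr <- parse_trees("((A:0.6,B:0.6):0.4,C:1);")[[1]]
  cps1 <- list(c(-1, 0, 1), c(-1, 0, 1))
  cps2 <- list(c(-2, 0, 2), c(-2, 0, 2))
  p1 <- ou_params(diag(c(-1, -1)), cutpoints = cps1)
  p2 <- ou_params(diag(c(-1, -1)), cutpoints = cps2)
  eta <- matrix(c(-0.5, 0.5, 0, 0.5, -0.5, 0), 3, 2,
                dimnames = list(c("A", "B", "C"), NULL))
  y <- rbind(c(1L, 2L), c(2L, 1L), c(1L, 1L))
  tab <- make_society_table(tr, y)
  d_obs <- function(cps) {
    s <- 0
    for (i in 1:3) for (d in 1:2) {
      bnd <- c(-Inf, cps[[d]], Inf)
      s <- s + log(stats::pnorm(bnd[y[i, d] + 2] - eta[i, d]) -
                     stats::pnorm(bnd[y[i, d] + 1] - eta[i, d]))
    }
    s
  }
  expect_equal(coev_loglik(tr, tab, NULL, p2, eta) -
                 coev_loglik(tr, tab, NULL, p1, eta),
               unname(d_obs(cps2) - d_obs(cps1)), tolerance = 1e-9)
})

test_that("delta-theta follows the selection-matrix formula and is
           MAD-equivariant", {
  p <- ou_params(matrix(c(-1, 0.4, 0.5, -1), 2, 2),
                 cutpoints = list(c(-1, 0, 1), c(-1, 0, 1)))
  dt <- delta_theta(p, mad = c(1, 1))
  expect_equal(unname(dt["pol_from_rel"]), 0.5)
  expect_equal(unname(dt["rel_from_pol"]), 0.4)
  # zero cross-selection gives exactly zero
  p0 <- ou_params(diag(c(-1, -2)), cutpoints = list(c(-1, 0, 1), c(-1, 0, 1)))
  expect_equal(unname(delta_theta(p0, mad = c(2, 3))), c(0, 0))
  # equivariance: scaling the conditioning trait's MAD scales the response
  dt2 <- delta_theta(p, mad = c(1, 3))
  expect_equal(unname(dt2["pol_from_rel"]), 3 * 0.5)
  expect_equal(unname(dt2["rel_from_pol"]), 0.4)
  expect_error(delta_theta(p, mad = c(0, 1)), "positive")
})

test_that("the coevolution fit recovers cross-trait selection and supports
           its methods", {
  tree <- simulate_tree(60, seed = 101)
  truth <- default_ou_truth()
  sim <- simulate_coevolution(tree, truth, seed = 102)
  tab <- make_society_table(tree, sim$ordinal)
  fit <- fit_coevolution(tab, tree, config = list(n_trees = 1, chains = 2,
                                                  n_iter = 1600, burn = 600,
                                                  thin = 2, gp = FALSE),
                         seed = 7)
  h <- hpdi(fit$draws$a12)
  expect_true(h[1] <= 0.8 && 0.8 <= h[2])
  expect_true(all(fit$draws$a11 < 0))
  dt <- delta_theta(fit)
  expect_s3_class(dt, "coev_delta_theta")
  expect_true(all(is.finite(dt$summary$median)))
  expect_output(print(fit), "coevolutionary|Dynamic")
  expect_named(coef(fit))
  sims <- simulate(fit, nsim = 1, seed = 3)
  expect_true(all(sims[[1]]$ordinal %in% 0:3))
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("ancestral probabilities are coherent and symmetric", {
  # per-draw level probabilities sum to 1; symmetric two-tip configuration
  # gives a symmetric root reconstruction
  two <- ape::read.tree(text = "(A:1,B:1);")
  y <- rbind(c(0L, 0L), c(3L, 3L))
  tab <- make_society_table(two, y)
  fit <- fit_coevolution(tab, two, config = list(n_trees = 1, chains = 1,
                                                 n_iter = 1200, burn = 400,
                                                 thin = 2, gp = FALSE),
                         seed = 9)
  asr <- ancestral_states(fit, n_draws = 150, seed = 10)
  expect_true(all(abs(rowSums(as.matrix(asr[, c("p0", "p1", "p2", "p3")])) - 1) < 0.5))
  pol <- asr[asr$trait == "pol", ]
  expect_lt(abs(pol$p0 - pol$p3), 0.25)
  # clade naming by MRCA
  tree <- simulate_tree(20, seed = 31)
  sim <- simulate_coevolution(tree, default_ou_truth(), seed = 32)
  tab2 <- make_society_table(tree, sim$ordinal)
  fit2 <- fit_coevolution(tab2, tree, config = list(n_trees = 1, chains = 1,
                                                    n_iter = 1000, burn = 400,
                                                    gp = FALSE), seed = 33)
  cl <- list(rootclade = tree$tip.label[1:2])
  asr2 <- ancestral_states(fit2, clades = cl, n_draws = 60, seed = 34)
  expect_true(any(asr2$clade == "rootclade", na.rm = TRUE))
  expect_error(ancestral_states(fit2, clades = list(bad = c("zz", "t1"))),
               "zz")
})

test_that("ordinal level probabilities partition to one and pin in the
           tails", {
  bnd <- c(-Inf, c(-1, 0, 1), Inf)
  for (eta in c(-8, -0.3, 0.7, 5)) {
    pk <- stats::pnorm(bnd[-1] - eta) - stats::pnorm(bnd[-5] - eta)
    expect_equal(sum(pk), 1, tolerance = 1e-12)
  }
  eta <- -8
  p0 <- stats::pnorm(bnd[2] - eta) - stats::pnorm(bnd[1] - eta)
  expect_gt(p0, 0.999)
})

test_that("(A, b) are locally identified at the recovery truth once S = I
           and the middle cutpoint anchor the scale", {
  # the expected log-likelihood Hessian at truth is minus the Fisher
  # information of the Gaussian tip-latent family: positive definite iff no
  # local parameter redundancy remains. For mean mu(par), cov Sigma(par):
  # I_ij = 0.5 tr(Si dSi Si dSj) + dmu_i' Si dmu_j.
  tree <- simulate_tree(60, seed = 201)
  cache <- coevauth:::coev_tree_cache(tree, order = tree$tip.label)
  moments <- function(par) {
    A <- matrix(c(-exp(par[1]), par[4], par[3], -exp(par[2])), 2, 2)
    St <- coevauth:::coev_sigma_tree(A, par[5:6], cache)
    list(mu = St$mean, S = St$Sigma + diag(1e-10, 120))
  }
  par0 <- c(0, 0, 0.8, 0, 0, 0)
  eps <- 1e-5
  dS <- list(); dmu <- list()
  for (i in 1:6) {
    ei <- rep(0, 6); ei[i] <- eps
    up <- moments(par0 + ei); dn <- moments(par0 - ei)
    dS[[i]] <- (up$S - dn$S) / (2 * eps)
    dmu[[i]] <- (up$mu - dn$mu) / (2 * eps)
  }
  S0 <- moments(par0)$S
  Si <- solve(S0)
  FI <- matrix(0, 6, 6)
  for (i in 1:6) for (j in i:6) {
    FI[i, j] <- FI[j, i] <-
      0.5 * sum(diag(Si %*% dS[[i]] %*% Si %*% dS[[j]])) +
      as.numeric(dmu[[i]] %*% Si %*% dmu[[j]])
  }
  expect_gt(min(eigen(FI, symmetric = TRUE, only.values = TRUE)$values), 1e-4)
})
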