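#' Liability-scale phylogenetic signal
#'
#' The proportion of liability variance captured by phylogeny,
#' \eqn{\lambda = \sigma^2 / (\sigma^2 + 1)}, with the residual liability
#' variance fixed at 1.
#'
#' @param sigma2 Phylogenetic variance (>= 0).
#' @export
lambda_from_variance <- function(sigma2) {
  if (any(sigma2 < 0)) stop("sigma2 must be nonnegative")
  sigma2 / (sigma2 + 1)
}

#' Parameters of the bivariate ordinal signal model
#'
#' @param sigma2_phylo Length-2 per-trait phylogenetic variances (liability
#'   scale).
#' @param rho_phylo,rho_resid Phylogenetic and residual cross-trait
#'   correlations in [-1, 1].
#' @param cutpoints List of two strictly increasing triples.
#' @return Object of class \code{signal_model_params}; \code{lambda} is the
#'   derived per-trait signal.
#' @export
signal_model_params <- function(sigma2_phylo, rho_phylo, rho_resid,
                                cutpoints) {
  if (any(sigma2_phylo < 0)) stop("sigma2_phylo must be nonnegative")
  if (abs(rho_phylo) > 1 || abs(rho_resid) > 1) {
    stop("correlations must lie in [-1, 1]")
  }
  for (cp in cutpoints) {
    if (length(cp) != 3L || any(diff(cp) <= 0)) {
      stop("cutpoints must be strictly increasing triples")
    }
  }
  structure(list(sigma2_phylo = sigma2_phylo, rho_phylo = rho_phylo,
                 rho_resid = rho_resid, cutpoints = cutpoints,
                 lambda = lambda_from_variance(sigma2_phylo)),
            class = "signal_model_params")
}

# Bivariate standard-normal rectangle probability
# P(lo1 < X <= hi1, lo2 < Y <= hi2) with corr(X, Y) = rho, by Gauss-Legendre
# quadrature of the conditional normal over the first margin.
binorm_rect <- function(lo1, hi1, lo2, hi2, rho, nquad = 64) {
  if (abs(rho) < 1e-12) {
    return((stats::pnorm(hi1) - stats::pnorm(lo1)) *
             (stats::pnorm(hi2) - stats::pnorm(lo2)))
  }
  a <- max(lo1, -8.5); b <- min(hi1, 8.5)
  if (b <= a) return(0)
  gl <- gauss_legendre(nquad)
  x <- (a + b) / 2 + (b - a) / 2 * gl$nodes
  w <- (b - a) / 2 * gl$weights
  s <- sqrt(1 - rho^2)
  inner <- stats::pnorm((hi2 - rho * x) / s) - stats::pnorm((lo2 - rho * x) / s)
  sum(w * stats::dnorm(x) * inner)
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch), memoised.
gauss_legendre <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    k <- seq_len(n - 1)
    beta <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1)] <- beta
    J[cbind(k + 1, k)] <- beta
    eg <- eigen(J, symmetric = TRUE)
    out <- list(nodes = eg$values, weights = 2 * eg$vectors[1, ]^2)
    cache[[key]] <<- out
    out
  }
})

#' Log-likelihood of the bivariate ordinal signal model
#'
#' Given per-tip phylogenetic effects for both traits, returns
#' \eqn{\log p(y \mid a, cutpoints, \rho_{resid}) + \log p(a \mid tree,
#' \sigma^2, \rho_{phylo})}. The phylogenetic effects are jointly Gaussian
#' with covariance \eqn{B \otimes C} (B = 2x2 between-trait covariance, C =
#' tree correlation matrix), and residual liabilities are bivariate normal
#' with unit variances and correlation \code{rho_resid}, marginalized into
#' the ordinal probability via bivariate-probit rectangle probabilities.
#'
#' @param table Data.frame with columns \code{taxon},
#'   \code{political_authority}, \code{religious_authority}.
#' @param tree A \code{phylo} containing all taxa of \code{table}.
#' @param params A \code{\link{signal_model_params}}.
#' @param phylo_effects n x 2 matrix of per-tip effects (rownames = taxa, or
#'   in table order).
#' @return Log-likelihood (scalar).
#' @export
signal_loglik <- function(table, tree, params, phylo_effects) {
  stopifnot(inherits(params, "signal_model_params"))
  if (!all(table$taxon %in% tree$tip.label)) {
    stop("taxa of table not all present in tree")
  }
  a <- as.matrix(phylo_effects)
  if (!is.null(rownames(a))) a <- a[table$taxon, , drop = FALSE]
  n <- nrow(table)
  y <- cbind(table$political_authority, table$religious_authority)
  # ordinal part: bivariate probit rectangles around the effects
  ll_obs <- 0
  for (i in seq_len(n)) {
    b1 <- c(-Inf, params$cutpoints[[1]], Inf)
    b2 <- c(-Inf, params$cutpoints[[2]], Inf)
    p <- binorm_rect(b1[y[i, 1] + 1] - a[i, 1], b1[y[i, 1] + 2] - a[i, 1],
                     b2[y[i, 2] + 1] - a[i, 2], b2[y[i, 2] + 2] - a[i, 2],
                     params$rho_resid)
    ll_obs <- ll_obs + log(max(p, 1e-300))
  }
  # phylogenetic part: a ~ N(0, B (x) C) in trait-major order
  tr <- prune_to_taxa(tree, table$taxon)
  C <- phylo_corr(tr)[table$taxon, table$taxon]
  s1 <- sqrt(params$sigma2_phylo[1]); s2 <- sqrt(params$sigma2_phylo[2])
  B <- matrix(c(s1^2, s1 * s2 * params$rho_phylo,
                s1 * s2 * params$rho_phylo, s2^2), 2, 2)
  if (all(params$sigma2_phylo == 0)) {
    ll_phy <- if (all(abs(a) < 1e-12)) 0 else -Inf
  } else {
    S <- kronecker(B, C) + diag(1e-10, 2 * n)
    ll_phy <- dmvnorm_log(c(a[, 1], a[, 2]), rep(0, 2 * n), S)
  }
  ll_obs + ll_phy
}

dmvnorm_log <- function(x, mu, Sigma) {
  ch <- chol(Sigma)
  v <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(v^2)
}

signal_config_defaults <- function(config = list(), scale = "desk") {
  base <- if (identical(scale, "paper")) {
    list(n_trees = 100, chains = 2, n_iter = 4000, burn = 1500, thin = 2)
  } else {
    list(n_trees = 10, chains = 2, n_iter = 2000, burn = 600, thin = 1)
  }
  base$jitter <- 1e-8
  base$prior_cut_sd <- 2
  utils::modifyList(base, config)
}

#' Fit the bivariate ordinal phylogenetic signal model
#'
#' Bayesian cumulative-probit mixed model for two 4-level ordinal traits
#' with correlated phylogenetic random effects: liabilities
#' \eqn{z \sim N(0, B \otimes C + R \otimes I)} (C = tree correlation, B =
#' between-trait phylogenetic covariance, R = unit-variance residual
#' correlation matrix) thresholded at per-trait cutpoints. Sampling is by
#' Gibbs data augmentation: truncated-normal sweeps for the liabilities,
#' conjugate truncated-normal updates for the cutpoints, and adaptive
#' random-walk Metropolis for the variance/correlation block. Priors:
#' half-normal(0,1) on phylogenetic SDs, LKJ(2) on both correlations,
#' normal(0, 2) on cutpoints. The model is iterated over randomly drawn
#' trees from the sample and the posteriors pooled.
#'
#' @param table Data.frame with columns \code{taxon},
#'   \code{political_authority}, \code{religious_authority} (values 0..3).
#' @param trees A \code{multiPhylo}/\code{phylo} sample.
#' @param config List overriding sampler settings (\code{n_trees},
#'   \code{chains}, \code{n_iter}, \code{burn}, \code{thin}).
#' @param scale \code{"desk"} (10 trees) or \code{"paper"} (100 trees).
#' @param seed Integer seed.
#' @return Object of class \code{coevauth_signal_fit} with pooled
#'   \code{draws} (data.frame: sigma2/lambda per trait, correlations,
#'   cutpoints, tree id, chain), a \code{summary} table with medians, 95\%
#'   HPDIs, split R-hat and ESS, and a \code{converged} flag (all R-hat <=
#'   1.05).
#' @export
fit_signal_model <- function(table, trees, config = list(), scale = "desk",
                             seed = 1) {
  cfg <- signal_config_defaults(config, scale)
  if (inherits(trees, "phylo")) trees <- c(trees)
  n <- nrow(table)
  if (n < 10) stop("need at least 10 taxa")
  y <- cbind(table$political_authority, table$religious_authority)
  if (any(y < 0 | y > 3)) stop("ordinal values outside 0..3")
  if (any(apply(y, 2, function(v) length(unique(v))) < 2)) {
    stop("need >= 2 observed categories per trait")
  }
  set.seed(seed)
  n_trees <- min(cfg$n_trees, length(trees))
  tree_ids <- sample.int(length(trees), n_trees)
  all_draws <- list()
  rhat_by_tree <- list()
  par_names <- c("sigma2_pol", "sigma2_rel", "lambda_pol", "lambda_rel",
                 "rho_phylo", "rho_resid",
                 "cut_pol_1", "cut_pol_2", "cut_pol_3",
                 "cut_rel_1", "cut_rel_2", "cut_rel_3")
  for (ti in seq_along(tree_ids)) {
    tr <- prune_to_taxa(trees[[tree_ids[ti]]], table$taxon)
    C <- phylo_corr(tr)[table$taxon, table$taxon]
    egC <- eigen(C + diag(cfg$jitter, n), symmetric = TRUE)
    chains <- vector("list", cfg$chains)
    for (ch in seq_len(cfg$chains)) {
      chains[[ch]] <- signal_gibbs_chain(
        y, egC, cfg, seed = seed + 1000L * ti + ch)
    }
    # per-tree split R-hat across chains
    rh <- vapply(seq_along(par_names), function(j) {
      suppressWarnings(rhat(sapply(chains, function(d) d[, j])))
    }, 1)
    rhat_by_tree[[ti]] <- rh
    for (ch in seq_len(cfg$chains)) {
      d <- as.data.frame(chains[[ch]])
      names(d) <- par_names
      d$tree_id <- tree_ids[ti]
      d$chain <- ch
      all_draws[[length(all_draws) + 1L]] <- d
    }
  }
  draws <- do.call(rbind, all_draws)
  rh_mat <- do.call(rbind, rhat_by_tree)
  summ <- data.frame(parameter = par_names, median = NA_real_,
                     hpdi_low = NA_real_, hpdi_high = NA_real_,
                     rhat = apply(rh_mat, 2, max), ess = NA_real_,
                     stringsAsFactors = FALSE)
  for (j in seq_along(par_names)) {
    x <- draws[[par_names[j]]]
    h <- hpdi(x)
    summ$median[j] <- stats::median(x)
    summ$hpdi_low[j] <- h[1]; summ$hpdi_high[j] <- h[2]
    summ$ess[j] <- suppressWarnings(ess(matrix(x, ncol = 1)))
  }
  converged <- all(is.finite(summ$rhat)) && all(summ$rhat <= 1.05)
  structure(list(draws = draws, summary = summ, converged = converged,
                 tree_ids = tree_ids, config = cfg, seed = seed,
                 n = n),
            class = "coevauth_signal_fit")
}

# One Gibbs chain for the signal model. y: n x 2 ordinal; egC: eigen of the
# (jittered) tree correlation matrix. Returns a matrix of kept draws.
#
# The sampler works in the eigenbasis of C, where both the marginal
# liability likelihood and the phylogenetic-effect full conditional factor
# into n independent 2x2 problems, giving O(n) parameter updates:
#   1. collapsed adaptive-RWM update of (log sd1, log sd2, atanh rho_p,
#      atanh rho_r) against the liability marginal p(z | phi);
#   2. exact Gaussian redraw of the phylogenetic effects a | z, phi
#      (which together with 1. samples (phi, a) | z jointly);
#   3. truncated-normal redraw of liabilities z | a, y (sites independent);
#   4. conjugate truncated-normal cutpoint updates;
#   5. per-trait scale and translation "ridge" moves that shift liabilities,
#      effects, cutpoints and the phylo SD together, targeting the stiff
#      cutpoint-scale direction of the posterior.
signal_gibbs_chain <- function(y, egC, cfg, seed) {
  set.seed(seed)
  n <- nrow(y)
  U <- egC$vectors
  lamC <- pmax(egC$values, 1e-12)
  Ut1 <- as.numeric(crossprod(U, rep(1, n)))
  # state
  cp <- list(c(-1, 0, 1), c(-1, 0, 1))
  phi <- c(ls1 = log(0.5), ls2 = log(0.5), ar_p = 0, ar_r = 0)
  z <- cbind(c(-1.5, -0.5, 0.5, 1.5)[y[, 1] + 1],
             c(-1.5, -0.5, 0.5, 1.5)[y[, 2] + 1]) +
    matrix(stats::rnorm(2 * n, 0, 0.1), n, 2)
  zt <- crossprod(U, z)
  at <- matrix(0, n, 2)                       # phylo effects, eigenbasis
  a <- U %*% at
  B_of <- function(phi) {
    phi <- as.numeric(phi)
    s1 <- exp(phi[1]); s2 <- exp(phi[2]); rp <- tanh(phi[3])
    c(b11 = s1^2, b22 = s2^2, b12 = s1 * s2 * rp)
  }
  # marginal liability likelihood + priors (half-normal SDs, LKJ(2) corrs,
  # with change-of-variable Jacobians)
  loglik_phi <- function(phi, zt) {
    if (any(!is.finite(phi)) || any(abs(phi) > 20)) return(-Inf)
    B <- B_of(phi); rr <- tanh(phi[4])
    a11 <- lamC * B["b11"] + 1
    a22 <- lamC * B["b22"] + 1
    a12 <- lamC * B["b12"] + rr
    det_k <- a11 * a22 - a12^2
    if (any(!is.finite(det_k)) || any(det_k <= 0)) return(-Inf)
    q_k <- (a22 * zt[, 1]^2 - 2 * a12 * zt[, 1] * zt[, 2] +
              a11 * zt[, 2]^2) / det_k
    -0.5 * sum(log(det_k)) - 0.5 * sum(q_k) - n * log(2 * pi) -
      0.5 * exp(2 * phi[1]) + phi[1] - 0.5 * exp(2 * phi[2]) + phi[2] +
      2 * log1p(-tanh(phi[3])^2) + 2 * log1p(-tanh(phi[4])^2)
  }
  # log p(at | phi): independent N(0, lam_k B) terms in the eigenbasis
  logp_at <- function(phi, at) {
    if (any(!is.finite(phi)) || any(abs(phi) > 20)) return(-Inf)
    B <- B_of(phi)
    det_k <- lamC^2 * (B["b11"] * B["b22"] - B["b12"]^2)
    if (any(!is.finite(det_k)) || any(det_k <= 0)) return(-Inf)
    q_k <- (lamC * B["b22"] * at[, 1]^2 - 2 * lamC * B["b12"] * at[, 1] * at[, 2] +
              lamC * B["b11"] * at[, 2]^2) / det_k
    -0.5 * sum(log(det_k)) - 0.5 * sum(q_k) - n * log(2 * pi)
  }
  # log p(z - a | rho_r): iid bivariate normal residuals
  logp_resid <- function(phi, z, a) {
    rr <- tanh(phi[4])
    e <- z - a
    det_r <- 1 - rr^2
    -0.5 * n * log(det_r) - n * log(2 * pi) -
      0.5 * sum(e[, 1]^2 - 2 * rr * e[, 1] * e[, 2] + e[, 2]^2) / det_r
  }
  logp_cp <- function(cp) {
    sum(stats::dnorm(unlist(cp), 0, cfg$prior_cut_sd, log = TRUE))
  }
  lp <- loglik_phi(phi, zt)
  Lp <- chol(diag(0.05, 4))
  mean_run <- phi; cov_run <- diag(0.05, 4); n_run <- 1
  nkeep <- floor((cfg$n_iter - cfg$burn) / cfg$thin)
  keep <- matrix(NA_real_, nkeep, 12)
  ki <- 0L
  for (it in seq_len(cfg$n_iter)) {
    # 1. collapsed variance/correlation update (phylo effects integrated out)
    for (rep_i in 1:2) {
      prop <- phi + as.numeric(crossprod(Lp, stats::rnorm(4)))
      lpp <- loglik_phi(prop, zt)
      if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
        phi <- prop; lp <- lpp
      }
    }
    # 2. phylo effects a | z, phi: per-eigencomponent 2x2 Gaussian
    B <- B_of(phi); rr <- tanh(phi[4])
    Bk11 <- lamC * B["b11"]; Bk22 <- lamC * B["b22"]; Bk12 <- lamC * B["b12"]
    m11 <- Bk11 + 1; m22 <- Bk22 + 1; m12 <- Bk12 + rr
    det_m <- m11 * m22 - m12^2
    W11 <- (Bk11 * m22 - Bk12 * m12) / det_m
    W12 <- (Bk12 * m11 - Bk11 * m12) / det_m
    W21 <- (Bk12 * m22 - Bk22 * m12) / det_m
    W22 <- (Bk22 * m11 - Bk12 * m12) / det_m
    mu1 <- W11 * zt[, 1] + W12 * zt[, 2]
    mu2 <- W21 * zt[, 1] + W22 * zt[, 2]
    V11 <- pmax(Bk11 - (W11 * Bk11 + W12 * Bk12), 0)
    V12 <- Bk12 - (W11 * Bk12 + W12 * Bk22)
    V22 <- pmax(Bk22 - (W21 * Bk12 + W22 * Bk22), 0)
    sd1 <- sqrt(V11)
    c21 <- ifelse(V11 > 0, V12 / pmax(sd1, 1e-300), 0)
    sd2 <- sqrt(pmax(V22 - c21^2, 0))
    g1 <- stats::rnorm(n); g2 <- stats::rnorm(n)
    at[, 1] <- mu1 + sd1 * g1
    at[, 2] <- mu2 + c21 * g1 + sd2 * g2
    a <- U %*% at
    # 3. liabilities z | a, y: truncated normals, sites independent
    s_r <- sqrt(1 - rr^2)
    for (d in 1:2) {
      other <- 3 - d
      lo <- c(-Inf, cp[[d]])[y[, d] + 1]
      hi <- c(cp[[d]], Inf)[y[, d] + 1]
      cmean <- a[, d] + rr * (z[, other] - a[, other])
      z[, d] <- rtruncnorm_vec(cmean, s_r, lo, hi)
    }
    zt <- crossprod(U, z)
    # 4. cutpoints
    cp[[1]] <- draw_cutpoints(z[, 1], y[, 1], cp[[1]], cfg$prior_cut_sd)
    cp[[2]] <- draw_cutpoints(z[, 2], y[, 2], cp[[2]], cfg$prior_cut_sd)
    # 5. per-trait ridge moves (scale, then translation)
    for (d in 1:2) {
      tstep <- stats::rnorm(1, 0, 0.06)
      cfac <- exp(tstep)
      phi2 <- phi; phi2[d] <- phi[d] + tstep
      z2 <- z; z2[, d] <- cfac * z[, d]
      at2 <- at; at2[, d] <- cfac * at[, d]
      cp2 <- cp; cp2[[d]] <- cfac * cp[[d]]
      a2 <- a; a2[, d] <- cfac * a[, d]
      num <- logp_at(phi2, at2) + logp_resid(phi2, z2, a2) + logp_cp(cp2) -
        0.5 * exp(2 * phi2[d]) + phi2[d]
      den <- logp_at(phi, at) + logp_resid(phi, z, a) + logp_cp(cp) -
        0.5 * exp(2 * phi[d]) + phi[d]
      if (is.finite(num) &&
          log(stats::runif(1)) < num - den + (2 * n + 3) * tstep) {
        phi <- phi2; z <- z2; at <- at2; cp <- cp2; a <- a2
        zt <- crossprod(U, z)
        lp <- loglik_phi(phi, zt)
      }
      dstep <- stats::rnorm(1, 0, 0.12)
      z2 <- z; z2[, d] <- z[, d] + dstep
      at2 <- at; at2[, d] <- at[, d] + dstep * Ut1
      a2 <- a; a2[, d] <- a[, d] + dstep
      cp2 <- cp; cp2[[d]] <- cp[[d]] + dstep
      num <- logp_at(phi, at2) + logp_resid(phi, z2, a2) + logp_cp(cp2)
      den <- logp_at(phi, at) + logp_resid(phi, z, a) + logp_cp(cp)
      if (is.finite(num) && log(stats::runif(1)) < num - den) {
        z <- z2; at <- at2; a <- a2; cp <- cp2
        zt <- crossprod(U, z)
        lp <- loglik_phi(phi, zt)
      }
    }
    if (it <= cfg$burn) {
      n_run <- n_run + 1
      delta <- phi - mean_run
      mean_run <- mean_run + delta / n_run
      cov_run <- cov_run * (n_run - 2) / (n_run - 1) + tcrossprod(delta) / n_run
      if (it %% 50 == 0 && it >= 100) {
        ch <- tryCatch(chol(2.88 * cov_run / 4 + diag(1e-6, 4)),
                       error = function(e) NULL)
        if (!is.null(ch)) Lp <- ch
      }
    } else if ((it - cfg$burn) %% cfg$thin == 0 && ki < nkeep) {
      ki <- ki + 1L
      s1sq <- exp(2 * phi[1]); s2sq <- exp(2 * phi[2])
      keep[ki, ] <- c(s1sq, s2sq, s1sq / (s1sq + 1), s2sq / (s2sq + 1),
                      tanh(phi[3]), tanh(phi[4]), cp[[1]], cp[[2]])
    }
  }
  keep[seq_len(ki), , drop = FALSE]
}

# Vectorized truncated-normal draws by inverse CDF, with tail safeguards.
rtruncnorm_vec <- function(mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi_ <- stats::pnorm(hi, mean, sd)
  w <- phi_ - plo
  u <- plo + stats::runif(length(mean)) * w
  out <- stats::qnorm(pmin(pmax(u, 1e-15), 1 - 1e-15), mean, sd)
  bad <- w < 1e-14
  if (any(bad)) {
    rb <- ifelse(mean[bad] < lo[bad], lo[bad],
                 ifelse(mean[bad] > hi[bad], hi[bad], mean[bad]))
    rb[!is.finite(rb)] <- mean[bad][!is.finite(rb)]
    out[bad] <- rb
  }
  pmin(pmax(out, lo), hi)
}

# Gibbs update of one trait's cutpoints: each c_j is truncated normal
# (prior N(0, sd^2)) between the largest liability in category j-1 and the
# smallest in category j (neighbouring cutpoints bound empty categories).
draw_cutpoints <- function(z, y, cp, prior_sd) {
  out <- cp
  for (j in 1:3) {
    lo <- max(c(z[y == j - 1], if (j > 1) out[j - 1] else -Inf))
    hi <- min(c(z[y == j], if (j < 3) out[j + 1] else Inf))
    if (!(lo < hi)) next                  # degenerate window: keep current
    plo <- stats::pnorm(lo / prior_sd)
    phi_ <- stats::pnorm(hi / prior_sd)
    if (phi_ - plo > 1e-14) {
      u <- stats::runif(1, plo, phi_)
      out[j] <- prior_sd * stats::qnorm(min(max(u, 1e-15), 1 - 1e-15))
    } else if (is.finite(lo) && is.finite(hi)) {
      out[j] <- (lo + hi) / 2             # prior mass underflow in (lo, hi)
    }
    out[j] <- min(max(out[j], lo), hi)
  }
  out
}

#' @export
print.coevauth_signal_fit <- function(x, ...) {
  cat("Bivariate ordinal phylogenetic signal model:", x$n, "taxa,",
      length(x$tree_ids), "trees x", x$config$chains, "chains\n")
  cat("  converged (all R-hat <= 1.05):", x$converged, "\n")
  keyrows <- x$summary$parameter %in%
    c("lambda_pol", "lambda_rel", "rho_phylo", "rho_resid")
  print(x$summary[keyrows, ], digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
summary.coevauth_signal_fit <- function(object, ...) object$summary

#' @export
coef.coevauth_signal_fit <- function(object, ...) {
  stats::setNames(object$summary$median, object$summary$parameter)
}

#' Write a posterior summary table as CSV
#' @param fit A fitted model object with a \code{summary} data.frame.
#' @param file Output path.
#' @export
write_posterior_summary <- function(fit, file) {
  utils::write.csv(fit$summary, file, row.names = FALSE)
  invisible(file)
}
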