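#' Log-likelihood of the dynamic coevolutionary model
#'
#' For given tip latents (and optionally spatial effects), returns the sum
#' of (i) the log density of the tip OU latents under the tree-structured
#' process with the root at its stationary distribution (internal nodes are
#' marginalized exactly: the joint tip covariance collects
#' \eqn{e^{At_i} V_\infty e^{A^\top t_j}} over MRCA paths, the closed form
#' of Gaussian belief propagation from tips to root), (ii) the log density
#' of the spatial Gaussian-process component, and (iii) the ordinal probit
#' observation terms \eqn{\log[\Phi(c_{k+1}-\ell) - \Phi(c_k-\ell)]} at each
#' tip and trait, where \eqn{\ell} is latent plus spatial effect.
#'
#' @param tree A rooted \code{phylo}.
#' @param table Data.frame with \code{taxon}, \code{political_authority},
#'   \code{religious_authority} (0..3).
#' @param coords (lat, lon) matrix in table order, or NULL when the GP is
#'   off.
#' @param params An \code{\link{ou_params}} with cutpoints.
#' @param tip_latents n x 2 matrix of OU tip latents (table order, or with
#'   rownames = taxa).
#' @param spatial_effects Optional n x 2 matrix of GP effects; default zero.
#' @return Log density (scalar).
#' @export
coev_loglik <- function(tree, table, coords = NULL, params, tip_latents,
                        spatial_effects = NULL) {
  stopifnot(inherits(params, "ou_params"))
  n <- nrow(table)
  eta <- as.matrix(tip_latents)
  if (!is.null(rownames(eta))) eta <- eta[table$taxon, , drop = FALSE]
  tr <- if (length(tree$tip.label) > n) prune_to_taxa(tree, table$taxon) else tree
  mom <- ou_tip_moments(tr, params)
  ord <- match(table$taxon, mom$tip_order)
  perm <- c(ord, length(mom$tip_order) + ord)
  ll_tree <- dmvnorm_log(c(eta[, 1], eta[, 2]), mom$mean[perm],
                         mom$Sigma[perm, perm] + diag(1e-10, 2 * n))
  g <- if (is.null(spatial_effects)) matrix(0, n, 2) else
    as.matrix(spatial_effects)
  ll_gp <- 0
  if (any(params$gp_amplitude > 0)) {
    if (is.null(coords)) stop("coords required when gp_amplitude > 0")
    Dkm <- great_circle_distances(coords)
    for (d in 1:2) {
      if (params$gp_amplitude[d] > 0) {
        K <- params$gp_amplitude[d]^2 *
          exp(-Dkm^2 / (2 * params$gp_lengthscale[d]^2)) + diag(1e-8, n)
        ll_gp <- ll_gp + dmvnorm_log(g[, d], rep(0, n), K)
      } else if (any(g[, d] != 0)) {
        return(-Inf)
      }
    }
  } else if (any(g != 0)) {
    stop("nonzero spatial effects with zero GP amplitude")
  }
  liab <- eta + g
  y <- cbind(table$political_authority, table$religious_authority)
  ll_obs <- 0
  for (d in 1:2) {
    cp <- c(-Inf, params$cutpoints[[d]], Inf)
    p <- stats::pnorm(cp[y[, d] + 2] - liab[, d]) -
      stats::pnorm(cp[y[, d] + 1] - liab[, d])
    ll_obs <- ll_obs + sum(log(pmax(p, 1e-300)))
  }
  ll_tree + ll_gp + ll_obs
}

# Per-tree cache for the fast tip-covariance builder. On an ultrametric
# tree the covariance block of a tip pair depends only on the time back to
# the pair's MRCA, so blocks are filled by indexing per-unique-time values.
# `order` optionally re-expresses everything in a chosen taxon order.
coev_tree_cache <- function(tree, order = NULL) {
  n <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  Tdepth <- max(depths[seq_len(n)])
  ultra <- (Tdepth - min(depths[seq_len(n)])) < 1e-6 * max(Tdepth, 1)
  if (!ultra) stop("fitting requires an ultrametric (time-scaled) tree")
  mr <- ape::mrca(tree)
  s_mat <- Tdepth - matrix(depths[mr], n, n)
  diag(s_mat) <- 0
  tips <- tree$tip.label
  if (!is.null(order)) {
    p <- match(order, tips)
    if (anyNA(p)) stop("order contains taxa not in tree")
    s_mat <- s_mat[p, p]
    tips <- tips[p]
  }
  s_uniq <- sort(unique(as.numeric(s_mat)))
  idx <- matrix(match(s_mat, s_uniq), n, n)
  diag_idx <- which(diag(2 * n) == 1)
  list(n = n, s_uniq = s_uniq, idx = idx, tips = tips, depth = Tdepth,
       tree = tree, diag_idx = diag_idx)
}

# Tip covariance/mean of the bivariate OU on an ultrametric tree from the
# cached MRCA-time structure (trait-major). NULL if A is unstable. Uses the
# closed-form 2x2 exponential e^{As} = alpha I + beta A, so defective
# selection matrices are handled exactly.
coev_sigma_tree <- function(A, b, cache) {
  # Routh-Hurwitz: a 2x2 system is stable iff trace < 0 and det > 0
  if (any(!is.finite(A)) || A[1, 1] + A[2, 2] >= -1e-10 ||
      A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1] <= 1e-10) return(NULL)
  K <- kronecker(diag(2), A) + kronecker(A, diag(2))
  Vinf <- matrix(as.numeric(-solve(K, as.numeric(diag(2)))), 2, 2)
  Vinf <- (Vinf + t(Vinf)) / 2
  theta <- as.numeric(-solve(A, b))
  ab <- ou_alpha_beta(A, cache$s_uniq)
  AV <- A %*% Vinf; VA <- Vinf %*% t(A); AVA <- tcrossprod(AV, A)
  a2 <- ab$alpha^2; abm <- ab$alpha * ab$beta; b2 <- ab$beta^2
  # the MRCA-time index matrix is symmetric, so each block is symmetric
  n <- cache$n
  i1 <- seq_len(n); i2 <- n + i1
  Sigma <- matrix(0, 2 * n, 2 * n)
  f11 <- a2 * Vinf[1, 1] + abm * (AV[1, 1] + VA[1, 1]) + b2 * AVA[1, 1]
  f12 <- a2 * Vinf[1, 2] + abm * (AV[1, 2] + VA[1, 2]) + b2 * AVA[1, 2]
  f22 <- a2 * Vinf[2, 2] + abm * (AV[2, 2] + VA[2, 2]) + b2 * AVA[2, 2]
  Sigma[i1, i1] <- f11[cache$idx]
  Sigma[i1, i2] <- f12[cache$idx]
  Sigma[i2, i1] <- f12[cache$idx]
  Sigma[i2, i2] <- f22[cache$idx]
  list(Sigma = Sigma, mean = rep(theta, each = n), theta = theta,
       Vinf = Vinf)
}

coev_config_defaults <- function(config = list(), scale = "desk") {
  base <- if (identical(scale, "paper")) {
    list(n_trees = 100, chains = 4, n_iter = 8000, burn = 3000, thin = 4)
  } else {
    list(n_trees = 5, chains = 2, n_iter = 3000, burn = 1000, thin = 2)
  }
  base$jitter <- 1e-8
  base$prior_cut_sd <- 2
  base$gp <- NA            # NA: spatial GP on iff coordinates available
  base$n_prop <- 2
  utils::modifyList(base, config)
}

#' Fit the dynamic coevolutionary model
#'
#' Bayesian latent bivariate Ornstein-Uhlenbeck model for two 4-level
#' ordinal traits on a time-scaled phylogeny: latent traits evolve under
#' autoregressive selection (strictly negative diagonal of the selection
#' matrix A), cross-trait selection (off-diagonals of A), drift intercept b
#' and unit diffusion (S = I, fixed for identifiability); tip liabilities
#' acquire an additive spatial Gaussian-process effect (squared-exponential
#' kernel on great-circle km, one independent GP per trait, controlling for
#' spatial proximity) and are observed as ordinal categories through probit
#' thresholding at cutpoints whose middle value is anchored at 0. The root
#' latent is drawn from the OU stationary distribution.
#'
#' Sampling is Gibbs data augmentation: probit liabilities and cutpoints
#' have truncated-normal full conditionals, tip latents an exact Gaussian
#' one (internal nodes marginalized analytically), and (A, b, GP) are
#' updated by adaptive random-walk Metropolis against the marginal
#' tip-latent likelihood. Priors: N(0,1) on off-diagonal selection and
#' drift, -exp(N(0,1)) on diagonal selection, ordered N(0,2) on free
#' cutpoints, half-normal(0,1) on GP amplitudes, log-normal(log 1000, 1) on
#' GP lengthscales (km).
#'
#' @param table Data.frame with columns \code{taxon},
#'   \code{political_authority}, \code{religious_authority} (0..3), and
#'   optionally \code{lat}, \code{lon}.
#' @param trees \code{multiPhylo}/\code{phylo} ultrametric tree sample.
#' @param coords Optional (lat, lon) matrix in table order; defaults to the
#'   table's lat/lon columns when present.
#' @param config Sampler settings (\code{n_trees}, \code{chains},
#'   \code{n_iter}, \code{burn}, \code{thin}, \code{gp}).
#' @param scale \code{"desk"} or \code{"paper"} presets.
#' @param seed Integer seed.
#' @return Object of class \code{coevauth_coev_fit}: pooled parameter
#'   \code{draws} (selection matrix entries, drift, equilibria, cutpoints,
#'   GP), thinned liability draws, per-trait \code{mad} of posterior-mean
#'   tip liabilities (the standardization constant for
#'   \code{\link{delta_theta}}), a summary table with split R-hat and ESS,
#'   and a \code{converged} flag (all R-hat <= 1.01).
#' @export
fit_coevolution <- function(table, trees, coords = NULL, config = list(),
                            scale = "desk", seed = 1) {
  cfg <- coev_config_defaults(config, scale)
  if (inherits(trees, "phylo")) trees <- c(trees)
  n <- nrow(table)
  if (n < 2) stop("need at least 2 taxa (>= 20 recommended)")
  y <- cbind(table$political_authority, table$religious_authority)
  if (any(y < 0 | y > 3)) stop("ordinal values outside 0..3")
  if (any(apply(y, 2, function(v) length(unique(v))) < 2)) {
    stop("both traits must be non-constant")
  }
  if (is.null(coords) && all(c("lat", "lon") %in% names(table))) {
    coords <- as.matrix(table[, c("lat", "lon")])
  }
  use_gp <- if (is.na(cfg$gp)) !is.null(coords) else isTRUE(cfg$gp)
  if (use_gp && is.null(coords)) stop("gp requested but no coordinates")
  Dkm2 <- if (use_gp) great_circle_distances(coords)^2 else NULL
  set.seed(seed)
  n_trees <- min(cfg$n_trees, length(trees))
  tree_ids <- sample.int(length(trees), n_trees)
  par_names <- c("a11", "a12", "a21", "a22", "b_pol", "b_rel",
                 "theta_pol", "theta_rel",
                 "cut_pol_1", "cut_pol_3", "cut_rel_1", "cut_rel_3")
  if (use_gp) par_names <- c(par_names, "gp_amp_pol", "gp_amp_rel",
                             "gp_ls_pol", "gp_ls_rel")
  all_draws <- list(); liab_list <- list()
  rhat_by_tree <- list(); caches <- list()
  for (ti in seq_along(tree_ids)) {
    tr <- prune_to_taxa(trees[[tree_ids[ti]]], table$taxon)
    cache <- coev_tree_cache(tr, order = table$taxon)
    caches[[ti]] <- cache
    chains <- vector("list", cfg$chains)
    for (ch in seq_len(cfg$chains)) {
      chains[[ch]] <- coev_gibbs_chain(y, cache, Dkm2, use_gp, cfg,
                                       seed = seed + 1000L * ti + ch)
    }
    rh <- vapply(seq_along(par_names), function(j) {
      suppressWarnings(rhat(sapply(chains, function(cc) cc$draws[, j])))
    }, 1)
    rhat_by_tree[[ti]] <- rh
    for (ch in seq_len(cfg$chains)) {
      d <- as.data.frame(chains[[ch]]$draws)
      names(d) <- par_names
      d$tree_id <- tree_ids[ti]; d$chain <- ch
      all_draws[[length(all_draws) + 1L]] <- d
      liab_list[[length(liab_list) + 1L]] <- chains[[ch]]$liab
    }
  }
  draws <- do.call(rbind, all_draws)
  liab <- do.call(rbind, liab_list)
  liab_mean <- colMeans(liab)
  mad_traits <- c(pol = mad_raw(liab_mean[seq_len(n)]),
                  rel = mad_raw(liab_mean[n + seq_len(n)]))
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
  converged <- all(is.finite(summ$rhat)) && all(summ$rhat <= 1.01)
  structure(list(draws = draws, liab = liab, mad = mad_traits,
                 summary = summ, converged = converged,
                 tree_ids = tree_ids, caches = caches, table = table,
                 coords = coords, use_gp = use_gp, Dkm2 = Dkm2,
                 config = cfg, seed = seed, n = n),
            class = "coevauth_coev_fit")
}

# A and b from the sampled parameter vector.
coev_A_of <- function(phi) {
  matrix(c(-exp(phi[1]), phi[4], phi[3], -exp(phi[2])), 2, 2)
}

# One Gibbs chain for the coevolution model; y in cache tip order.
#
# The probit liabilities u are Gaussian given the parameters with
# covariance Sigma(A) + I (tip latents integrate out analytically), so the
# parameter updates are collapsed: theta (hence the drift b = -A theta) has
# an exact Gaussian full conditional against u, the selection matrix (+ GP)
# moves by adaptive RWM against the u-marginal, and per-trait "scale ridge"
# moves rescale (u, cutpoints) jointly with a similarity transform of A.
# Tip latents are redrawn from their exact conditional afterwards
# (Matheron update), giving the stored liability draws.
coev_gibbs_chain <- function(y, cache, Dkm2, use_gp, cfg, seed) {
  set.seed(seed)
  n <- nrow(y)
  np <- if (use_gp) 10L else 6L
  phi <- c(la1 = 0, la2 = 0, a12 = 0, a21 = 0, b1 = 0, b2 = 0)
  if (use_gp) phi <- c(phi, lg1 = log(0.3), lg2 = log(0.3),
                       ll1 = log(1000), ll2 = log(1000))
  cp <- list(pol = c(-1, 1), rel = c(-1, 1))   # free cutpoints (c2 = 0)
  u <- cbind(c(-1.5, -0.5, 0.5, 1.5)[y[, 1] + 1],
             c(-1.5, -0.5, 0.5, 1.5)[y[, 2] + 1]) +
    matrix(stats::rnorm(2 * n, 0, 0.1), n, 2)
  ell <- u
  build <- function(phi) {
    phi <- as.numeric(phi)
    if (any(!is.finite(phi)) || any(abs(phi[1:6]) > 15)) return(NULL)
    St <- coev_sigma_tree(coev_A_of(phi), phi[5:6], cache)
    if (is.null(St)) return(NULL)
    Sigma <- St$Sigma
    if (use_gp) {
      for (d in 1:2) {
        amp2 <- exp(2 * phi[6 + d])
        ls2 <- exp(2 * phi[8 + d])
        idxd <- (d - 1) * n + seq_len(n)
        Sigma[idxd, idxd] <- Sigma[idxd, idxd] + amp2 * exp(-Dkm2 / (2 * ls2))
      }
    }
    Sigma[cache$diag_idx] <- Sigma[cache$diag_idx] + cfg$jitter
    M <- Sigma
    M[cache$diag_idx] <- M[cache$diag_idx] + 1
    cholM <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(cholM)) return(NULL)
    list(Sigma = Sigma, cholM = cholM, mean = St$mean, theta = St$theta)
  }
  logprior_phi <- function(phi) {
    phi <- as.numeric(phi)
    lp <- sum(stats::dnorm(phi[1:6], log = TRUE))
    if (use_gp) {
      # amplitude half-normal(0,1) with log-scale Jacobian
      lp <- lp - 0.5 * exp(2 * phi[7]) + phi[7] -
        0.5 * exp(2 * phi[8]) + phi[8] +
        stats::dnorm(phi[9], log(1000), 1, log = TRUE) +
        stats::dnorm(phi[10], log(1000), 1, log = TRUE)
    }
    lp
  }
  # u-marginal log posterior: N(u; mean, Sigma + I) + parameter priors
  logpost_marg <- function(S, phi, uv) {
    v <- backsolve(S$cholM, uv - S$mean, transpose = TRUE)
    -sum(log(diag(S$cholM))) - 0.5 * sum(v^2) - n * log(2 * pi) +
      logprior_phi(phi)
  }
  logp_cp <- function(cp) {
    sum(stats::dnorm(c(cp[[1]], cp[[2]]), 0, cfg$prior_cut_sd, log = TRUE))
  }
  S <- build(phi)
  if (is.null(S)) stop("could not initialize covariance")
  uv <- c(u[, 1], u[, 2])
  lp <- logpost_marg(S, phi, uv)
  rwm_idx <- if (use_gp) c(1:4, 7:10) else 1:4
  nr <- length(rwm_idx)
  Z <- cbind(c(rep(1, n), rep(0, n)), c(rep(0, n), rep(1, n)))
  Lp <- chol(diag(0.02, nr))
  mean_run <- phi[rwm_idx]; cov_run <- diag(0.02, nr); n_run <- 1
  nkeep <- floor((cfg$n_iter - cfg$burn) / cfg$thin)
  keep <- matrix(NA_real_, nkeep, if (use_gp) 16 else 12)
  liab_keep <- matrix(NA_real_, nkeep, 2 * n)
  ki <- 0L
  for (it in seq_len(cfg$n_iter)) {
    # 1. probit liabilities u | ell, cutpoints
    for (d in 1:2) {
      bnd <- c(-Inf, cp[[d]][1], 0, cp[[d]][2], Inf)
      u[, d] <- rtruncnorm_vec(ell[, d], 1, bnd[y[, d] + 1], bnd[y[, d] + 2])
    }
    uv <- c(u[, 1], u[, 2])
    # 2. free cutpoints | u (middle cutpoint anchored at 0)
    for (d in 1:2) {
      c1 <- draw_one_cutpoint(lo = max(c(u[y[, d] == 0, d], -Inf)),
                              hi = min(c(u[y[, d] == 1, d], 0)),
                              cur = cp[[d]][1], prior_sd = cfg$prior_cut_sd)
      c3 <- draw_one_cutpoint(lo = max(c(u[y[, d] == 2, d], 0)),
                              hi = min(c(u[y[, d] == 3, d], Inf)),
                              cur = cp[[d]][2], prior_sd = cfg$prior_cut_sd)
      cp[[d]] <- c(c1, c3)
    }
    # 3. drift via the equilibrium: theta | u, A is Gaussian with precision
    #    Z' (Sigma+I)^-1 Z + A'A (prior b ~ N(0, I), b = -A theta)
    A <- coev_A_of(phi)
    MZ <- backsolve(S$cholM, backsolve(S$cholM, Z, transpose = TRUE))
    prec_t <- crossprod(Z, MZ) + crossprod(A)
    cht <- chol((prec_t + t(prec_t)) / 2)
    lin <- as.numeric(crossprod(MZ, uv))
    mean_t <- backsolve(cht, backsolve(cht, lin, transpose = TRUE))
    theta <- as.numeric(mean_t + backsolve(cht, stats::rnorm(2)))
    phi[5:6] <- as.numeric(-A %*% theta)
    S$mean <- rep(theta, each = n)
    S$theta <- theta
    lp <- logpost_marg(S, phi, uv)
    # 4. selection (+ GP) | u: adaptive RWM on the collapsed marginal
    for (r in seq_len(cfg$n_prop)) {
      prop <- phi
      prop[rwm_idx] <- prop[rwm_idx] + as.numeric(crossprod(Lp, stats::rnorm(nr)))
      Sp <- build(prop)
      if (!is.null(Sp)) {
        lpp <- logpost_marg(Sp, prop, uv)
        if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
          phi <- prop; S <- Sp; lp <- lpp
        }
      }
    }
    # 5. per-trait scale ridge: rescale liabilities and cutpoints jointly
    #    with a similarity transform of A whose diagonal absorbs the fixed
    #    unit diffusion (V_inf ~ 1/|a_dd|)
    for (d in 1:2) {
      tstep <- stats::rnorm(1, 0, 0.08)
      cfac <- exp(tstep)
      phi2 <- phi; phi2[d] <- phi[d] - 2 * tstep
      if (d == 1) {
        phi2[3] <- phi[3] * cfac        # a12 (row 1 scales by c)
        phi2[4] <- phi[4] / cfac        # a21
      } else {
        phi2[3] <- phi[3] / cfac
        phi2[4] <- phi[4] * cfac
      }
      u2 <- u; u2[, d] <- cfac * u[, d]
      cp2 <- cp; cp2[[d]] <- cfac * cp[[d]]
      Sp <- build(phi2)
      if (!is.null(Sp)) {
        uv2 <- c(u2[, 1], u2[, 2])
        num <- logpost_marg(Sp, phi2, uv2) + logp_cp(cp2)
        den <- lp + logp_cp(cp)
        if (is.finite(num) &&
            log(stats::runif(1)) < num - den + (n + 2) * tstep) {
          phi <- phi2; u <- u2; cp <- cp2; uv <- uv2
          S <- Sp; lp <- logpost_marg(S, phi, uv)
        }
      }
    }
    # 6. tip latents ell | u, phi by the Matheron update:
    #    ell* = mu + l0 + Sigma (Sigma+I)^-1 (u - mu - l0 - eta)
    cholS <- tryCatch(chol(S$Sigma), error = function(e) NULL)
    if (is.null(cholS)) {
      egS <- eigen(S$Sigma, symmetric = TRUE)
      cholS <- diag(sqrt(pmax(egS$values, 0))) %*% t(egS$vectors)
    }
    l0 <- as.numeric(crossprod(cholS, stats::rnorm(2 * n)))
    resid <- uv - S$mean - l0 - stats::rnorm(2 * n)
    w <- backsolve(S$cholM, backsolve(S$cholM, resid, transpose = TRUE))
    ellv <- as.numeric(S$mean + l0 + S$Sigma %*% w)
    ell <- matrix(ellv, n, 2)
    if (it <= cfg$burn) {
      n_run <- n_run + 1
      delta <- phi[rwm_idx] - mean_run
      mean_run <- mean_run + delta / n_run
      cov_run <- cov_run * (n_run - 2) / (n_run - 1) + tcrossprod(delta) / n_run
      if (it %% 50 == 0 && it >= 100) {
        ch <- tryCatch(chol(2.38^2 * cov_run / nr + diag(1e-7, nr)),
                       error = function(e) NULL)
        if (!is.null(ch)) Lp <- ch
      }
    } else if ((it - cfg$burn) %% cfg$thin == 0 && ki < nkeep) {
      ki <- ki + 1L
      A <- coev_A_of(phi)
      row <- c(A[1, 1], A[1, 2], A[2, 1], A[2, 2], phi[5], phi[6],
               S$theta, cp[[1]][1], cp[[1]][2], cp[[2]][1], cp[[2]][2])
      if (use_gp) row <- c(row, exp(phi[7]), exp(phi[8]),
                           exp(phi[9]), exp(phi[10]))
      keep[ki, ] <- row
      liab_keep[ki, ] <- ellv
    }
  }
  list(draws = keep[seq_len(ki), , drop = FALSE],
       liab = liab_keep[seq_len(ki), , drop = FALSE])
}

draw_one_cutpoint <- function(lo, hi, cur, prior_sd) {
  if (!(lo < hi)) return(min(max(cur, lo), hi))
  plo <- stats::pnorm(lo / prior_sd)
  phi_ <- stats::pnorm(hi / prior_sd)
  out <- cur
  if (phi_ - plo > 1e-14) {
    uu <- stats::runif(1, plo, phi_)
    out <- prior_sd * stats::qnorm(min(max(uu, 1e-15), 1 - 1e-15))
  } else if (is.finite(lo) && is.finite(hi)) {
    out <- (lo + hi) / 2
  }
  min(max(out, lo), hi)
}

#' Standardized coevolutionary effect sizes
#'
#' The change in the equilibrium value of one trait per one-MAD increase in
#' the other: per posterior draw,
#' \eqn{\Delta\theta_{d \leftarrow e} = -(A_{de} / A_{dd}) \cdot MAD_e},
#' where the MAD (unscaled median absolute deviation) of the conditioning
#' trait's posterior-mean tip liabilities is computed once per fit.
#' Summaries: posterior median, 95 percent HPDI, posterior probability of a
#' positive value, and a Savage-Dickey doubled-log Bayes factor against 0
#' (Gaussian KDE of posterior and prior draws at 0). The posterior
#' difference between the two directions is reported alongside.
#'
#' @param fit A \code{coevauth_coev_fit}, or an \code{\link{ou_params}} for
#'   a point evaluation.
#' @param mad Per-trait MAD pair; taken from the fit when omitted.
#' @param prior_draws Number of prior simulations for the Savage-Dickey
#'   denominator.
#' @param seed Seed for the prior simulation.
#' @return For a fit: object of class \code{coev_delta_theta} with a
#'   summary data.frame (rows pol_from_rel, rel_from_pol, difference) and
#'   the per-draw values. For \code{ou_params}: named numeric pair.
#' @export
delta_theta <- function(fit, mad = NULL, prior_draws = 40000, seed = 1) {
  if (inherits(fit, "ou_params")) {
    if (is.null(mad)) stop("mad required for a point evaluation")
    if (any(mad <= 0)) stop("mad must be positive")
    A <- fit$A
    return(c(pol_from_rel = -(A[1, 2] / A[1, 1]) * mad[2],
             rel_from_pol = -(A[2, 1] / A[2, 2]) * mad[1]))
  }
  stopifnot(inherits(fit, "coevauth_coev_fit"))
  if (is.null(mad)) mad <- fit$mad
  if (any(mad <= 0)) stop("mad must be positive")
  d12 <- -(fit$draws$a12 / fit$draws$a11) * mad[2]
  d21 <- -(fit$draws$a21 / fit$draws$a22) * mad[1]
  diff_dir <- d12 - d21
  set.seed(seed)
  pri12 <- -(stats::rnorm(prior_draws) / (-exp(stats::rnorm(prior_draws)))) *
    mad[2]
  pri21 <- -(stats::rnorm(prior_draws) / (-exp(stats::rnorm(prior_draws)))) *
    mad[1]
  kde0 <- function(x) {
    d <- stats::density(x)
    max(stats::approx(d$x, d$y, xout = 0, yleft = 0, yright = 0)$y, 1e-12)
  }
  row_of <- function(x, prior0) {
    h <- hpdi(x)
    lbf <- if (is.null(prior0)) NA_real_ else
      suppressWarnings(savage_dickey_logbf(x, prior0))
    data.frame(median = stats::median(x), hpdi_low = h[1], hpdi_high = h[2],
               pp = pp_positive(x), logbf = lbf)
  }
  out <- rbind(pol_from_rel = row_of(d12, kde0(pri12)),
               rel_from_pol = row_of(d21, kde0(pri21)),
               difference = row_of(diff_dir, NULL))
  structure(list(summary = out, draws = data.frame(
    pol_from_rel = d12, rel_from_pol = d21, difference = diff_dir),
    mad = mad), class = "coev_delta_theta")
}

#' @export
print.coev_delta_theta <- function(x, ...) {
  cat("Equilibrium responses per MAD increase of the other trait:\n")
  print(round(x$summary, 3))
  invisible(x)
}

#' Ancestral state reconstruction from a coevolution fit
#'
#' For a subsample of posterior draws, conditions the internal-node latents
#' on that draw's tip liabilities (joint Gaussian under the OU tree process;
#' the spatial GP contributes only to tip liabilities), samples the node
#' latents, converts them to ordinal level probabilities
#' \eqn{P(k) = \Phi(c_{k+1} - \eta) - \Phi(c_k - \eta)} (summing to 1 per
#' draw), and reports per-node medians across draws.
#'
#' @param fit A \code{coevauth_coev_fit}.
#' @param clades Optional named list of taxon vectors; each names the MRCA
#'   node of the listed taxa (e.g. proto-language clades).
#' @param n_draws Number of posterior draws to use.
#' @param seed Integer seed.
#' @return Data.frame with node id, optional clade name, trait, median
#'   latent, and median level probabilities p0..p3.
#' @export
ancestral_states <- function(fit, clades = NULL, n_draws = 200, seed = 1) {
  stopifnot(inherits(fit, "coevauth_coev_fit"))
  set.seed(seed)
  n <- fit$n
  cache1 <- fit$caches[[1]]
  tree <- cache1$tree
  tid1 <- fit$tree_ids[1]
  sel_pool <- which(fit$draws$tree_id == tid1)
  sel <- sel_pool[sort(sample.int(length(sel_pool),
                                  min(n_draws, length(sel_pool))))]
  node_cache <- ou_node_cache(tree)
  m <- length(node_cache$node_ids)
  clade_nodes <- NULL
  if (!is.null(clades)) {
    clade_nodes <- vapply(clades, function(tx) {
      miss <- setdiff(tx, tree$tip.label)
      if (length(miss)) stop("clade taxa not in tree: ",
                             paste(miss, collapse = ", "))
      ape::getMRCA(tree, tx)
    }, 1L)
  }
  # taxa order: fit table order; map node-tip covariances accordingly
  perm_tips <- match(fit$table$taxon, tree$tip.label)
  acc_lat <- array(NA_real_, c(length(sel), m, 2))
  acc_p <- array(NA_real_, c(length(sel), m, 2, 4))
  for (si in seq_along(sel)) {
    dr <- fit$draws[sel[si], ]
    A <- matrix(c(dr$a11, dr$a21, dr$a12, dr$a22), 2, 2)
    b <- c(dr$b_pol, dr$b_rel)
    params <- ou_params(A, b)
    St <- coev_sigma_tree(A, b, cache1)
    Sigma <- St$Sigma + diag(fit$config$jitter, 2 * n)
    if (fit$use_gp) {
      for (d in 1:2) {
        amp2 <- dr[[c("gp_amp_pol", "gp_amp_rel")[d]]]^2
        ls2 <- dr[[c("gp_ls_pol", "gp_ls_rel")[d]]]^2
        idxd <- (d - 1) * n + seq_len(n)
        Sigma[idxd, idxd] <- Sigma[idxd, idxd] + amp2 * exp(-fit$Dkm2 / (2 * ls2))
      }
    }
    nb <- ou_node_blocks(params, node_cache, perm_tips)
    ellv <- fit$liab[sel[si], ]
    Sinv_r <- solve(Sigma, cbind(ellv - St$mean, t(nb$C_nt)))
    mean_nodes <- nb$mean + as.numeric(nb$C_nt %*% Sinv_r[, 1])
    cov_nodes <- nb$C_nn - nb$C_nt %*% Sinv_r[, -1, drop = FALSE]
    eta_nodes <- mean_nodes +
      as.numeric(chol_psd(cov_nodes) %*% stats::rnorm(2 * m))
    cps <- list(c(dr$cut_pol_1, 0, dr$cut_pol_3),
                c(dr$cut_rel_1, 0, dr$cut_rel_3))
    for (d in 1:2) {
      etad <- eta_nodes[(d - 1) * m + seq_len(m)]
      acc_lat[si, , d] <- etad
      bnd <- c(-Inf, cps[[d]], Inf)
      for (k in 1:4) {
        acc_p[si, , d, k] <- stats::pnorm(bnd[k + 1] - etad) -
          stats::pnorm(bnd[k] - etad)
      }
    }
  }
  out <- expand.grid(node = node_cache$node_ids, trait = c("pol", "rel"),
                     stringsAsFactors = FALSE)
  out$clade <- NA_character_
  if (!is.null(clade_nodes)) {
    for (nmv in names(clade_nodes)) {
      out$clade[out$node == clade_nodes[[nmv]]] <- nmv
    }
  }
  di <- ifelse(out$trait == "pol", 1, 2)
  ni <- match(out$node, node_cache$node_ids)
  out$median_latent <- vapply(seq_len(nrow(out)), function(r) {
    stats::median(acc_lat[, ni[r], di[r]])
  }, 1)
  for (k in 1:4) {
    out[[paste0("p", k - 1)]] <- vapply(seq_len(nrow(out)), function(r) {
      stats::median(acc_p[, ni[r], di[r], k])
    }, 1)
  }
  out
}

# Precomputed depth/MRCA structure over internal nodes and tips.
ou_node_cache <- function(tree) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  depths <- ape::node.depth.edgelength(tree)
  mrF <- ape::mrca(tree, full = TRUE)
  list(n = n, node_ids = n + seq_len(m), depths = depths, mrF = mrF)
}

# Node-node and node-tip covariance blocks of the stationary OU on a tree.
ou_node_blocks <- function(params, cache, perm_tips = NULL) {
  A <- params$A
  n <- cache$n
  nodes <- cache$node_ids
  m <- length(nodes)
  depths <- cache$depths
  st <- stationary_moments(params)
  tips <- seq_len(n)
  if (!is.null(perm_tips)) tips <- perm_tips
  block_set <- function(rows, cols) {
    d_a <- matrix(depths[cache$mrF[rows, cols, drop = FALSE]],
                  length(rows), length(cols))
    Ti <- outer(depths[rows], rep(1, length(cols))) - d_a
    Tj <- t(outer(depths[cols], rep(1, length(rows)))) - d_a
    ou_pair_blocks(A, st$V_inf, Ti, Tj)
  }
  C_nn <- assemble_blocks(block_set(nodes, nodes), 2, m, m)
  C_nt <- assemble_blocks(block_set(nodes, tips), 2, m, n)
  list(mean = rep(st$theta_star, each = m),
       C_nn = (C_nn + t(C_nn)) / 2, C_nt = C_nt)
}

#' Parameter-recovery experiment for the coevolution model
#'
#' Simulates replicate datasets under fixed selection/drift truth, fits the
#' model to each, and reports 95 percent credible-interval coverage of the
#' selection and drift parameters, plus the posterior probability of a
#' positive equilibrium response in each direction (used for null
#' calibration when the true cross-trait selection is zero).
#'
#' @param n_rep Number of replicates.
#' @param n_tips Tips per simulated tree.
#' @param truth An \code{\link{ou_params}} truth (default: the fixed
#'   recovery configuration, cross-trait selection 0.8).
#' @param fit_config Sampler settings passed to
#'   \code{\link{fit_coevolution}}.
#' @param seed Integer base seed.
#' @param out_csv Optional path for the per-parameter coverage CSV.
#' @return List with \code{per_rep} (data.frame of CI bounds, coverage
#'   indicators and direction PPs per replicate) and \code{coverage} (named
#'   coverage fractions).
#' @export
recovery_experiment <- function(n_rep = 20, n_tips = 60,
                                truth = default_ou_truth(),
                                fit_config = list(), seed = 1,
                                out_csv = NULL) {
  pars <- c(a11 = truth$A[1, 1], a12 = truth$A[1, 2],
            a21 = truth$A[2, 1], a22 = truth$A[2, 2],
            b_pol = truth$b[1], b_rel = truth$b[2])
  cfgf <- utils::modifyList(list(n_trees = 1, chains = 1, n_iter = 2200,
                                 burn = 700, thin = 2, gp = FALSE),
                            fit_config)
  rows <- list()
  for (r in seq_len(n_rep)) {
    tree <- simulate_tree(n_tips, seed = seed + 37L * r)
    sim <- simulate_coevolution(tree, truth, coords = NULL,
                                seed = seed + 37L * r + 1L)
    tab <- data.frame(taxon = tree$tip.label,
                      political_authority = sim$ordinal[, 1],
                      religious_authority = sim$ordinal[, 2])
    if (any(apply(tab[, 2:3], 2, function(v) length(unique(v))) < 2)) next
    fit <- fit_coevolution(tab, tree, config = cfgf,
                           seed = seed + 37L * r + 2L)
    dt <- delta_theta(fit)
    row <- data.frame(rep = r)
    for (p in names(pars)) {
      h <- hpdi(fit$draws[[p]])
      row[[paste0(p, "_low")]] <- h[1]
      row[[paste0(p, "_high")]] <- h[2]
      row[[paste0(p, "_cover")]] <- as.integer(pars[p] >= h[1] & pars[p] <= h[2])
    }
    row$pp_pol_from_rel <- dt$summary["pol_from_rel", "pp"]
    row$pp_rel_from_pol <- dt$summary["rel_from_pol", "pp"]
    rows[[length(rows) + 1L]] <- row
  }
  per_rep <- do.call(rbind, rows)
  coverage <- vapply(names(pars), function(p) {
    mean(per_rep[[paste0(p, "_cover")]])
  }, 1)
  if (!is.null(out_csv)) {
    utils::write.csv(
      data.frame(parameter = names(pars), truth = as.numeric(pars),
                 coverage = as.numeric(coverage), n_rep = nrow(per_rep)),
      out_csv, row.names = FALSE)
  }
  list(per_rep = per_rep, coverage = coverage, truth = pars)
}

#' @export
print.coevauth_coev_fit <- function(x, ...) {
  cat("Dynamic coevolutionary model:", x$n, "taxa,",
      length(x$tree_ids), "trees x", x$config$chains, "chains",
      if (x$use_gp) "(spatial GP on)" else "(spatial GP off)", "\n")
  cat("  converged (all R-hat <= 1.01):", x$converged, "\n")
  keyrows <- x$summary$parameter %in% c("a11", "a12", "a21", "a22",
                                        "b_pol", "b_rel")
  print(x$summary[keyrows, ], digits = 3, row.names = FALSE)
  dt <- delta_theta(x)
  print(dt)
  invisible(x)
}

#' @export
summary.coevauth_coev_fit <- function(object, ...) object$summary

#' @export
coef.coevauth_coev_fit <- function(object, ...) {
  stats::setNames(object$summary$median, object$summary$parameter)
}

#' @export
plot.coevauth_coev_fit <- function(x, grid_n = 15, ...) {
  md <- coef(x)
  A <- matrix(c(md["a11"], md["a21"], md["a12"], md["a22"]), 2, 2)
  p <- ou_params(A, b = c(md["b_pol"], md["b_rel"]),
                 cutpoints = list(c(md["cut_pol_1"], 0, md["cut_pol_3"]),
                                  c(md["cut_rel_1"], 0, md["cut_rel_3"])))
  pp <- phase_plane(p, grid_n = grid_n)
  plot(pp, ...)
  invisible(pp)
}

#' Simulate ordinal data from a fitted coevolution model
#'
#' Forward-simulates tip data on the fit's first tree using the posterior
#' median parameters.
#'
#' @param object A \code{coevauth_coev_fit}.
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List of simulation lists (see
#'   \code{\link{simulate_coevolution}}).
#' @export
simulate.coevauth_coev_fit <- function(object, nsim = 1, seed = 1, ...) {
  md <- coef(object)
  A <- matrix(c(md["a11"], md["a21"], md["a12"], md["a22"]), 2, 2)
  p <- ou_params(A, b = c(md["b_pol"], md["b_rel"]),
                 cutpoints = list(c(md["cut_pol_1"], 0, md["cut_pol_3"]),
                                  c(md["cut_rel_1"], 0, md["cut_rel_3"])))
  tree <- object$caches[[1]]$tree
  lapply(seq_len(nsim), function(i) {
    simulate_coevolution(tree, p, coords = NULL, seed = seed + i - 1L)
  })
}
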