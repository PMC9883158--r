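#' Adaptive random-walk Metropolis sampler
#'
#' Reference MCMC engine used by the model-fitting routines: a Gaussian
#' random-walk Metropolis sampler whose proposal covariance is adapted to the
#' running sample covariance during burn-in (Haario-style, with a small
#' regularizing nugget) and frozen afterwards, so the post-burn-in chain is a
#' valid Markov chain.
#'
#' @param logpost Function taking a numeric parameter vector, returning the
#'   (unnormalized) log posterior density; may return \code{-Inf}.
#' @param init Numeric start vector.
#' @param n_iter Total iterations (including burn-in).
#' @param burn Burn-in iterations (adaptation window).
#' @param seed Integer seed.
#' @param prop_scale Initial proposal standard deviation per coordinate.
#' @param thin Keep every \code{thin}-th post-burn-in draw.
#' @return List with \code{draws} (matrix, post-burn-in), \code{accept}
#'   (acceptance rate), \code{logpost} (vector of retained log posteriors).
#' @export
adaptive_metropolis <- function(logpost, init, n_iter = 5000,
                                burn = floor(n_iter / 3), seed = 1,
                                prop_scale = 0.1, thin = 1) {
  set.seed(seed)
  d <- length(init)
  x <- as.numeric(init)
  lp <- logpost(x)
  if (!is.finite(lp)) stop("initial value has zero posterior density")
  C <- diag(prop_scale^2, d)
  L <- chol(C)
  mean_run <- x; cov_run <- diag(prop_scale^2, d); n_run <- 1
  keep <- matrix(NA_real_, ceiling((n_iter - burn) / thin), d)
  kept_lp <- numeric(nrow(keep))
  acc <- 0L; ki <- 0L
  sd_fac <- 2.38^2 / d
  for (i in seq_len(n_iter)) {
    prop <- x + as.numeric(crossprod(L, stats::rnorm(d)))
    lpp <- logpost(prop)
    if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
      x <- prop; lp <- lpp; acc <- acc + 1L
    }
    if (i <= burn) {
      # running moments for adaptation
      n_run <- n_run + 1
      delta <- x - mean_run
      mean_run <- mean_run + delta / n_run
      cov_run <- cov_run * (n_run - 2) / (n_run - 1) +
        tcrossprod(delta) / n_run
      if (i %% 50 == 0 && i >= 100) {
        Cad <- sd_fac * cov_run + diag(1e-8 + 1e-4 * prop_scale^2, d)
        ch <- tryCatch(chol(Cad), error = function(e) NULL)
        if (!is.null(ch)) L <- ch
      }
    } else if ((i - burn) %% thin == 0) {
      ki <- ki + 1L
      keep[ki, ] <- x
      kept_lp[ki] <- lp
    }
  }
  list(draws = keep[seq_len(ki), , drop = FALSE], accept = acc / n_iter,
       logpost = kept_lp[seq_len(ki)])
}

#' Split R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, optionally on rank-normalized draws.
#'
#' @param chains A matrix (iterations x chains) or list of equal-length
#'   numeric vectors.
#' @param rank_normalize Use rank-normalized draws.
#' @return R-hat; \code{NaN} (with a warning) for constant chains.
#' @export
rhat <- function(chains, rank_normalize = FALSE) {
  X <- as_chain_matrix(chains)
  if (ncol(X) < 2L) {
    # single chain: split in half to get two pseudo-chains
    n2 <- floor(nrow(X) / 2)
    X <- cbind(X[seq_len(n2), 1], X[n2 + seq_len(n2), 1])
  }
  if (nrow(X) < 4L) stop("chains must have length >= 4")
  n2 <- floor(nrow(X) / 2)
  X <- cbind(X[seq_len(n2), , drop = FALSE],
             X[nrow(X) - n2 + seq_len(n2), , drop = FALSE])
  if (stats::sd(as.numeric(X)) < 1e-300 || any(apply(X, 2, stats::sd) == 0)) {
    warning("constant chain; R-hat undefined")
    return(NaN)
  }
  if (rank_normalize) {
    r <- rank(X, ties.method = "average")
    X <- matrix(stats::qnorm((r - 0.375) / (length(X) + 0.25)), nrow(X))
  }
  m <- ncol(X); n <- nrow(X)
  means <- colMeans(X)
  B <- n * stats::var(means)
  W <- mean(apply(X, 2, stats::var))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS with Geyer's initial monotone positive-sequence
#' truncation, summed over chains.
#'
#' @param chains Matrix (iterations x chains), list of vectors, or vector.
#' @return Estimated effective number of independent draws.
#' @export
ess <- function(chains) {
  X <- as_chain_matrix(chains)
  n <- nrow(X); m <- ncol(X)
  if (stats::sd(as.numeric(X)) == 0) return(NaN)
  ess_one <- function(x) {
    n <- length(x)
    v <- stats::var(x)
    if (v == 0) return(n)
    ac <- stats::acf(x, lag.max = min(n - 2, 2000), plot = FALSE)$acf[-1]
    # pair sums; truncate at first negative, enforce monotone decrease
    np <- floor(length(ac) / 2)
    if (np < 1) return(n)
    ps <- ac[2 * seq_len(np) - 1] + ac[2 * seq_len(np)]
    ps <- cummin(pmax(ps, 0))
    k <- which(ps <= 0)[1]
    if (!is.na(k)) ps <- ps[seq_len(k - 1)]
    n / max(1, 1 + 2 * sum(ps))
  }
  sum(apply(X, 2, ess_one))
}

as_chain_matrix <- function(chains) {
  if (is.list(chains)) {
    len <- unique(vapply(chains, length, 1L))
    if (length(len) != 1L) stop("chains must have equal lengths")
    X <- do.call(cbind, chains)
  } else if (is.matrix(chains)) {
    X <- chains
  } else {
    X <- matrix(as.numeric(chains), ncol = 1)
  }
  X
}

#' Highest posterior density interval
#'
#' Narrowest contiguous interval containing a given posterior mass, by the
#' sorted-window method.
#'
#' @param draws Numeric vector (>= 100 draws).
#' @param mass Interval mass in (0, 1).
#' @return Numeric \code{c(low, high)}.
#' @export
hpdi <- function(draws, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  x <- sort(as.numeric(draws))
  n <- length(x)
  if (n < 100) stop("need at least 100 draws for an HPDI")
  k <- max(1L, ceiling(mass * n))
  nwin <- n - k + 1L
  widths <- x[k:n] - x[seq_len(nwin)]
  i <- which.min(widths)
  c(x[i], x[i + k - 1L])
}

#' Unscaled median absolute deviation
#'
#' \code{median(|x - median(x)|)} with no normal-consistency factor; the
#' robust dispersion used to standardize the coevolution effect sizes.
#'
#' @param values Numeric vector (nonempty).
#' @export
mad_raw <- function(values) {
  if (length(values) < 1L) stop("empty input")
  stats::mad(values, constant = 1)
}

#' Savage-Dickey log Bayes factor against a point null at zero
#'
#' Returns \eqn{2\ln(p_{prior}(0) / p_{posterior}(0))}, the
#' doubled-natural-log Bayes factor in favour of the unrestricted model,
#' with the posterior density at zero estimated by a Gaussian kernel density
#' (Silverman bandwidth).
#'
#' @param posterior_draws Numeric vector of posterior draws (>= 500).
#' @param prior_density_at_0 Prior density evaluated at zero (finite,
#'   positive).
#' @param bw Kernel bandwidth rule, passed to \code{stats::density}.
#' @export
savage_dickey_logbf <- function(posterior_draws, prior_density_at_0,
                                bw = "nrd0") {
  if (length(posterior_draws) < 500) stop("need at least 500 draws")
  if (!is.finite(prior_density_at_0) || prior_density_at_0 <= 0) {
    stop("prior density at 0 must be finite and positive")
  }
  d <- stats::density(posterior_draws, bw = bw)
  post0 <- stats::approx(d$x, d$y, xout = 0, yleft = 0, yright = 0)$y
  if (is.na(post0) || post0 <= 0) {
    warning("estimated posterior density at 0 is zero; returning +Inf")
    return(Inf)
  }
  2 * (log(prior_density_at_0) - log(post0))
}

#' Posterior probability of a positive value
#'
#' Fraction of draws greater than zero.
#' @param draws Numeric vector.
#' @export
pp_positive <- function(draws) {
  if (length(draws) < 1L) stop("empty input")
  mean(draws > 0)
}

#' Posterior summary of a parameter
#'
#' @param draws Numeric vector of pooled draws.
#' @param chains Optional matrix/list for diagnostics; defaults to treating
#'   \code{draws} as one chain.
#' @param mass HPDI mass.
#' @return List: median, hpdi_low, hpdi_high, pp_positive, rhat, ess.
#' @export
summarize_draws <- function(draws, chains = NULL, mass = 0.95) {
  h <- hpdi(draws, mass)
  rh <- if (is.null(chains)) NA_real_ else suppressWarnings(rhat(chains))
  es <- if (is.null(chains)) suppressWarnings(ess(draws)) else
    suppressWarnings(ess(chains))
  list(median = stats::median(draws), hpdi_low = h[1], hpdi_high = h[2],
       pp_positive = pp_positive(draws), rhat = rh, ess = es)
}

#' Stepping-stone marginal likelihood for a generic model
#'
#' Estimates \eqn{\log p(y)} by power-posterior path sampling: stones at
#' powers \eqn{\beta_k = (k/K)^{1/0.3}} (quantiles of a Beta(0.3, 1)
#' density, concentrating stones near the prior), a random-walk Metropolis
#' chain per stone warm-started from the previous stone, and the
#' log-sum-exp stepping-stone identity
#' \eqn{\log p(y) = \sum_k \log \mathrm{mean}_j\,
#' L_j^{\beta_{k+1}-\beta_k}} with likelihoods sampled under \eqn{\beta_k}.
#'
#' @param loglik Function(theta) -> log likelihood.
#' @param logprior Function(theta) -> log prior density.
#' @param init Start vector (should have positive prior density).
#' @param K Number of stones.
#' @param iter Post-burn-in iterations per stone.
#' @param burn Burn-in iterations per stone.
#' @param seed Integer seed.
#' @param prop_scale Proposal standard deviation.
#' @return List: \code{logml}, per-stone \code{betas}, acceptance rates.
#' @export
stepping_stone <- function(loglik, logprior, init, K = 20, iter = 2000,
                           burn = 500, seed = 1, prop_scale = 0.5) {
  set.seed(seed)
  betas <- (seq(0, K) / K)^(1 / 0.3)
  d <- length(init)
  x <- as.numeric(init)
  ll <- loglik(x); lp <- logprior(x)
  if (!is.finite(lp)) stop("init has zero prior density")
  logml <- 0
  acc_rates <- numeric(K)
  for (k in seq_len(K)) {
    beta <- betas[k]
    dbeta_k <- betas[k + 1] - betas[k]
    samples <- numeric(iter)
    acc <- 0L
    for (i in seq_len(burn + iter)) {
      prop <- x + stats::rnorm(d, 0, prop_scale)
      llp <- loglik(prop); lpp <- logprior(prop)
      if (is.finite(lpp) &&
          log(stats::runif(1)) < (beta * llp + lpp) - (beta * ll + lp)) {
        x <- prop; ll <- llp; lp <- lpp; acc <- acc + 1L
      }
      if (i > burn) samples[i - burn] <- ll
    }
    acc_rates[k] <- acc / (burn + iter)
    logml <- logml + log_mean_exp(dbeta_k * samples)
  }
  list(logml = logml, betas = betas, accept = acc_rates)
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

# Plain-text chain trace IO: columnar TSV plus a JSON sidecar with seeds
# and configuration, so runs can be audited without binary formats.
write_chain_traces <- function(draws, file, meta = list()) {
  utils::write.table(as.data.frame(draws), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

read_chain_traces <- function(file) {
  as.matrix(utils::read.table(file, header = TRUE, sep = "\t"))
}
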