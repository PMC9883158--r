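ms_states <- c("none", "combined", "partly_independent", "independent")

ms_pair_names <- function() {
  p <- expand.grid(to = 0:3, from = 0:3)
  p <- p[p$from != p$to, c("from", "to")]
  p <- p[order(p$from, p$to), ]
  rownames(p) <- sprintf("q%d%d", p$from, p$to)
  p
}

ms_masks <- list(
  full = character(0),
  weak_differentiation = c("q02", "q03"),
  strong_differentiation = c("q02", "q03", "q13"),
  weak_unification = c("q01", "q02"),
  strong_unification = c("q01", "q02", "q31")
)

#' Build one of the five authority-structure transition models
#'
#' Four-state continuous-time Markov models of the structure of religious
#' and political authority (0 = none, 1 = combined, 2 = partly independent,
#' 3 = independent). The full model frees all 12 ordered transition rates;
#' the differentiation models forbid transitions that skip towards more
#' differentiated states (strong: q02, q03, q13; weak: q02, q03), and the
#' unification models forbid transitions that skip towards less
#' differentiated states (strong: q01, q02, q31; weak: q01, q02).
#'
#' @param name One of \code{"full"}, \code{"weak_differentiation"},
#'   \code{"strong_differentiation"}, \code{"weak_unification"},
#'   \code{"strong_unification"}.
#' @param rates Optional named vector of rates for the free ordered pairs
#'   (names like \code{"q01"}); defaults to 1 for every free rate. Values
#'   supplied for masked pairs are ignored (they are structurally zero).
#' @return An object of class \code{rate_model} with elements \code{name},
#'   \code{mask} (matrix of forbidden from/to states), \code{free} (names of
#'   free pairs), \code{rates}, and the rate matrix \code{Q}.
#' @export
build_rate_model <- function(name, rates = NULL) {
  if (!name %in% names(ms_masks)) {
    stop("unknown model name: ", name, "; valid: ",
         paste(names(ms_masks), collapse = ", "))
  }
  pairs <- ms_pair_names()
  masked <- ms_masks[[name]]
  free <- setdiff(rownames(pairs), masked)
  r <- stats::setNames(rep(1, length(free)), free)
  if (!is.null(rates)) {
    known <- intersect(names(rates), free)
    r[known] <- rates[known]
  }
  if (any(r < 0)) stop("rates must be nonnegative")
  Q <- matrix(0, 4, 4, dimnames = list(ms_states, ms_states))
  for (nm in free) {
    Q[pairs[nm, "from"] + 1L, pairs[nm, "to"] + 1L] <- r[[nm]]
  }
  diag(Q) <- -rowSums(Q)
  mask <- as.matrix(pairs[masked, , drop = FALSE])
  structure(list(name = name, mask = mask, free = free, rates = r,
                 states = ms_states, Q = Q),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("4-state transition model:", x$name, "\n")
  if (nrow(x$mask) > 0) {
    cat("  forbidden:", paste(rownames(x$mask), collapse = ", "), "\n")
  }
  cat("  free rates:", length(x$free), "\n")
  invisible(x)
}

#' CTMC transition probabilities
#'
#' \eqn{P(t) = e^{Qt}}: a stochastic matrix (rows sum to one, entries
#' nonnegative).
#'
#' @param q A \code{\link{rate_model}} or rate matrix.
#' @param t Elapsed time (>= 0).
#' @export
transition_probabilities <- function(q, t) {
  if (t < 0) stop("t must be nonnegative")
  Q <- if (inherits(q, "rate_model")) q$Q else as.matrix(q)
  P <- expm_mat(Q * t)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Log-likelihood of tip states under a CTMC on a tree
#'
#' Felsenstein pruning: post-order partial likelihoods with per-branch
#' transition matrices \eqn{e^{Qt}}, summed at the root against the root
#' state frequencies. Missing states (NA) are treated as fully ambiguous.
#'
#' @param tree A \code{phylo} object.
#' @param states Integer vector of tip states in 0..3, named by tip label
#'   (or in tip order if unnamed); NA = missing.
#' @param q A \code{\link{rate_model}} or rate matrix.
#' @param root_freq Root state frequencies (default uniform).
#' @return Log-likelihood (scalar).
#' @export
pruning_loglik <- function(tree, states, q, root_freq = rep(0.25, 4)) {
  Q <- if (inherits(q, "rate_model")) q$Q else as.matrix(q)
  st <- align_states(tree, states, nrow(Q))
  tp <- ape::reorder.phylo(tree, "postorder")
  cpp_pruning_loglik(tp$edge, tp$edge.length, length(tp$tip.label),
                     st, Q, root_freq)
}

align_states <- function(tree, states, ns = 4) {
  if (!is.null(names(states))) {
    if (!all(tree$tip.label %in% names(states))) {
      stop("states missing for tips: ",
           paste(setdiff(tree$tip.label, names(states)), collapse = ", "))
    }
    states <- states[tree$tip.label]
  }
  if (length(states) != length(tree$tip.label)) {
    stop("states length does not match tip count")
  }
  st <- as.integer(states)
  bad <- !is.na(st) & (st < 0 | st >= ns)
  if (any(bad)) stop("states outside 0..", ns - 1)
  st[is.na(st)] <- -1L
  st
}

# Pack trees + aligned states for the C++ chain.
ms_pack_trees <- function(trees, states) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  lapply(trees, function(tr) {
    tp <- ape::reorder.phylo(tr, "postorder")
    list(edge = tp$edge, elen = tp$edge.length,
         ntip = length(tp$tip.label), states = align_states(tp, states))
  })
}

ms_config_defaults <- function(config = list(), scale = "desk") {
  base <- if (identical(scale, "paper")) {
    list(n_iter = 1e8, burn_frac = 0.1, chains = 3, thin = 1000,
         stones = 100, stone_iter = 1e5, stone_burn = 1e4)
  } else {
    list(n_iter = 1e5, burn_frac = 0.1, chains = 3, thin = 10,
         stones = 20, stone_iter = 2000, stone_burn = 500)
  }
  base$s_joint <- 0.12; base$s_single <- 0.6
  base$root_freq <- rep(0.25, 4)
  base$m_upper <- 10
  utils::modifyList(base, config)
}

#' Fit a constrained multistate model by MCMC
#'
#' Metropolis-within-Gibbs over the free transition rates, with the prior
#' \eqn{rate_j \sim Exp(mean = m)}, \eqn{m \sim Uniform(0, 10)}, and
#' phylogenetic uncertainty handled by sampling the tree index (uniform
#' prior over the supplied sample, Metropolis move). Runs independent
#' replicate chains (default 3).
#'
#' @param trees \code{multiPhylo}/\code{phylo} tree sample.
#' @param states Named tip states 0..3 (see \code{\link{pruning_loglik}}).
#' @param model A \code{\link{rate_model}} or model name.
#' @param config List of sampler settings: \code{n_iter}, \code{burn_frac},
#'   \code{chains}, \code{thin}, \code{root_freq}, proposal scales; see
#'   source for desk defaults (100,000 iterations, 10\% burn-in, 3 chains).
#' @param scale \code{"desk"} (default) or \code{"paper"} preset.
#' @param seed Integer seed.
#' @return Object of class \code{coevauth_ms_fit}: per-chain rate draws,
#'   hyperprior draws, log-likelihood traces, R-hat/ESS per rate, and a
#'   convergence flag.
#' @export
fit_multistate_mcmc <- function(trees, states, model, config = list(),
                                scale = "desk", seed = 1) {
  if (is.character(model)) model <- build_rate_model(model)
  cfg <- ms_config_defaults(config, scale)
  obs <- stats::na.omit(as.integer(states))
  if (length(unique(obs)) < 2) stop("need >= 2 distinct observed states")
  packed <- ms_pack_trees(trees, states)
  pairs <- ms_pair_names()
  fidx <- as.matrix(pairs[model$free, , drop = FALSE])
  burn <- floor(cfg$n_iter * cfg$burn_frac)
  chains <- vector("list", cfg$chains)
  for (ch in seq_len(cfg$chains)) {
    set.seed(seed + 7919L * (ch - 1L))
    init <- stats::rexp(length(model$free), 1)
    res <- cpp_ms_chain(packed, fidx, init, init_m = stats::runif(1, 0.5, 5),
                        root_freq = cfg$root_freq, beta = 1,
                        n_iter = cfg$n_iter, burn = burn, thin = cfg$thin,
                        s_joint = cfg$s_joint, s_single = cfg$s_single,
                        m_upper = cfg$m_upper, ns = 4)
    colnames(res$rates) <- model$free
    chains[[ch]] <- res
  }
  rate_draws <- lapply(chains, `[[`, "rates")
  diag_tab <- data.frame(parameter = model$free,
                         median = NA_real_, hpdi_low = NA_real_,
                         hpdi_high = NA_real_, rhat = NA_real_,
                         ess = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_along(model$free)) {
    per_chain <- sapply(rate_draws, function(m) m[, j])
    pooled <- as.numeric(per_chain)
    s <- summarize_draws(pooled, chains = per_chain)
    diag_tab[j, -1] <- c(s$median, s$hpdi_low, s$hpdi_high, s$rhat, s$ess)
  }
  converged <- all(is.finite(diag_tab$rhat)) && all(diag_tab$rhat <= 1.05)
  structure(list(model = model, chains = chains, summary = diag_tab,
                 converged = converged, config = cfg, seed = seed),
            class = "coevauth_ms_fit")
}

#' @export
print.coevauth_ms_fit <- function(x, ...) {
  cat("Multistate CTMC fit:", x$model$name, "model,",
      length(x$chains), "chains x",
      nrow(x$chains[[1]]$rates), "kept draws\n")
  cat("  converged (all R-hat <= 1.05):", x$converged, "\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
summary.coevauth_ms_fit <- function(object, ...) object$summary

#' @export
coef.coevauth_ms_fit <- function(object, ...) {
  stats::setNames(object$summary$median, object$summary$parameter)
}

#' Stepping-stone log marginal likelihood of a multistate model
#'
#' Power-posterior path with K stones at powers \eqn{\beta_k = (k/K)^{1/0.3}}
#' (Beta(0.3, 1) quantiles), one Metropolis chain per stone warm-started
#' from the previous stone, and the log-sum-exp stepping-stone identity.
#' Desk defaults: K = 20 stones, 2,000 sampled iterations per stone.
#'
#' @inheritParams fit_multistate_mcmc
#' @return List: \code{logml}, \code{betas}, per-stone acceptance.
#' @export
stepping_stone_logml <- function(trees, states, model, config = list(),
                                 scale = "desk", seed = 1) {
  if (is.character(model)) model <- build_rate_model(model)
  cfg <- ms_config_defaults(config, scale)
  packed <- ms_pack_trees(trees, states)
  pairs <- ms_pair_names()
  fidx <- as.matrix(pairs[model$free, , drop = FALSE])
  K <- cfg$stones
  betas <- (seq(0, K) / K)^(1 / 0.3)
  set.seed(seed)
  rates <- stats::rexp(length(model$free), 1)
  m <- stats::runif(1, 0.5, 5)
  logml <- 0
  acc <- numeric(K)
  for (k in seq_len(K)) {
    res <- cpp_ms_chain(packed, fidx, rates, init_m = m,
                        root_freq = cfg$root_freq, beta = betas[k],
                        n_iter = cfg$stone_burn + cfg$stone_iter,
                        burn = cfg$stone_burn, thin = 1,
                        s_joint = cfg$s_joint, s_single = cfg$s_single,
                        m_upper = cfg$m_upper, ns = 4)
    dbeta_k <- betas[k + 1] - betas[k]
    logml <- logml + log_mean_exp(dbeta_k * res$loglik)
    nlast <- nrow(res$rates)
    rates <- as.numeric(res$rates[nlast, ])
    m <- res$m[nlast]
    acc[k] <- res$accept
  }
  list(logml = logml, betas = betas, accept = acc, model = model$name)
}

#' Compare models by log Bayes factors
#'
#' Pairwise \eqn{2\ln BF = 2(\log ML_a - \log ML_b)} from stepping-stone log
#' marginal likelihoods, labelled on the conventional evidence scale
#' (0-2 'not worth more than a bare mention', 2-6 'positive evidence',
#' 6-10 'strong evidence', >= 10 'very strong evidence').
#'
#' @param logml Named numeric vector of log marginal likelihoods (>= 2).
#' @return Object of class \code{ms_model_comparison}: antisymmetric
#'   \code{bf2ln} matrix and a \code{labels} character matrix.
#' @export
compare_models <- function(logml) {
  if (length(logml) < 2) stop("need at least 2 models")
  nm <- names(logml)
  if (is.null(nm)) nm <- paste0("model", seq_along(logml))
  bf <- 2 * outer(logml, logml, `-`)
  dimnames(bf) <- list(nm, nm)
  labels <- matrix(bf_label(abs(bf)), nrow(bf), dimnames = dimnames(bf))
  structure(list(logml = stats::setNames(as.numeric(logml), nm),
                 bf2ln = bf, labels = labels),
            class = "ms_model_comparison")
}

bf_label <- function(x) {
  cut(x, breaks = c(-Inf, 2, 6, 10, Inf), right = FALSE,
      labels = c("not worth more than a bare mention", "positive evidence",
                 "strong evidence", "very strong evidence"))
}

#' @export
print.ms_model_comparison <- function(x, ...) {
  cat("Log marginal likelihoods:\n")
  print(round(x$logml, 2))
  cat("\n2 ln BF (row vs column):\n")
  print(round(x$bf2ln, 2))
  invisible(x)
}

#' Maximum-likelihood rates by multistart optimization
#'
#' Best of \code{attempts} bounded optimizations of the pruning
#' log-likelihood over the free rates (log scale, L-BFGS-B), used to
#' sanity-check prior ranges.
#'
#' @param tree A \code{phylo}.
#' @param states Tip states (see \code{\link{pruning_loglik}}).
#' @param model A \code{\link{rate_model}} or name.
#' @param attempts Number of random restarts (>= 1).
#' @param seed Integer seed (same seed, same result).
#' @return List: \code{rates} (named), \code{logL}, \code{attempts_used}.
#' @export
max_likelihood_fit <- function(tree, states, model, attempts = 100, seed = 1) {
  if (attempts < 1) stop("attempts must be >= 1")
  if (is.character(model)) model <- build_rate_model(model)
  st <- align_states(tree, states)
  tp <- ape::reorder.phylo(tree, "postorder")
  pairs <- ms_pair_names()
  fidx <- as.matrix(pairs[model$free, , drop = FALSE])
  negll <- function(lr) {
    Q <- matrix(0, 4, 4)
    Q[fidx + 1L] <- exp(lr)
    diag(Q) <- -rowSums(Q)
    -cpp_pruning_loglik(tp$edge, tp$edge.length, length(tp$tip.label), st, Q,
                        rep(0.25, 4))
  }
  set.seed(seed)
  best <- NULL
  fails <- 0L
  for (a in seq_len(attempts)) {
    init <- stats::rnorm(length(model$free), 0, 1.5)
    res <- tryCatch(
      stats::optim(init, negll, method = "L-BFGS-B",
                   lower = log(1e-8), upper = log(1e3)),
      error = function(e) NULL)
    if (is.null(res)) { fails <- fails + 1L; next }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all ", attempts, " optimization attempts failed")
  list(rates = stats::setNames(exp(best$par), model$free),
       logL = -best$value, attempts_used = attempts - fails)
}
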