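#' Ornstein-Uhlenbeck parameter set
#'
#' Bundles the parameters of the latent bivariate (generally D-variate)
#' OU process \eqn{d\eta = (A\eta + b)\,dt + S\,dW}: the selection matrix
#' \code{A} (strictly negative diagonal = autoregressive selection towards the
#' equilibrium, off-diagonals = cross-trait selection), the drift intercept
#' \code{b}, the diffusion scale \code{S} (fixed to the identity for
#' identifiability unless supplied), per-trait ordinal cutpoints (ordered
#' triples; the middle cutpoint is anchored at 0 in the fitted model), and a
#' spatial Gaussian-process kernel (squared-exponential on great-circle km)
#' per trait.
#'
#' @param A D x D selection matrix; all eigenvalues must have negative real
#'   part (mean reversion).
#' @param b Length-D drift intercept.
#' @param S D x D diffusion scale (defaults to identity).
#' @param cutpoints List of ordered numeric triples, one per trait, or NULL.
#' @param gp_amplitude,gp_lengthscale Per-trait GP amplitude (latent scale)
#'   and lengthscale (km); amplitude 0 disables the spatial term.
#' @return An object of class \code{ou_params}.
#' @export
ou_params <- function(A, b = rep(0, nrow(A)), S = diag(nrow(A)),
                      cutpoints = NULL, gp_amplitude = rep(0, nrow(A)),
                      gp_lengthscale = rep(1000, nrow(A))) {
  A <- as.matrix(A)
  D <- nrow(A)
  stopifnot(ncol(A) == D, length(b) == D)
  if (!is_stable(A)) stop("selection matrix not mean-reverting")
  if (!is.null(cutpoints)) {
    cutpoints <- lapply(cutpoints, as.numeric)
    for (cp in cutpoints) {
      if (length(cp) != 3L || any(diff(cp) <= 0)) {
        stop("cutpoints must be strictly increasing triples")
      }
    }
  }
  if (any(gp_amplitude < 0) || any(gp_lengthscale <= 0)) {
    stop("gp parameters must be nonnegative (lengthscale positive)")
  }
  structure(list(A = A, b = as.numeric(b), S = as.matrix(S),
                 cutpoints = cutpoints, gp_amplitude = gp_amplitude,
                 gp_lengthscale = gp_lengthscale, D = D),
            class = "ou_params")
}

is_stable <- function(A) all(Re(eigen(A, only.values = TRUE)$values) < 0)

# Matrix exponential: eigendecomposition fast path, Pade scaling-squaring
# (Matrix::expm) fallback when the eigenbasis is ill-conditioned (defective
# or near-defective generators, e.g. constrained rate matrices with
# repeated eigenvalues).
expm_mat <- function(A) {
  eg <- tryCatch(eigen(A), error = function(e) NULL)
  if (!is.null(eg)) {
    sv <- svd(eg$vectors, nu = 0, nv = 0)$d
    if (sv[length(sv)] / sv[1] > 1e-8) {
      out <- eg$vectors %*% (exp(eg$values) * solve(eg$vectors))
      return(Re(out))
    }
  }
  as.matrix(Matrix::expm(Matrix::Matrix(A)))
}

#' Exact Gaussian OU transition moments along a branch
#'
#' For the process \eqn{d\eta = (A\eta + b)dt + S dW} over time \code{t}, the
#' child state given the parent state \eqn{\eta_0} is Gaussian with mean
#' \eqn{M\eta_0 + m} and covariance \eqn{V}, where \eqn{M = e^{At}},
#' \eqn{m = A^{-1}(M - I)b}, and \eqn{vec(V) = (A \oplus A)^{-1}
#' (e^{(A \oplus A)t} - I)\, vec(SS^\top)} with \eqn{\oplus} the Kronecker
#' sum. For a stable \code{A} the Kronecker sum is nonsingular; a series
#' expansion handles very small \code{t} where the exponential difference
#' loses precision.
#'
#' @param params An \code{\link{ou_params}} object.
#' @param t Branch length (nonnegative).
#' @return List with matrix \code{M}, vector \code{m}, covariance \code{V}.
#' @export
ou_transition <- function(params, t) {
  stopifnot(inherits(params, "ou_params"), t >= 0)
  A <- params$A; b <- params$b; D <- params$D
  SSt <- params$S %*% t(params$S)
  if (t == 0) {
    return(list(M = diag(D), m = rep(0, D), V = matrix(0, D, D)))
  }
  M <- expm_mat(A * t)
  m <- as.numeric(solve(A, (M - diag(D)) %*% b))
  K <- kronecker(diag(D), A) + kronecker(A, diag(D))
  if (t < 1e-8) {
    # (e^{Kt} - I) K^{-1} ~ tI + t^2 K / 2 for small t
    Vv <- (diag(D * D) * t + K * t^2 / 2) %*% as.numeric(SSt)
  } else {
    Vv <- solve(K, (expm_mat(K * t) - diag(D * D)) %*% as.numeric(SSt))
  }
  V <- matrix(as.numeric(Vv), D, D)
  V <- (V + t(V)) / 2
  list(M = M, m = m, V = V)
}

#' Stationary moments of the OU process
#'
#' The equilibrium trait value \eqn{\theta^* = -A^{-1}b} and the stationary
#' covariance \eqn{V_\infty} solving the Lyapunov equation
#' \eqn{A V + V A^\top + S S^\top = 0}.
#'
#' @param params An \code{\link{ou_params}} object.
#' @return List with \code{theta_star} and \code{V_inf}.
#' @export
stationary_moments <- function(params) {
  stopifnot(inherits(params, "ou_params"))
  A <- params$A; D <- params$D
  SSt <- params$S %*% t(params$S)
  theta <- as.numeric(-solve(A, params$b))
  K <- kronecker(diag(D), A) + kronecker(A, diag(D))
  V <- matrix(as.numeric(-solve(K, as.numeric(SSt))), D, D)
  V <- (V + t(V)) / 2
  list(theta_star = theta, V_inf = V)
}

# Fast per-branch OU transition generator. For D <= 2 the stationary
# identity V(t) = V_inf - e^{At} V_inf e^{A^T t} and the closed-form
# exponential avoid per-branch Kronecker solves; higher D falls back to
# ou_transition. Agrees with ou_transition to numerical precision.
make_ou_transition_fn <- function(params, st = stationary_moments(params)) {
  A <- params$A; b <- params$b; D <- params$D
  if (D > 2) return(function(t) ou_transition(params, t))
  Vinf <- st$V_inf
  Aib <- as.numeric(solve(A, b))
  AV <- A %*% Vinf; VA <- Vinf %*% t(A); AVA <- tcrossprod(AV, A)
  function(t) {
    ab <- ou_alpha_beta(A, t)
    M <- diag(ab$alpha, D) + ab$beta * A
    m <- (ab$alpha - 1) * Aib + ab$beta * b
    V <- Vinf - (ab$alpha^2 * Vinf + ab$alpha * ab$beta * (AV + VA) +
                   ab$beta^2 * AVA)
    list(M = M, m = m, V = (V + t(V)) / 2)
  }
}

# Closed-form matrix exponential coefficients for D <= 2:
# e^{At} = alpha(t) I + beta(t) A, exact for all 2x2 A including defective
# (repeated-eigenvalue) selection matrices; vectorized over t (vector or
# matrix). For 1x1, beta = 0 and alpha = exp(a t).
ou_alpha_beta <- function(A, t) {
  if (nrow(A) == 1L) {
    return(list(alpha = exp(A[1, 1] * t), beta = t * 0))
  }
  mu <- (A[1, 1] + A[2, 2]) / 2
  disc <- (A[1, 1] - A[2, 2])^2 / 4 + A[1, 2] * A[2, 1]
  emu <- exp(mu * t)
  q <- sqrt(abs(disc))
  x <- disc * t^2
  small <- abs(x) < 1e-10
  if (disc > 0) {
    c_ <- cosh(q * t); f <- sinh(q * t) / q
  } else if (disc < 0) {
    c_ <- cos(q * t); f <- sin(q * t) / q
  } else {
    c_ <- t * 0 + 1; f <- t
  }
  c_[small] <- 1 + x[small] / 2
  f[small] <- t[small] * (1 + x[small] / 6)
  list(alpha = emu * (c_ - mu * f), beta = emu * f)
}

# Pairwise covariance blocks F(t1, t2) = e^{A t1} V e^{A^T t2}, evaluated
# elementwise over matching arrays t1, t2. Returns a list of D^2 arrays
# indexed (e-1)*D + d (block row d, block column e).
ou_pair_blocks <- function(A, V, T1, T2) {
  D <- nrow(A)
  if (D <= 2) {
    ab1 <- ou_alpha_beta(A, T1)
    ab2 <- ou_alpha_beta(A, T2)
    AV <- A %*% V; VA <- V %*% t(A); AVA <- A %*% V %*% t(A)
    out <- vector("list", D * D)
    for (d in seq_len(D)) for (e in seq_len(D)) {
      out[[(e - 1) * D + d]] <-
        ab1$alpha * ab2$alpha * V[d, e] + ab1$alpha * ab2$beta * VA[d, e] +
        ab1$beta * ab2$alpha * AV[d, e] + ab1$beta * ab2$beta * AVA[d, e]
    }
    return(out)
  }
  eg <- eigen(A)
  U <- eg$vectors; Ui <- solve(U); lam <- eg$values
  G <- Ui %*% V %*% t(Ui)
  out <- vector("list", D * D)
  for (d in seq_len(D)) for (e in seq_len(D)) {
    Fde <- T1 * 0i
    for (k in seq_len(D)) for (l in seq_len(D)) {
      Fde <- Fde + (U[d, k] * G[k, l] * U[e, l]) *
        exp(lam[k] * T1) * exp(lam[l] * T2)
    }
    out[[(e - 1) * D + d]] <- Re(Fde)
  }
  out
}

assemble_blocks <- function(bl, D, nr, nc) {
  S <- matrix(0, D * nr, D * nc)
  for (d in seq_len(D)) for (e in seq_len(D)) {
    S[(d - 1) * nr + seq_len(nr), (e - 1) * nc + seq_len(nc)] <-
      bl[[(e - 1) * D + d]]
  }
  S
}

# Joint Gaussian moments of the tip latents under the tree-structured OU.
#
# With the root drawn from the stationary distribution every node is
# marginally stationary and Cov(eta_i, eta_j) = e^{A t_i} V_inf e^{A^T t_j},
# with t_i, t_j the times from the pair's MRCA; this marginalizes all
# internal nodes exactly. Ordering of the returned moments is trait-major:
# (trait 1 over tips, trait 2 over tips, ...).
#
# mode = "fixed" conditions on a known root value instead.
ou_tip_moments <- function(tree, params, mode = c("stationary", "fixed"),
                           root_value = NULL) {
  mode <- match.arg(mode)
  A <- params$A; D <- params$D
  n <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree)                       # n x n node ids
  d_a <- matrix(depths[mr], n, n)
  Ti <- outer(depths[seq_len(n)], rep(1, n)) - d_a
  Tj <- t(Ti)
  st <- stationary_moments(params)
  if (mode == "stationary") {
    mu <- rep(st$theta_star, each = n)
    blocks <- ou_pair_blocks(A, st$V_inf, Ti, Tj)
  } else {
    if (is.null(root_value)) stop("root_value required for fixed-root mode")
    # mean: M(d_i) root + m(d_i); covariance uses branch variance V(d_a)
    mu <- matrix(0, n, D)
    for (i in seq_len(n)) {
      tr <- ou_transition(params, depths[i])
      mu[i, ] <- as.numeric(tr$M %*% root_value + tr$m)
    }
    mu <- as.numeric(mu)                      # trait-major via column stacking
    blocks <- rep(list(matrix(0, n, n)), D * D)
    for (a in unique(as.numeric(mr))) {
      Va <- ou_transition(params, depths[a])$V
      idx <- which(mr == a)
      sub <- ou_pair_blocks(A, Va, Ti[idx], Tj[idx])
      for (j in seq_len(D * D)) blocks[[j]][idx] <- sub[[j]]
    }
  }
  Sigma <- assemble_blocks(blocks, D, n, n)
  Sigma <- (Sigma + t(Sigma)) / 2
  list(mean = mu, Sigma = Sigma, tip_order = tree$tip.label)
}

#' Phase plane of the fitted selection field
#'
#' Evaluates the deterministic drift \eqn{d\eta/dt = b + A\eta} on a grid of
#' latent coordinates; the field vanishes at the equilibrium
#' \eqn{\theta^* = -A^{-1}b}. Cutpoint lines mark the ordinal category
#' boundaries on each axis.
#'
#' @param params An \code{\link{ou_params}} object (D = 2).
#' @param grid_bounds Numeric length-4: (lo1, hi1, lo2, hi2).
#' @param grid_n Grid points per axis.
#' @return Object of class \code{phase_plane}: data.frame \code{grid} with
#'   columns x, y, dx, dy; \code{theta_star}; \code{cutpoints}.
#' @export
phase_plane <- function(params, grid_bounds = c(-3, 3, -3, 3), grid_n = 15) {
  stopifnot(inherits(params, "ou_params"), params$D == 2)
  gx <- seq(grid_bounds[1], grid_bounds[2], length.out = grid_n)
  gy <- seq(grid_bounds[3], grid_bounds[4], length.out = grid_n)
  grid <- expand.grid(x = gx, y = gy)
  f <- t(params$A %*% t(as.matrix(grid))) +
    matrix(params$b, nrow(grid), 2, byrow = TRUE)
  grid$dx <- f[, 1]; grid$dy <- f[, 2]
  structure(list(grid = grid,
                 theta_star = stationary_moments(params)$theta_star,
                 cutpoints = params$cutpoints),
            class = "phase_plane")
}

#' @export
plot.phase_plane <- function(x, scale = 0.15, ...) {
  g <- x$grid
  graphics::plot(g$x, g$y, type = "n", xlab = "latent trait 1",
                 ylab = "latent trait 2", ...)
  graphics::arrows(g$x, g$y, g$x + scale * g$dx, g$y + scale * g$dy,
                   length = 0.04, col = "grey50")
  graphics::points(x$theta_star[1], x$theta_star[2], pch = 19, col = "red")
  if (!is.null(x$cutpoints)) {
    graphics::abline(v = x$cutpoints[[1]], lty = 2, col = "grey70")
    graphics::abline(h = x$cutpoints[[2]], lty = 2, col = "grey70")
  }
  invisible(x)
}
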