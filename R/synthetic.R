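#' Simulate an ultrametric birth-death tree
#'
#' Birth-death tree conditioned on the number of surviving tips (via
#' \code{ape::rphylo}), rescaled so the root-to-tip depth is 1 by default so
#' that OU rates are comparable across replicates.
#'
#' @param n_tips Number of extant tips (>= 4).
#' @param birth_rate,death_rate Per-lineage rates; \code{birth_rate >
#'   death_rate >= 0}.
#' @param seed Integer seed; identical seeds give byte-identical trees.
#' @param rescale_depth Target root depth, or \code{NULL} to keep the
#'   simulated time scale.
#' @param max_retry Bounded retries if conditioning fails.
#' @return A \code{phylo} object.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, death_rate = 0, seed = 1,
                          rescale_depth = 1, max_retry = 50) {
  if (n_tips < 4) stop("n_tips must be >= 4")
  if (!(birth_rate > death_rate && death_rate >= 0)) {
    stop("need birth_rate > death_rate >= 0")
  }
  set.seed(seed)
  for (i in seq_len(max_retry)) {
    tr <- tryCatch(ape::rphylo(n_tips, birth_rate, death_rate),
                   error = function(e) NULL)
    if (!is.null(tr) && length(tr$tip.label) == n_tips) {
      if (!is.null(rescale_depth)) {
        depth <- max(ape::node.depth.edgelength(tr))
        tr$edge.length <- tr$edge.length * rescale_depth / depth
      }
      return(tr)
    }
  }
  stop("could not simulate a tree with ", n_tips, " tips after ",
       max_retry, " retries")
}

#' Simulate society coordinates
#'
#' Uniform draws in a lat/lon box. Longitudes may exceed 180 to express
#' boxes crossing the antimeridian (Pacific-style); sampled values are
#' wrapped back into [-180, 180].
#'
#' @param n Number of points.
#' @param geo_box Numeric (lat_min, lat_max, lon_min, lon_max).
#' @param seed Integer seed.
#' @return Matrix with columns lat, lon.
#' @export
simulate_coords <- function(n, geo_box = c(-45, 25, 95, 230), seed = 1) {
  if (geo_box[2] < geo_box[1] || geo_box[4] < geo_box[3]) {
    stop("degenerate geo_box")
  }
  set.seed(seed)
  lat <- stats::runif(n, geo_box[1], geo_box[2])
  lon <- stats::runif(n, geo_box[3], geo_box[4])
  lon <- ((lon + 180) %% 360) - 180
  cbind(lat = lat, lon = lon)
}

#' Map latent values to ordinal categories
#'
#' With \code{noise = "none"}, returns the category k such that
#' \eqn{c_k < latent \le c_{k+1}} (with \eqn{c_0 = -\infty},
#' \eqn{c_4 = +\infty}). With \code{noise = "probit"}, the category is drawn
#' with \eqn{P(k) = \Phi(c_{k+1} - latent) - \Phi(c_k - latent)}, i.e. unit
#' Gaussian observation noise is added before thresholding.
#'
#' @param latent Numeric vector of latent values.
#' @param cutpoints Strictly increasing numeric triple.
#' @param noise \code{"none"} or \code{"probit"}.
#' @return Integer vector with values in 0..3.
#' @export
ordinalize <- function(latent, cutpoints, noise = c("none", "probit")) {
  noise <- match.arg(noise)
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) != 3L || any(diff(cutpoints) <= 0)) {
    stop("cutpoints must be a strictly increasing triple")
  }
  x <- if (noise == "probit") latent + stats::rnorm(length(latent)) else latent
  findInterval(x, cutpoints, left.open = TRUE)
}

#' Simulate coevolving ordinal traits on a tree
#'
#' Forward simulation of the dynamic coevolutionary model: the root latent
#' pair is drawn from the OU stationary distribution, child latents from the
#' exact Gaussian OU transition along each branch, tip latents are augmented
#' with a draw from the spatial Gaussian process (squared-exponential kernel
#' on great-circle km, independently per trait), and ordinal categories are
#' produced by probit thresholding at the cutpoints.
#'
#' @param tree A \code{phylo} object.
#' @param ou An \code{\link{ou_params}} object with cutpoints set.
#' @param coords Matrix of (lat, lon) per tip, in tip-label order; may be
#'   \code{NULL} when all GP amplitudes are zero.
#' @param seed Integer seed.
#' @return List: \code{latents} (n x D matrix of tip OU latents),
#'   \code{spatial} (n x D matrix of GP effects), \code{ordinal} (n x D
#'   integer matrix, values 0..3), \code{node_latents} (latents for internal
#'   nodes), rownames = tip labels.
#' @export
simulate_coevolution <- function(tree, ou, coords = NULL, seed = 1) {
  stopifnot(inherits(ou, "ou_params"))
  if (is.null(ou$cutpoints)) stop("ou_params must carry cutpoints")
  if (!is_stable(ou$A)) stop("selection matrix not mean-reverting")
  set.seed(seed)
  D <- ou$D
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  st <- stationary_moments(ou)
  lat_all <- matrix(NA_real_, nn, D)
  root <- n + 1L
  lat_all[root, ] <- st$theta_star +
    as.numeric(chol_psd(st$V_inf) %*% stats::rnorm(D))
  # pre-order traversal over edges (ape edge matrices are not guaranteed
  # pre-ordered; reorder explicitly)
  tre <- ape::reorder.phylo(tree, "cladewise")
  trans_of <- make_ou_transition_fn(ou, st)
  for (k in seq_len(nrow(tre$edge))) {
    par <- tre$edge[k, 1]; chd <- tre$edge[k, 2]
    tr <- trans_of(tre$edge.length[k])
    lat_all[chd, ] <- as.numeric(tr$M %*% lat_all[par, ]) + tr$m +
      as.numeric(chol_psd(tr$V) %*% stats::rnorm(D))
  }
  latents <- lat_all[seq_len(n), , drop = FALSE]
  spatial <- matrix(0, n, D)
  if (any(ou$gp_amplitude > 0)) {
    if (is.null(coords)) stop("coords required when gp_amplitude > 0")
    Dkm <- great_circle_distances(coords)
    for (d in seq_len(D)) {
      if (ou$gp_amplitude[d] > 0) {
        Kd <- ou$gp_amplitude[d]^2 *
          exp(-Dkm^2 / (2 * ou$gp_lengthscale[d]^2))
        spatial[, d] <- as.numeric(chol_psd(Kd) %*% stats::rnorm(n))
      }
    }
  }
  liab <- latents + spatial
  ordinal <- matrix(NA_integer_, n, D)
  for (d in seq_len(D)) {
    ordinal[, d] <- ordinalize(liab[, d], ou$cutpoints[[d]], noise = "probit")
  }
  rownames(latents) <- rownames(spatial) <- rownames(ordinal) <- tree$tip.label
  list(latents = latents, spatial = spatial, ordinal = ordinal,
       node_latents = lat_all[(n + 1L):nn, , drop = FALSE])
}

# Cholesky-like factor of a PSD matrix (eigenvalue clipping), for sampling.
chol_psd <- function(M) {
  if (all(abs(M) < 1e-300)) return(M * 0)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  eg$vectors %*% (sqrt(ev) * t(eg$vectors))
}

#' Simulate a discrete character on a tree by exact CTMC simulation
#'
#' The root state is drawn from \code{root_freq}; along each branch the state
#' evolves by Gillespie jump simulation under the rate matrix of
#' \code{model}, so forbidden transitions can never be realized.
#'
#' @param tree A \code{phylo} object.
#' @param model A \code{\link{rate_model}} (or its Q matrix).
#' @param root_freq Length-4 probability vector over states 0..3.
#' @param seed Integer seed.
#' @return Named integer vector of tip states (0..3).
#' @export
simulate_multistate <- function(tree, model, root_freq = rep(0.25, 4),
                                seed = 1) {
  Q <- if (inherits(model, "rate_model")) model$Q else as.matrix(model)
  ns <- nrow(Q)
  if (any(Q[row(Q) != col(Q)] < 0) || any(abs(rowSums(Q)) > 1e-8)) {
    stop("invalid rate matrix")
  }
  set.seed(seed)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  states <- integer(nn)
  states[n + 1L] <- sample.int(ns, 1, prob = root_freq) - 1L
  tre <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(tre$edge))) {
    par <- tre$edge[k, 1]; chd <- tre$edge[k, 2]
    s <- states[par]
    t_left <- tre$edge.length[k]
    repeat {
      rate <- -Q[s + 1L, s + 1L]
      if (rate <= 0) break
      dt <- stats::rexp(1, rate)
      if (dt > t_left) break
      t_left <- t_left - dt
      p <- Q[s + 1L, ]; p[s + 1L] <- 0
      s <- sample.int(ns, 1, prob = p) - 1L
    }
    states[chd] <- s
  }
  out <- states[seq_len(n)]
  names(out) <- tree$tip.label
  out
}

#' Simulate data under the bivariate ordinal signal model
#'
#' Generates two ordinal traits with phylogenetic liabilities
#' \eqn{a \sim N(0, B \otimes C)} (C = tree correlation, B built from
#' per-trait phylogenetic variances and the phylogenetic correlation), unit
#' residual liabilities with correlation \code{rho_resid}, and thresholding
#' at the cutpoints.
#'
#' @param tree A \code{phylo} object.
#' @param sigma2_phylo Length-2 phylogenetic variances (liability scale).
#' @param rho_phylo,rho_resid Correlations in [-1, 1].
#' @param cutpoints List of two ordered triples.
#' @param seed Integer seed.
#' @return List: \code{ordinal} (n x 2), \code{liability} (n x 2),
#'   \code{lambda_true} (length 2).
#' @export
simulate_signal_data <- function(tree, sigma2_phylo = c(1.5, 1.5),
                                 rho_phylo = 0.8, rho_resid = 0.2,
                                 cutpoints = list(c(-1.2, 0, 1.2),
                                                  c(-1.2, 0, 1.2)),
                                 seed = 1) {
  set.seed(seed)
  n <- length(tree$tip.label)
  C <- phylo_corr(tree)
  sd1 <- sqrt(sigma2_phylo[1]); sd2 <- sqrt(sigma2_phylo[2])
  B <- matrix(c(sigma2_phylo[1], sd1 * sd2 * rho_phylo,
                sd1 * sd2 * rho_phylo, sigma2_phylo[2]), 2, 2)
  a <- matrix(0, n, 2)
  if (any(sigma2_phylo > 0)) {
    a_vec <- as.numeric(chol_psd(kronecker(B, C)) %*% stats::rnorm(2 * n))
    a <- matrix(a_vec, n, 2)        # trait-major stacking -> columns
  }
  R <- matrix(c(1, rho_resid, rho_resid, 1), 2, 2)
  e <- matrix(stats::rnorm(2 * n), n, 2) %*% chol(R)
  z <- a + e
  y <- cbind(ordinalize(z[, 1], cutpoints[[1]], "none"),
             ordinalize(z[, 2], cutpoints[[2]], "none"))
  rownames(y) <- rownames(z) <- tree$tip.label
  list(ordinal = y, liability = z,
       lambda_true = sigma2_phylo / (sigma2_phylo + 1))
}

# Tree correlation matrix: Brownian vcv normalized by its maximum diagonal,
# so lambda is invariant to overall branch-length rescaling.
phylo_corr <- function(tree) {
  C <- phylo_vcv(tree)
  C / max(diag(C))
}

#' Generate a complete synthetic dataset
#'
#' One seeded draw of everything the pipeline consumes: an ultrametric tree,
#' society coordinates, two coevolving ordinal authority traits from the OU
#' generator, and a four-state authority-structure trait from a CTMC. The
#' default parameters are the fixed conditions of the parameter-recovery
#' study (cross-trait selection of political on religious authority set to
#' 0.8, unit autoregressive selection, unit-depth trees).
#'
#' @param n_tips Number of societies/tips.
#' @param seed Integer seed.
#' @param ou An \code{\link{ou_params}} truth; default is the recovery-study
#'   configuration.
#' @param q_model A \code{\link{rate_model}} truth for the structure trait.
#' @param root_freq CTMC root frequencies.
#' @param birth_rate,death_rate Tree simulator rates.
#' @param geo_box Coordinate box.
#' @return Object of class \code{synthetic_dataset}: \code{tree},
#'   \code{society_table} (data.frame with columns society, taxon, lat, lon,
#'   political_authority, religious_authority, authority_structure),
#'   \code{latents}, \code{truth}.
#' @export
synthetic_dataset <- function(n_tips = 97, seed = 1,
                              ou = default_ou_truth(),
                              q_model = default_ctmc_truth(),
                              root_freq = rep(0.25, 4),
                              birth_rate = 1, death_rate = 0,
                              geo_box = c(-45, 25, 95, 230)) {
  tree <- simulate_tree(n_tips, birth_rate, death_rate, seed = seed)
  coords <- simulate_coords(n_tips, geo_box, seed = seed + 1000L)
  rownames(coords) <- tree$tip.label
  coev <- simulate_coevolution(tree, ou, coords, seed = seed + 2000L)
  struct <- simulate_multistate(tree, q_model, root_freq, seed = seed + 3000L)
  tab <- data.frame(
    society = sprintf("SOC%03d", seq_len(n_tips)),
    taxon = tree$tip.label,
    lat = coords[, "lat"], lon = coords[, "lon"],
    political_authority = coev$ordinal[, 1],
    religious_authority = coev$ordinal[, 2],
    authority_structure = as.integer(struct),
    stringsAsFactors = FALSE)
  structure(list(tree = tree, society_table = tab, latents = coev$latents,
                 spatial = coev$spatial,
                 truth = list(ou = ou, q = q_model, seed = seed)),
            class = "synthetic_dataset")
}

#' Recovery-study OU truth
#'
#' The fixed selection/drift configuration of the simulation study: unit
#' autoregressive selection, cross-trait selection of 0.8 in one direction
#' and 0 in the other, zero drift intercept, identity diffusion, cutpoints
#' (-1, 0, 1), spatial GP off.
#' @param a12 Cross-trait selection of trait 2 on trait 1.
#' @param a21 Cross-trait selection of trait 1 on trait 2.
#' @export
default_ou_truth <- function(a12 = 0.8, a21 = 0) {
  ou_params(A = matrix(c(-1, a21, a12, -1), 2, 2),
            b = c(0, 0),
            cutpoints = list(c(-1, 0, 1), c(-1, 0, 1)))
}

#' Recovery-study CTMC truth (strong differentiation)
#'
#' Forward (differentiating) transitions at rate 2, direct reversals at rate
#' 1, skip-down reversals at rate 0.5, on unit-depth trees; the three
#' forbidden differentiation-skipping transitions are structurally zero.
#' @export
default_ctmc_truth <- function() {
  build_rate_model("strong_differentiation",
                   rates = c(q01 = 2, q10 = 1, q12 = 2, q20 = 0.5,
                             q21 = 1, q23 = 2, q30 = 0.5, q31 = 0.5,
                             q32 = 1))
}

#' Write a synthetic dataset to plain-text files
#'
#' Society table as CSV, tree as Newick, and a JSON manifest recording the
#' seed and true parameters.
#'
#' @param dataset A \code{synthetic_dataset}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_csv <- file.path(dir, "society_table.csv")
  p_tre <- file.path(dir, "tree.nwk")
  p_man <- file.path(dir, "manifest.json")
  utils::write.csv(dataset$society_table, p_csv, row.names = FALSE)
  write_trees(dataset$tree, p_tre, format = "newick")
  tr <- dataset$truth
  manifest <- list(seed = tr$seed,
                   ou = list(A = as.numeric(tr$ou$A), b = tr$ou$b,
                             cutpoints = tr$ou$cutpoints,
                             gp_amplitude = tr$ou$gp_amplitude,
                             gp_lengthscale = tr$ou$gp_lengthscale),
                   ctmc = list(name = tr$q$name, Q = as.numeric(tr$q$Q)))
  jsonlite::write_json(manifest, p_man, auto_unbox = TRUE, digits = NA)
  invisible(c(p_csv, p_tre, p_man))
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic authority dataset:", nrow(x$society_table), "societies\n")
  cat("  tree depth:",
      format(max(ape::node.depth.edgelength(x$tree)), digits = 4), "\n")
  cat("  political authority counts:",
      paste(tabulate(x$society_table$political_authority + 1L, 4), collapse = "/"),
      "\n")
  cat("  religious authority counts:",
      paste(tabulate(x$society_table$religious_authority + 1L, 4), collapse = "/"),
      "\n")
  cat("  structure counts:",
      paste(tabulate(x$society_table$authority_structure + 1L, 4), collapse = "/"),
      "\n")
  invisible(x)
}
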