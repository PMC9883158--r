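#' Parse a sample of phylogenetic trees
#'
#' Reads one or more rooted, time-scaled trees from a Newick or NEXUS
#' TREES-block string (or a file path) and validates them as a tree sample:
#' every tree must be rooted, carry branch lengths, and share one taxon set
#' with unique tip labels.
#'
#' @param text A character scalar holding tree text, or a path to a file.
#' @param format Either \code{"newick"} or \code{"nexus"}.
#' @return An \code{ape} \code{multiPhylo} object with attribute
#'   \code{source_format}.
#' @examples
#' trs <- parse_trees("((A:1,B:1):1,C:2);")
#' length(trs)
#' @export
parse_trees <- function(text, format = c("newick", "nexus")) {
  format <- match.arg(format)
  is_path <- length(text) == 1L && !grepl("[(;]", text) && file.exists(text)
  if (!is_path) check_tree_text(text, format)
  trees <- if (format == "newick") {
    if (is_path) ape::read.tree(file = text) else ape::read.tree(text = text)
  } else {
    if (is_path) {
      ape::read.nexus(file = text)
    } else {
      tf <- tempfile(fileext = ".nex")
      on.exit(unlink(tf), add = TRUE)
      writeLines(text, tf)
      ape::read.nexus(file = tf)
    }
  }
  if (inherits(trees, "phylo")) trees <- c(trees)  # promote to multiPhylo
  if (length(trees) == 0L) stop("no trees found in input")
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (anyDuplicated(tr$tip.label)) {
      stop("duplicate tip labels in tree ", i, ": ",
           paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
    }
    if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
      stop("malformed tree ", i, ": missing branch lengths")
    }
    if (any(tr$edge.length < 0)) stop("tree ", i, " has negative branch lengths")
    if (!identical(sort(tr$tip.label), ref)) {
      stop("tree ", i, " does not share the taxon set of tree 1")
    }
  }
  attr(trees, "source_format") <- format
  trees
}

# Cheap syntactic pre-check so malformed text fails with a character offset
# rather than an opaque parser error.
check_tree_text <- function(text, format) {
  s <- paste(text, collapse = "\n")
  depth <- 0L
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("malformed tree text: unmatched ')' at character ", i)
    }
  }
  if (depth != 0L) {
    stop("malformed tree text: ", depth, " unclosed '(' by character ",
         length(chars))
  }
  if (format == "newick" && !grepl(";", s)) {
    stop("malformed tree text: no ';' terminator by character ", length(chars))
  }
  invisible(TRUE)
}

#' Write a tree sample
#'
#' @param trees A \code{phylo} or \code{multiPhylo} object.
#' @param file Output path; if \code{NULL}, the serialized text is returned.
#' @param format \code{"newick"} or \code{"nexus"}.
#' @param digits Significant digits for branch lengths.
#' @return The file path (invisibly) or the text.
#' @export
write_trees <- function(trees, file = NULL, format = c("newick", "nexus"),
                        digits = 12) {
  format <- match.arg(format)
  if (format == "newick") {
    txt <- ape::write.tree(trees, digits = digits)
    if (is.null(file)) return(txt)
    writeLines(txt, file)
  } else {
    if (is.null(file)) file <- tempfile(fileext = ".nex")
    ape::write.nexus(trees, file = file, translate = TRUE)
  }
  invisible(file)
}

#' Prune a tree to a set of taxa
#'
#' Drops all tips outside \code{keep}, collapsing unary internal nodes and
#' summing their branch lengths, so patristic distances among the kept tips
#' are unchanged.
#'
#' @param tree A \code{phylo} object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned \code{phylo}.
#' @export
prune_to_taxa <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0L) {
    stop("labels not in tree: ", paste(missing, collapse = ", "))
  }
  if (length(keep) < 2L) stop("need at least 2 taxa to keep")
  ape::keep.tip(tree, keep)
}

#' Brownian covariance matrix implied by a tree
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds tip depths. This is the Gram matrix of root-to-tip paths,
#' hence positive semidefinite.
#'
#' @param tree A rooted \code{phylo} object.
#' @return A symmetric matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  # a pure star (single internal node) is rooted at that node by convention
  if (!ape::is.rooted(tree) && tree$Nnode > 1L) stop("tree must be rooted")
  ape::vcv.phylo(tree)
}

#' Pagel-style lambda transform of a phylogenetic correlation matrix
#'
#' Multiplies off-diagonal entries by \code{lam}, leaving the diagonal
#' unchanged; \code{lam = 0} gives the identity, \code{lam = 1} returns the
#' input.
#'
#' @param C Symmetric PSD matrix with unit diagonal.
#' @param lam Scalar in [0, 1].
#' @export
lambda_transform <- function(C, lam) {
  if (length(lam) != 1L || is.na(lam) || lam < 0 || lam > 1) {
    stop("lam must be a scalar in [0, 1]")
  }
  out <- C * lam
  diag(out) <- diag(C)
  out
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the tree path between every pair of tips.
#'
#' @param tree A \code{phylo} object with at least two tips.
#' @return Symmetric matrix in tree-time units.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("need at least 2 tips")
  ape::cophenetic.phylo(tree)
}

#' Great-circle distance matrix
#'
#' Haversine distances between coordinates, Earth radius 6371.0088 km
#' (IUGG mean).
#'
#' @param coords Two-column matrix or data.frame of (lat, lon) in degrees,
#'   optionally with rownames used as labels.
#' @return Symmetric matrix of distances in kilometres.
#' @export
great_circle_distances <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coords must have two columns (lat, lon)")
  lat <- coords[, 1]; lon <- coords[, 2]
  if (any(lat < -90 | lat > 90)) stop("latitude out of [-90, 90]")
  if (any(lon < -180 | lon > 180)) stop("longitude out of [-180, 180]")
  # geosphere expects (lon, lat) and metres
  P <- cbind(lon, lat)
  n <- nrow(P)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d[i, ] <- geosphere::distHaversine(P[i, ], P, r = 6371008.8) / 1000
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(rownames(coords), rownames(coords))
  d
}

#' Correlation between two distance matrices
#'
#' Pearson correlation over the n(n-1)/2 unordered taxon pairs, with a
#' parametric test (df = n(n-1)/2 - 2, Fisher-z 95 percent CI) and an
#' optional Mantel permutation p-value. The parametric p-value treats pairs
#' as independent, which pairwise distances are not; the permutation option
#' is provided for that reason.
#'
#' @param D1,D2 Symmetric distance matrices over the same labels in the same
#'   order.
#' @param method \code{"parametric"} (default) or \code{"permutation"}.
#' @param n_perm Number of Mantel permutations when \code{method =
#'   "permutation"}.
#' @param seed Integer seed for the permutation test.
#' @param conf_level Confidence level for the Fisher-z interval.
#' @return List with \code{r}, \code{ci_low}, \code{ci_high}, \code{df},
#'   \code{p}, and \code{method}.
#' @export
distance_correlation <- function(D1, D2, method = c("parametric", "permutation"),
                                 n_perm = 9999, seed = 1, conf_level = 0.95) {
  method <- match.arg(method)
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  if (!all(dim(D1) == dim(D2))) stop("distance matrices differ in size")
  if (!is.null(rownames(D1)) && !is.null(rownames(D2)) &&
      !identical(rownames(D1), rownames(D2))) {
    stop("distance matrix labels do not match")
  }
  n <- nrow(D1)
  if (n < 4L) stop("need at least 4 taxa")
  lt <- lower.tri(D1)
  x <- D1[lt]; y <- D2[lt]
  m <- length(x)                       # n(n-1)/2 pairs
  r <- stats::cor(x, y)
  df <- m - 2L
  z <- atanh(r)
  se <- 1 / sqrt(m - 3)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- tanh(z + c(-1, 1) * q * se)
  if (method == "parametric") {
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df)
  } else {
    set.seed(seed)
    r_perm <- replicate(n_perm, {
      idx <- sample.int(n)
      stats::cor(x, D2[idx, idx][lt])
    })
    p <- (1 + sum(abs(r_perm) >= abs(r))) / (n_perm + 1)
  }
  list(r = r, ci_low = ci[1], ci_high = ci[2], df = df, p = p, method = method)
}

#' Write a labelled distance matrix as CSV
#'
#' @param D Symmetric matrix with dimnames.
#' @param file Output path.
#' @export
write_distance_matrix <- function(D, file) {
  utils::write.csv(as.data.frame(D), file, row.names = TRUE)
  invisible(file)
}
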