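#' Random additive (treelike) distance matrix
#'
#' Draws a random unrooted binary tree topology, assigns branch lengths
#' uniformly in `branch_range`, and returns the patristic distance matrix
#' together with the ground-truth split system (the `2n - 3` splits induced
#' by the tree's edges, weighted by branch length). Additive metrics satisfy
#' the four-point condition exactly and are circular, so the full pipeline
#' should recover the tree's splits with zero residual.
#'
#' @param n number of taxa (>= 4).
#' @param branch_range length-2 vector `(lo, hi)`, `0 < lo <= hi`.
#' @param seed integer seed.
#' @return list with `d` (a [distance_matrix()]), `splits` (canonical list),
#'   `weights` (branch lengths, aligned with `splits`), and `tree`
#'   (the `ape::phylo` object).
#' @export
random_tree_metric <- function(n, branch_range = c(0.1, 1), seed = 1L) {
  if (n < 4L) stop("need at least 4 taxa", call. = FALSE)
  lo <- branch_range[1]; hi <- branch_range[2]
  if (!(lo > 0 && lo <= hi)) {
    stop("`branch_range` must satisfy 0 < lo <= hi", call. = FALSE)
  }
  tree <- withr::with_seed(seed, {
    tr <- ape::rtopology(n, rooted = FALSE, tip.label = paste0("t", seq_len(n)))
    tr$edge.length <- stats::runif(nrow(tr$edge), lo, hi)
    tr
  })
  # order tips so that taxon index i is tip "t<i>"
  dmat <- ape::cophenetic.phylo(tree)
  ord <- paste0("t", seq_len(n))
  d <- distance_matrix(dmat[ord, ord], labels = ord)
  gt <- tree_splits(tree, ord)
  list(d = d, splits = gt$splits, weights = gt$weights, tree = tree)
}

# canonical splits + branch lengths of an unrooted phylo tree
tree_splits <- function(tree, label_order) {
  n <- length(label_order)
  sp <- phangorn::as.splits(tree)
  labs <- attr(sp, "labels")
  w <- attr(sp, "weights")
  map <- match(labs, label_order)
  splits <- list()
  weights <- numeric(0)
  seen <- character(0)
  for (i in seq_along(sp)) {
    side <- map[sp[[i]]]
    if (length(side) == 0L || length(side) == n) next  # full-set pseudo-split
    cs <- canonical_split(side, n)
    key <- paste(cs, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    splits <- c(splits, list(cs))
    weights <- c(weights, w[i])
  }
  list(splits = splits, weights = weights)
}

#' Random circular (Kalmanson) distance matrix
#'
#' Draws a random cycle over the taxa, samples `n_splits` distinct arc splits
#' of that cycle — always including the n trivial splits, so distances
#' between distinct taxa stay positive — gives them positive weights uniform
#' in `weight_range`, and returns the induced phyletic distance matrix
#' `d = A w`. By construction the generating cycle is an optimal circular
#' ordering with tour energy exactly `2 * sum(weights)` (a closed tour
#' crosses each circular split's two arc boundaries once each), and NNLS at
#' that cycle recovers the weights with zero residual.
#'
#' @param n number of taxa (>= 4).
#' @param n_splits number of splits, between `n` and `n(n-1)/2`.
#' @param weight_range length-2 vector `(lo, hi)`, `0 < lo <= hi`.
#' @param seed integer seed.
#' @return list with `d`, `cycle` (canonical generating ordering), `splits`,
#'   and `weights`.
#' @export
random_circular_metric <- function(n, n_splits = 2L * n,
                                   weight_range = c(0.1, 1), seed = 1L) {
  if (n < 4L) stop("need at least 4 taxa", call. = FALSE)
  max_s <- n * (n - 1L) / 2L
  if (n_splits < n || n_splits > max_s) {
    stop("`n_splits` must lie between n = ", n, " and n(n-1)/2 = ", max_s,
         call. = FALSE)
  }
  lo <- weight_range[1]; hi <- weight_range[2]
  if (!(lo > 0 && lo <= hi)) {
    stop("`weight_range` must satisfy 0 < lo <= hi", call. = FALSE)
  }
  withr::with_seed(seed, {
    cycle <- sample.int(n)
    all_splits <- circular_splits(cycle)
    trivial <- which(vapply(all_splits, is_trivial_split, logical(1), n = n))
    extra <- setdiff(seq_along(all_splits), trivial)
    pick <- sort(c(trivial,
                   if (n_splits > n) sample(extra, n_splits - n) else integer(0)))
    splits <- all_splits[pick]
    weights <- stats::runif(length(splits), lo, hi)
    A <- split_design_matrix(splits, n)
    dv <- as.numeric(A %*% weights)
    pairs <- taxon_pairs(n)
    vals <- matrix(0, n, n)
    vals[pairs] <- dv
    vals <- vals + t(vals)
    d <- distance_matrix(vals, labels = paste0("t", seq_len(n)))
    list(d = d, cycle = canonical_ordering(cycle),
         splits = splits, weights = weights)
  })
}

#' Perturb a distance matrix with truncated Gaussian noise
#'
#' Adds independent `N(0, noise_sd)` noise to each off-diagonal pair,
#' truncates at zero so distances stay non-negative, and re-symmetrizes.
#' The diagonal stays zero. Used to build noisy fixtures that are no longer
#' exactly additive or circular.
#'
#' @param d a [distance_matrix()].
#' @param noise_sd standard deviation of the noise (>= 0).
#' @param seed integer seed.
#' @return a perturbed [distance_matrix()].
#' @export
perturb_distances <- function(d, noise_sd, seed = 1L) {
  check_dist(d)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (noise_sd == 0) return(d)
  n <- n_taxa(d)
  withr::with_seed(seed, {
    pairs <- taxon_pairs(n)
    noise <- stats::rnorm(nrow(pairs), sd = noise_sd)
    vals <- matrix(0, n, n)
    vals[pairs] <- pmax(unclass(d)[pairs] + noise, 0)
    vals <- vals + t(vals)
    distance_matrix(vals, labels = taxa_labels(d))
  })
}

#' Random symmetric dissimilarity matrix
#'
#' Uniform off-diagonal dissimilarities with no structure (not additive, not
#' circular); used to exercise the search on unstructured inputs.
#'
#' @param n number of taxa.
#' @param range length-2 vector of the uniform support.
#' @param seed integer seed.
#' @return a [distance_matrix()].
#' @export
random_dissimilarity <- function(n, range = c(0.1, 1), seed = 1L) {
  if (n < 4L) stop("need at least 4 taxa", call. = FALSE)
  withr::with_seed(seed, {
    pairs <- taxon_pairs(n)
    vals <- matrix(0, n, n)
    vals[pairs] <- stats::runif(nrow(pairs), range[1], range[2])
    vals <- vals + t(vals)
    distance_matrix(vals, labels = paste0("t", seq_len(n)))
  })
}
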