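#' Closed-tour energy of a circular ordering
#'
#' The energy of an ordering `sigma` is the length of the closed tour that
#' visits the taxa in that order and returns to the start:
#' `d(s1, sn) + sum_k d(sk, s(k+1))`. Its minimizers over all circular
#' orderings are the optimal circular orderings that the annealer searches
#' for; for an additive (tree) metric the minimum equals twice the total
#' branch length.
#'
#' @param d a [distance_matrix()].
#' @param sigma integer permutation of `1:n` (taxon indices into `d`).
#' @return non-negative tour length.
#' @export
tour_energy <- function(d, sigma) {
  check_dist(d)
  sigma <- check_ordering(sigma, n_taxa(d))
  nxt <- c(sigma[-1], sigma[1])
  sum(d[cbind(sigma, nxt)])
}

check_ordering <- function(sigma, n) {
  sigma <- as.integer(sigma)
  if (length(sigma) != n || anyNA(sigma) ||
      !identical(sort(sigma), seq_len(n))) {
    stop("`sigma` must be a permutation of 1:", n, call. = FALSE)
  }
  sigma
}

#' Canonical form of a circular ordering
#'
#' Two permutations denote the same circular ordering when they differ only
#' by rotation or reversal of the tour. The canonical representative rotates
#' the smallest index to the front and orients the tour so that the second
#' element is smaller than the last.
#'
#' @param sigma integer permutation.
#' @return the canonical permutation.
#' @export
canonical_ordering <- function(sigma) {
  sigma <- as.integer(sigma)
  n <- length(sigma)
  i <- which.min(sigma)
  sigma <- sigma[((seq_len(n) + i - 2L) %% n) + 1L]
  if (n > 2L && sigma[2L] > sigma[n]) {
    sigma <- c(sigma[1L], rev(sigma[-1L]))
  }
  sigma
}

#' Test whether two orderings denote the same circular ordering
#' @param a,b integer permutations.
#' @return logical.
#' @export
same_circular_ordering <- function(a, b) {
  identical(canonical_ordering(a), canonical_ordering(b))
}

#' Greedy initial circular ordering
#'
#' Builds a path greedily: seed with the pair of taxa at minimum distance
#' (lexicographically first such pair), then repeatedly attach the unplaced
#' taxon closest to either end of the path, prepending when the closest end
#' is the head and appending when it is the tail. The closed-up path is the
#' initial ordering handed to the annealer. Ties are broken by smallest taxon
#' index, and tail attachment wins when both ends tie, so the procedure is
#' deterministic.
#'
#' @param d a [distance_matrix()].
#' @return integer permutation of `1:n`.
#' @export
initial_ordering <- function(d) {
  check_dist(d)
  n <- n_taxa(d)
  dm <- unclass(d)
  # lexicographically-first pair attaining the minimum off-diagonal distance
  off <- dm
  diag(off) <- Inf
  best <- Inf
  seed <- c(1L, 2L)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (off[i, j] < best) {
        best <- off[i, j]
        seed <- c(i, j)
      }
    }
  }
  path <- seed
  unplaced <- setdiff(seq_len(n), path)
  while (length(unplaced)) {
    head_d <- dm[unplaced, path[1L]]
    tail_d <- dm[unplaced, path[length(path)]]
    m <- min(head_d, tail_d)
    # smallest candidate taxon achieving the minimum; tail wins end ties
    cand <- unplaced[pmin(head_d, tail_d) == m]
    x <- min(cand)
    at_tail <- dm[x, path[length(path)]] == m
    if (at_tail) path <- c(path, x) else path <- c(x, path)
    unplaced <- setdiff(unplaced, x)
  }
  path
}
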