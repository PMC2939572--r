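#' Exhaustive search for the optimal circular ordering
#'
#' Enumerates every distinct circular ordering — first element fixed at taxon
#' 1 and second element smaller than the last, which kills rotations and
#' reflections, leaving `(n-1)!/2` tours — and returns a global minimizer of
#' [tour_energy()]. Finding the optimal ordering is equivalent to a traveling
#' salesman problem and NP-hard in general, so exhaustive search is capped at
#' `n <= 10`; it exists as the ground truth the stochastic search is
#' validated against.
#'
#' @param d a [distance_matrix()].
#' @return list with `ordering` (canonical form; ties broken lexicographically),
#'   `energy` (the global minimum), and `n_enumerated` (`(n-1)!/2`).
#' @export
optimal_ordering_exhaustive <- function(d) {
  check_dist(d)
  n <- n_taxa(d)
  if (n > 10L) {
    stop("exhaustive search is limited to n <= 10 taxa (got ", n, ")",
         call. = FALSE)
  }
  perms <- permutations_of(2:n)
  keep <- perms[, 1L] < perms[, ncol(perms)]
  perms <- perms[keep, , drop = FALSE]
  tours <- cbind(1L, perms)
  # vectorized tour lengths: sum consecutive-pair distances per row
  dm <- unclass(d)
  e <- numeric(nrow(tours))
  for (k in seq_len(n)) {
    a <- tours[, k]
    b <- tours[, if (k == n) 1L else k + 1L]
    e <- e + dm[cbind(a, b)]
  }
  best_e <- min(e)
  hits <- which(e <= best_e)
  # lexicographic tie-break on the canonical representative (rows are
  # enumerated in lexicographic order already)
  best <- tours[hits[1L], ]
  list(ordering = canonical_ordering(best),
       energy = best_e,
       n_enumerated = nrow(tours))
}

# all permutations of a vector, rows in lexicographic order
permutations_of <- function(x) {
  x <- as.integer(x)
  m <- length(x)
  if (m == 1L) return(matrix(x, 1L, 1L))
  out <- vector("list", m)
  for (i in seq_len(m)) {
    sub <- permutations_of(x[-i])
    out[[i]] <- cbind(x[i], sub)
  }
  do.call(rbind, out)
}
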