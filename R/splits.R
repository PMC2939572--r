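#' Circular splits of an ordering
#'
#' Every contiguous arc of a circular ordering defines a split (the arc
#' versus the rest). An ordering of n taxa induces `n(n-1)/2` distinct
#' splits, including all n trivial (single-taxon) splits. Splits are returned
#' in canonical form: the side not containing taxon 1, as a sorted integer
#' vector, so complements are deduplicated deterministically.
#'
#' @param sigma integer permutation of `1:n`.
#' @return list of integer vectors, one per split.
#' @export
circular_splits <- function(sigma) {
  sigma <- as.integer(sigma)
  n <- length(sigma)
  if (n < 4L) stop("need at least 4 taxa", call. = FALSE)
  if (!identical(sort(sigma), seq_len(n))) {
    stop("`sigma` must be a permutation of 1:", n, call. = FALSE)
  }
  splits <- vector("list", n * (n - 1L) / 2L)
  s <- 0L
  # arcs that avoid position 1 enumerate each split exactly once
  for (i in 2:n) {
    for (j in i:n) {
      s <- s + 1L
      splits[[s]] <- canonical_split(sigma[i:j], n)
    }
  }
  splits
}

# canonical form: the side not containing taxon 1, sorted
canonical_split <- function(side, n) {
  side <- as.integer(side)
  if (1L %in% side) side <- setdiff(seq_len(n), side)
  sort(side)
}

#' Is a split trivial?
#' @param side canonical split (integer vector).
#' @param n number of taxa.
#' @return logical: `TRUE` when one side is a single taxon.
#' @export
is_trivial_split <- function(side, n) {
  length(side) == 1L || length(side) == n - 1L
}

#' Pair-by-split design matrix
#'
#' Rows are taxon pairs `(i, j)` with `i < j` in lexicographic order, matching
#' the distance vector `(d_12, d_13, ..., d_(n-1)n)`; the entry for pair
#' `(i, j)` and split `k` is 1 when i and j lie on opposite sides of split k,
#' else 0. For the full set of circular splits of an ordering this matrix is
#' square (`n(n-1)/2` by `n(n-1)/2`) and of full rank.
#'
#' @param splits list of canonical splits.
#' @param n number of taxa.
#' @return 0/1 matrix with `n(n-1)/2` rows and `length(splits)` columns.
#' @export
split_design_matrix <- function(splits, n) {
  pairs <- taxon_pairs(n)
  memb <- vapply(splits, function(s) seq_len(n) %in% s, logical(n))
  A <- (memb[pairs[, 1L], , drop = FALSE] !=
        memb[pairs[, 2L], , drop = FALSE]) * 1
  rownames(A) <- paste(pairs[, 1L], pairs[, 2L], sep = ",")
  A
}

# lexicographic (i < j) pair index, row-aligned with the distance vector
taxon_pairs <- function(n) {
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  cbind(i = i, j = j)
}

# flatten a distance matrix into the lexicographic pair vector
distance_vector <- function(d) {
  p <- taxon_pairs(nrow(d))
  unclass(d)[cbind(p[, 1L], p[, 2L])]
}

#' Ordinary least-squares split weights
#'
#' Solves the unconstrained problem `min ||A b - d||_2` via the closed form
#' `b = (A'A)^-1 A'd` (computed by QR). Weights may come out negative; the
#' pipeline uses [fit_nnls()] instead, but the unconstrained fit is exposed
#' because its residual lower-bounds the constrained one.
#'
#' @param design 0/1 design matrix (full column rank).
#' @param dvec distance vector aligned with the design rows.
#' @return numeric weight vector.
#' @export
fit_ols <- function(design, dvec) {
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    stop("design matrix is rank deficient (rank ", qr_d$rank, " < ",
         ncol(design), " columns)", call. = FALSE)
  }
  as.numeric(qr.coef(qr_d, dvec))
}

#' Non-negative least-squares split weights
#'
#' Solves `min ||A b - d||_2` subject to `b >= 0` with the Lawson-Hanson
#' active-set method (`pracma::lsqnonneg`). At the solution the
#' Karush-Kuhn-Tucker conditions hold: the gradient `A'(Ab - d)` is
#' (numerically) zero on positive weights and non-negative on zero weights.
#'
#' @inheritParams fit_ols
#' @return non-negative numeric weight vector.
#' @export
fit_nnls <- function(design, dvec) {
  fit <- pracma::lsqnonneg(unname(as.matrix(design)), as.numeric(dvec))
  w <- as.numeric(fit$x)
  w[w < 0] <- 0
  w
}

#' Weight the circular splits of an ordering
#'
#' Builds the full circular split system of `sigma`, fits split weights to
#' the input distances, and returns a weighted split system carrying the
#' design matrix and distance vector for later scoring and filtering.
#'
#' @param d a [distance_matrix()].
#' @param sigma circular ordering (integer permutation).
#' @param method `"nnls"` (default, non-negative weights) or `"ols"`.
#' @return an `mcnet_splits` list: `splits`, `weights`, `cycle`, `design`,
#'   `dvec`, `labels`.
#' @export
weight_splits <- function(d, sigma, method = c("nnls", "ols")) {
  check_dist(d)
  method <- match.arg(method)
  n <- n_taxa(d)
  sigma <- check_ordering(sigma, n)
  splits <- circular_splits(sigma)
  A <- split_design_matrix(splits, n)
  dv <- distance_vector(d)
  w <- switch(method, nnls = fit_nnls(A, dv), ols = fit_ols(A, dv))
  structure(list(splits = splits, weights = w,
                 cycle = canonical_ordering(sigma),
                 design = A, dvec = dv, labels = taxa_labels(d)),
            class = "mcnet_splits")
}

#' Drop splits with (near-)zero weight
#'
#' The active-set fit returns exact zeros for excluded splits; the threshold
#' only guards solver noise (stray weights up to ~1e-9 have been observed on
#' exactly-fitted systems, so the default sits above that while staying far
#' below any weight of scientific interest). The design matrix and distance vector
#' are kept (columns subset to the retained splits) so the filtered system
#' can still be scored with [fit_norm()].
#'
#' @param system an `mcnet_splits` object.
#' @param threshold retain splits with weight strictly above this.
#' @return a filtered `mcnet_splits` object.
#' @export
filter_splits <- function(system, threshold = 1e-8) {
  stopifnot(inherits(system, "mcnet_splits"))
  if (threshold < 0) stop("`threshold` must be non-negative", call. = FALSE)
  keep <- system$weights > threshold
  system$splits <- system$splits[keep]
  system$weights <- system$weights[keep]
  system$design <- system$design[, keep, drop = FALSE]
  system
}

#' Residual norm of a fitted split system
#'
#' Euclidean norm of `A w - d`: how far the phyletic distances implied by the
#' weighted splits are from the input distances (0 for an exactly circular
#' or additive input at its generating ordering).
#'
#' @param system an `mcnet_splits` object (fitted, optionally filtered).
#' @return non-negative scalar.
#' @export
fit_norm <- function(system) {
  stopifnot(inherits(system, "mcnet_splits"))
  p <- as.numeric(system$design %*% system$weights)
  sqrt(sum((p - system$dvec)^2))
}

#' @export
print.mcnet_splits <- function(x, ...) {
  n <- length(x$labels)
  cat("Weighted split system:", length(x$splits), "splits over", n, "taxa\n")
  cat("  cycle:", paste(x$labels[x$cycle], collapse = " "), "\n")
  cat("  fit norm:", format(fit_norm(x)), "\n")
  invisible(x)
}

#' Tabulate a split system
#'
#' @param x an `mcnet_splits` object.
#' @param ... unused.
#' @return data frame with one row per split: the member taxa of the side not
#'   containing the first taxon, the split size, and the weight.
#' @export
as.data.frame.mcnet_splits <- function(x, ...) {
  data.frame(
    split = vapply(x$splits, function(s)
      paste(x$labels[s], collapse = " "), character(1)),
    size = vapply(x$splits, length, integer(1)),
    weight = x$weights,
    stringsAsFactors = FALSE
  )
}
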