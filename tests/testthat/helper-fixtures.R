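# Shared fixtures and independent oracles, built in code.

# 4-taxon "cycle" metric: distance 1 between cycle-adjacent pairs, 2 across.
# The tour (1,2,3,4) has length 4, the other two circular orderings 6.
cycle4_metric <- function() {
  distance_matrix(rbind(c(0, 1, 2, 1),
                        c(1, 0, 1, 2),
                        c(2, 1, 0, 1),
                        c(1, 2, 1, 0)),
                  labels = c("A", "B", "C", "D"))
}

# Additive quartet metric of the tree ((1,2),(3,4)) with unit branches:
# d = 2 within cherries, 3 across.
quartet_tree_metric <- function() {
  distance_matrix(rbind(c(0, 2, 3, 3),
                        c(2, 0, 3, 3),
                        c(3, 3, 0, 2),
                        c(3, 3, 2, 0)),
                  labels = paste0("t", 1:4))
}

# canonical string key for a list of splits, for set comparisons
split_keys <- function(splits) {
  vapply(splits, paste, character(1), collapse = ",")
}

# KKT conditions for min ||Ab - d|| s.t. b >= 0: gradient g = A'(Ab - d)
# must be ~0 where b > 0 and >= 0 where b = 0.
expect_kkt <- function(A, dvec, w, tol = 1e-7) {
  g <- as.numeric(crossprod(A, A %*% w - dvec))
  scale <- max(1, max(abs(dvec)))
  active <- w > 1e-10
  expect_lt(max(abs(g[active]), 0), tol * scale)
  if (any(!active)) expect_gt(min(g[!active]), -tol * scale)
  invisible(TRUE)
}

# Exhaustive NNLS oracle for small systems: try every support set, solve the
# unconstrained problem on it, keep feasible (non-negative) candidates, and
# return the one with smallest residual. Independent of the active-set path.
nnls_exhaustive <- function(A, dvec) {
  m <- ncol(A)
  best_w <- rep(0, m)
  best_r <- sqrt(sum(dvec^2))
  for (mask in seq_len(2^m) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    if (!length(sel)) next
    sub <- A[, sel, drop = FALSE]
    if (qr(sub)$rank < length(sel)) next
    w_sub <- qr.coef(qr(sub), dvec)
    if (any(w_sub < -1e-12)) next
    w <- rep(0, m)
    w[sel] <- pmax(w_sub, 0)
    r <- sqrt(sum((A %*% w - dvec)^2))
    if (r < best_r - 1e-12) {
      best_r <- r
      best_w <- w
    }
  }
  list(w = best_w, resid = best_r)
}

# brute-force tour energies of every circular ordering (tiny n only)
all_tour_energies <- function(d) {
  n <- n_taxa(d)
  perms <- as.matrix(expand.grid(rep(list(2:n), n - 1)))
  perms <- perms[apply(perms, 1, function(r) !anyDuplicated(r)), , drop = FALSE]
  perms <- perms[perms[, 1] < perms[, n - 1], , drop = FALSE]
  apply(perms, 1, function(r) tour_energy(d, c(1L, as.integer(r))))
}
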