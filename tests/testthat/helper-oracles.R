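# Independent oracles used across the suite.

# Brute-force LP solve by vertex enumeration for max c'v s.t. S v = 0,
# lb <= v <= ub with finite bounds and few variables (<= 8): every vertex
# has at least n - rank(S) variables at a bound; enumerate all such
# fixings, solve the remaining square-ish system, keep feasible points,
# and return the best objective. Completely independent of the package's
# simplex.
brute_force_lp <- function(S, lb, ub, obj) {
  n <- ncol(S)
  if (nrow(S) > 0) {
    qrS <- qr(t(S))
    S <- S[qrS$pivot[seq_len(qrS$rank)], , drop = FALSE]
  }
  r <- nrow(S)
  k <- n - r                      # number of variables to fix at bounds
  best <- -Inf
  feasible <- FALSE
  tol <- 1e-8
  fix_sets <- utils::combn(n, k, simplify = FALSE)
  for (fix in fix_sets) {
    free <- setdiff(seq_len(n), fix)
    Sf <- S[, free, drop = FALSE]
    if (length(free) > 0 && qr(Sf)$rank < length(free)) next
    # all 2^k assignments of fixed vars to lower/upper bound
    for (mask in 0:(2^k - 1)) {
      vfix <- numeric(k)
      for (j in seq_len(k)) {
        vfix[j] <- if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) > 0)
          ub[fix[j]] else lb[fix[j]]
      }
      v <- numeric(n)
      v[fix] <- vfix
      if (length(free) > 0) {
        rhs <- -as.numeric(S[, fix, drop = FALSE] %*% vfix)
        sol <- tryCatch(qr.solve(Sf, rhs), error = function(e) NULL)
        if (is.null(sol)) next
        v[free] <- sol
      }
      if (any(v < lb - tol) || any(v > ub + tol)) next
      if (nrow(S) > 0 && max(abs(S %*% v)) > tol) next
      feasible <- TRUE
      val <- sum(obj * v)
      if (val > best) best <- val
    }
  }
  if (!feasible) return(list(status = "infeasible", value = NA_real_))
  list(status = "optimal", value = best)
}

# Random toy flux networks with finite bounds; v = 0 is always feasible,
# so the LP is feasible and bounded.
random_toy_lp <- function(n_rxn = 6, n_met = 4) {
  S <- matrix(0, n_met, n_rxn)
  for (j in seq_len(n_rxn)) {
    nm <- sample(2:min(3, n_met), 1)
    idx <- sample(n_met, nm)
    S[idx, j] <- sample(c(-2, -1, 1, 2), nm, replace = TRUE)
  }
  lb <- ifelse(stats::runif(n_rxn) < 0.5, -round(stats::runif(n_rxn, 0, 10), 1), 0)
  ub <- round(stats::runif(n_rxn, 0, 10), 1)
  obj <- round(stats::rnorm(n_rxn), 2)
  list(S = S, lb = lb, ub = ub, obj = obj)
}
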