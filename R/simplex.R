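# Bounded-variable revised simplex.
#
# Solves   max/min  c'x   s.t.  A x = b,  lb <= x <= ub
# with a two-phase method: Phase I minimises artificial variables to find a
# feasible basis, Phase II optimises the true objective. Nonbasic variables
# sit at a finite bound; the basis is refactorised (dense solve) at every
# iteration, which is cheap at the problem sizes used here (tens of rows)
# and numerically safer than product-form updates. Dantzig pricing with a
# switch to Bland's rule after a run of degenerate steps guarantees
# termination.
#
# This solver exists because flux balance LPs are heavily degenerate
# (conserved cofactor pools, redundant bounds), which the general-purpose
# tableau implementations available to the package do not survive.

RF_SIMPLEX_BIG <- 1e9

rf_simplex <- function(A, b, lb, ub, obj, maximize = TRUE,
                       tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(lb) == n, length(ub) == n,
            length(obj) == n)
  if (any(lb > ub)) return(list(status = "infeasible", x = NULL,
                                value = NA_real_))
  sense <- if (maximize) 1 else -1
  cc <- sense * obj
  lo <- pmax(lb, -RF_SIMPLEX_BIG)
  hi <- pmin(ub, RF_SIMPLEX_BIG)

  if (m == 0L) {
    # pure box problem: optimum sits at the bounds selected by the costs
    x <- ifelse(cc > 0, hi, lo)
    return(list(status = "optimal", x = x, value = sum(obj * x)))
  }

  # start all structural variables at the bound closest to zero
  x <- ifelse(abs(lo) <= abs(hi), lo, hi)
  at_upper <- abs(lo) > abs(hi)
  resid <- b - as.numeric(A %*% x)

  # artificial columns with signs matching the residual
  sgn <- ifelse(resid >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, m))
  lo <- c(lo, rep(0, m))
  hi <- c(hi, abs(resid))
  x <- c(x, abs(resid))
  at_upper <- c(at_upper, rep(FALSE, m))
  ntot <- n + m
  basis <- n + seq_len(m)
  art <- rep(FALSE, ntot); art[n + seq_len(m)] <- TRUE

  run_phase <- function(cost, x, basis, at_upper, hi) {
    degen_run <- 0L
    for (iter in seq_len(max_iter)) {
      Bmat <- Afull[, basis, drop = FALSE]
      nonbasic <- setdiff(seq_len(ntot), basis)
      xN <- x[nonbasic]
      rhs <- b - as.numeric(Afull[, nonbasic, drop = FALSE] %*% xN)
      xB <- tryCatch(solve(Bmat, rhs), error = function(e) NULL)
      if (is.null(xB)) return(list(status = "singular"))
      x[basis] <- xB
      y <- tryCatch(solve(t(Bmat), cost[basis]), error = function(e) NULL)
      if (is.null(y)) return(list(status = "singular"))
      d <- cost[nonbasic] - as.numeric(crossprod(Afull[, nonbasic,
                                                       drop = FALSE], y))
      up <- at_upper[nonbasic]
      # improving: increase var at lower bound (d > tol) or decrease var at
      # upper bound (d < -tol); bound-fixed vars (lo == hi) can do neither
      movable <- hi[nonbasic] - lo[nonbasic] > 0
      cand_lo <- which(!up & movable & d > tol)
      cand_hi <- which(up & movable & d < -tol)
      if (length(cand_lo) + length(cand_hi) == 0) {
        return(list(status = "optimal", x = x, basis = basis,
                    at_upper = at_upper))
      }
      if (degen_run > 100L) {
        # Bland: smallest index among improving candidates
        all_c <- c(cand_lo, cand_hi)
        pick <- all_c[which.min(nonbasic[all_c])]
      } else {
        gain <- rep(-Inf, length(d))
        gain[cand_lo] <- d[cand_lo]
        gain[cand_hi] <- -d[cand_hi]
        pick <- which.max(gain)
      }
      q <- nonbasic[pick]
      dirq <- if (at_upper[q]) -1 else 1  # entering variable moves this way
      w <- tryCatch(solve(Bmat, Afull[, q]), error = function(e) NULL)
      if (is.null(w)) return(list(status = "singular"))
      # basic variables move by -dirq * w * t
      step <- hi[q] - lo[q]             # bound-flip limit
      leave <- 0L; leave_to_upper <- FALSE
      for (i in seq_len(m)) {
        delta <- -dirq * w[i]
        if (delta < -tol) {             # basic var decreasing
          tmax <- (x[basis[i]] - lo[basis[i]]) / (-delta)
          if (tmax < step - tol * max(1, abs(step))) {
            step <- tmax; leave <- i; leave_to_upper <- FALSE
          } else if (degen_run > 100L && abs(tmax - step) <= tol &&
                     (leave == 0L || basis[i] < basis[leave])) {
            step <- min(step, tmax); leave <- i; leave_to_upper <- FALSE
          }
        } else if (delta > tol) {       # basic var increasing
          tmax <- (hi[basis[i]] - x[basis[i]]) / delta
          if (tmax < step - tol * max(1, abs(step))) {
            step <- tmax; leave <- i; leave_to_upper <- TRUE
          } else if (degen_run > 100L && abs(tmax - step) <= tol &&
                     (leave == 0L || basis[i] < basis[leave])) {
            step <- min(step, tmax); leave <- i; leave_to_upper <- TRUE
          }
        }
      }
      if (!is.finite(step)) return(list(status = "unbounded"))
      step <- max(step, 0)
      degen_run <- if (step <= tol) degen_run + 1L else 0L
      # apply the move
      x[q] <- x[q] + dirq * step
      x[basis] <- x[basis] - dirq * w * step
      if (leave == 0L) {
        at_upper[q] <- !at_upper[q]     # bound flip, basis unchanged
      } else {
        lv <- basis[leave]
        x[lv] <- if (leave_to_upper) hi[lv] else lo[lv]
        at_upper[lv] <- leave_to_upper
        basis[leave] <- q
      }
    }
    list(status = "maxiter")
  }

  # Phase I: drive artificials to zero
  c1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_phase(c1, x, basis, at_upper, hi)
  if (ph1$status != "optimal") {
    return(list(status = if (ph1$status == "unbounded") "infeasible"
                         else ph1$status,
                x = NULL, value = NA_real_))
  }
  if (sum(ph1$x[art]) > 1e-7) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  x <- ph1$x; basis <- ph1$basis; at_upper <- ph1$at_upper
  hi[art] <- 0                          # freeze artificials at zero
  x[art] <- 0

  # Phase II
  c2 <- c(cc, rep(0, m))
  ph2 <- run_phase(c2, x, basis, at_upper, hi)
  if (ph2$status != "optimal") {
    return(list(status = ph2$status, x = NULL, value = NA_real_))
  }
  xs <- ph2$x[seq_len(n)]
  xs <- pmin(pmax(xs, lb), ub)
  list(status = "optimal", x = xs, value = sum(obj * xs))
}
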