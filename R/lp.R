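# Dense two-phase simplex for the small flux-balance LPs this package
# solves. Models here are toy-scale (tens of reactions), so a tableau
# simplex with Bland's anti-cycling rule is exact, dependency-free and fast
# enough; no robust general-purpose LP package is available to lean on.
#
# Problem form solved by lp_solve_():
#   max/min  obj' v   s.t.  S v = b,  lb <= v <= ub   (all bounds finite)

LP_EPS <- 1e-9

# Core routine: minimise cost' x over {A x = b, x >= 0} given a starting
# basis whose columns form an identity in A. The tableau is kept in
# canonical form with the reduced-cost row maintained as an extra bottom
# row (updated by the same pivot, so pricing is O(n) per iteration).
# Entering variable: Dantzig rule, falling back to Bland's anti-cycling
# rule after `bland_after` iterations to guarantee termination.
simplex_core_ <- function(cost, tab, basis, allowed, max_iter = 20000L,
                          bland_after = 500L) {
  n <- length(cost)
  rhs_col <- n + 1L
  m <- nrow(tab)
  cb <- cost[basis]
  red0 <- cost - as.vector(crossprod(tab[, seq_len(n), drop = FALSE], cb))
  tab <- rbind(tab, c(red0, -sum(cb * tab[, rhs_col])))
  rows <- seq_len(m)
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) {
      return(list(status = "iteration_limit", tab = tab[rows, , drop = FALSE], basis = basis))
    }
    red <- tab[m + 1L, seq_len(n)]
    cand <- allowed[red[allowed] < -LP_EPS]
    if (!length(cand)) {
      return(list(status = "optimal", tab = tab[rows, , drop = FALSE], basis = basis))
    }
    ent <- if (it <= bland_after) cand[which.min(red[cand])] else min(cand)
    col <- tab[rows, ent]
    pos <- which(col > LP_EPS)
    if (!length(pos)) {
      return(list(status = "unbounded", tab = tab[rows, , drop = FALSE], basis = basis))
    }
    ratio <- tab[pos, rhs_col] / col[pos]
    rmin <- min(ratio)
    tie <- pos[ratio <= rmin + LP_EPS]
    leave <- tie[which.min(basis[tie])]   # smallest basic index on ties
    piv <- tab[leave, ent]
    tab[leave, ] <- tab[leave, ] / piv
    other <- setdiff(seq_len(m + 1L), leave)
    tab[other, ] <- tab[other, ] - outer(tab[other, ent], tab[leave, ])
    tab[other, ent] <- 0
    basis[leave] <- ent
  }
}

# Bounded-variable LP via shift to x = v - lb plus explicit upper-bound
# slack rows. Returns list(status, objective, solution).
lp_solve_ <- function(obj, S, b, lb, ub, maximize = TRUE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    abort_("LP bounds must be finite (cap free fluxes at +/-1000)")
  }
  if (any(lb > ub + LP_EPS)) return(list(status = "infeasible", objective = NA_real_, solution = NULL))
  m <- if (is.null(S)) 0L else nrow(S)
  rng <- pmax(ub - lb, 0)

  beq <- if (m) as.vector(b - S %*% lb) else numeric(0)
  flip <- beq < 0
  if (any(flip)) {
    S[flip, ] <- -S[flip, , drop = FALSE]
    beq[flip] <- -beq[flip]
  }

  # columns: n structural x, n upper-bound slacks, m artificials
  ncols <- 2L * n + m
  nrows <- m + n
  A <- matrix(0, nrows, ncols)
  if (m) {
    A[seq_len(m), seq_len(n)] <- S
    A[cbind(seq_len(m), 2L * n + seq_len(m))] <- 1
  }
  A[cbind(m + seq_len(n), seq_len(n))] <- 1
  A[cbind(m + seq_len(n), n + seq_len(n))] <- 1
  rhs <- c(beq, rng)
  tab <- cbind(A, rhs)
  basis <- c(if (m) 2L * n + seq_len(m) else integer(0), n + seq_len(n))

  # phase 1: drive artificials to zero
  if (m) {
    cost1 <- c(rep(0, 2L * n), rep(1, m))
    r1 <- simplex_core_(cost1, tab, basis, allowed = seq_len(ncols))
    if (r1$status != "optimal") return(list(status = "infeasible", objective = NA_real_, solution = NULL))
    art_basic <- which(r1$basis > 2L * n)
    art_val <- if (length(art_basic)) sum(r1$tab[art_basic, ncols + 1L]) else 0
    if (art_val > 1e-7) return(list(status = "infeasible", objective = NA_real_, solution = NULL))
    tab <- r1$tab
    basis <- r1$basis
    # drive artificials out of the basis so phase 2 cannot re-inflate them;
    # rows with no eligible pivot are redundant constraints and stay inert
    for (row in which(basis > 2L * n)) {
      piv_col <- which(abs(tab[row, seq_len(2L * n)]) > LP_EPS)[1]
      if (is.na(piv_col)) next
      piv <- tab[row, piv_col]
      tab[row, ] <- tab[row, ] / piv
      other <- setdiff(seq_len(nrow(tab)), row)
      tab[other, ] <- tab[other, ] - outer(tab[other, piv_col], tab[row, ])
      tab[other, piv_col] <- 0
      basis[row] <- piv_col
    }
  }

  # phase 2: original objective over structural + slack columns only
  cost2 <- c(if (maximize) -obj else obj, rep(0, n + m))
  r2 <- simplex_core_(cost2, tab, basis, allowed = seq_len(2L * n))
  if (r2$status == "unbounded") return(list(status = "unbounded", objective = NA_real_, solution = NULL))
  if (r2$status != "optimal") return(list(status = "infeasible", objective = NA_real_, solution = NULL))

  x <- numeric(ncols)
  x[r2$basis] <- r2$tab[, ncols + 1L]
  v <- x[seq_len(n)] + lb
  list(status = "optimal", objective = sum(obj * v), solution = v)
}

# Convex QP: minimise sum(w_i * v_i^2) over {S v = 0-ish, lb <= v <= ub,
# extra' v >= rhs_extra}. Weights are 1 for the targeted variables and a
# tiny ridge elsewhere so quadprog's strictly-convex requirement is met
# while leaving the linear optimum essentially undisturbed.
qp_l2_solve_ <- function(S, b, lb, ub, quad_idx, extra = NULL, extra_rhs = NULL,
                         ridge = 1e-8) {
  n <- length(lb)
  d <- rep(ridge, n)
  d[quad_idx] <- 1
  Dmat <- diag(2 * d, n, n)
  dvec <- rep(0, n)
  m <- if (is.null(S)) 0L else nrow(S)
  Amat <- cbind(
    if (m) t(S) else NULL,
    diag(1, n, n),
    diag(-1, n, n),
    if (!is.null(extra)) t(extra) else NULL
  )
  bvec <- c(if (m) b else NULL, lb, -ub, extra_rhs)
  ans <- tryCatch(
    quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = m),
    error = function(e) NULL
  )
  if (is.null(ans) && !is.null(extra_rhs)) {
    # marginally infeasible growth constraints from LP rounding: retry with
    # a hair of slack before declaring failure
    bvec2 <- c(if (m) b else NULL, lb, -ub, extra_rhs - 1e-7 * (1 + abs(extra_rhs)))
    ans <- tryCatch(
      quadprog::solve.QP(Dmat, dvec, Amat, bvec2, meq = m),
      error = function(e) NULL
    )
  }
  if (is.null(ans)) return(list(status = "infeasible", solution = NULL))
  list(status = "optimal", solution = ans$solution)
}
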