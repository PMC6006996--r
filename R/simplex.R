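## Dense two-phase primal simplex with Bland's anti-cycling rule, for the
## small flux LPs of FBA/FVA. Standard form: min c'x s.t. A x = b, x >= 0
## with b >= 0. Bland's rule (smallest-index entering/leaving variable)
## guarantees termination on the degenerate bases these problems produce.

.simplexPivot <- function(Tb, basis, prow, pcol) {
  piv <- Tb[prow, pcol]
  Tb[prow, ] <- Tb[prow, ] / piv
  for (i in seq_len(nrow(Tb))) {
    if (i != prow && Tb[i, pcol] != 0)
      Tb[i, ] <- Tb[i, ] - Tb[i, pcol] * Tb[prow, ]
  }
  basis[prow] <- pcol
  list(Tb = Tb, basis = basis)
}

## iterate to optimality for min cost'x given a starting basic feasible
## tableau [A | b] whose basis columns are unit vectors
.simplexIter <- function(Tb, cost, basis, tol = 1e-9, maxit = 100000L) {
  m <- nrow(Tb); n <- ncol(Tb) - 1L
  for (it in seq_len(maxit)) {
    red <- cost - drop(crossprod(cost[basis], Tb[, seq_len(n),
                                                 drop = FALSE]))
    ent <- which(red < -tol)
    if (!length(ent))
      return(list(status = "optimal", Tb = Tb, basis = basis))
    j <- min(ent)                                   # Bland: smallest index
    col <- Tb[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded"))
    ratios <- Tb[pos, n + 1L] / col[pos]
    best <- pos[ratios <= min(ratios) + tol]
    prow <- best[which.min(basis[best])]            # Bland on ties
    up <- .simplexPivot(Tb, basis, prow, j)
    Tb <- up$Tb; basis <- up$basis
  }
  list(status = "iteration-limit")
}

## min (or max) c'x s.t. A x = b, x >= 0. Returns status, x, value.
.simplexSolve <- function(c0, A, b, maximise = FALSE, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  sgn <- b < 0
  A[sgn, ] <- -A[sgn, , drop = FALSE]; b[sgn] <- -b[sgn]
  cost <- if (maximise) -c0 else c0
  # phase 1
  Tb <- cbind(A, diag(m), b, deparse.level = 0)
  basis <- n + seq_len(m)
  c1 <- c(rep(0, n), rep(1, m))
  r1 <- .simplexIter(Tb, c1, basis, tol)
  if (r1$status != "optimal") return(list(status = "infeasible"))
  val1 <- sum(c1[r1$basis] * r1$Tb[, ncol(r1$Tb)])
  if (val1 > 1e-7) return(list(status = "infeasible"))
  Tb <- r1$Tb; basis <- r1$basis
  # drive remaining artificials out or drop redundant rows
  drop <- integer(0)
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      cand <- which(abs(Tb[i, seq_len(n)]) > tol)
      if (length(cand)) {
        up <- .simplexPivot(Tb, basis, i, min(cand))
        Tb <- up$Tb; basis <- up$basis
      } else drop <- c(drop, i)
    }
  }
  if (length(drop)) {
    Tb <- Tb[-drop, , drop = FALSE]
    basis <- basis[-drop]
  }
  Tb <- Tb[, c(seq_len(n), ncol(Tb)), drop = FALSE]
  r2 <- .simplexIter(Tb, cost, basis, tol)
  if (r2$status != "optimal") return(list(status = r2$status))
  x <- numeric(n)
  x[r2$basis] <- r2$Tb[, n + 1L]
  list(status = "optimal", x = x,
       value = if (maximise) sum(c0 * x) else sum(c0 * x))
}
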