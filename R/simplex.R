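# Two-phase primal simplex for the envelopment LPs.
#
# DEA programs are small (tens of variables, under ten rows) but heavily
# degenerate: feasible regions can collapse to a point and basic solutions
# carry many zero-valued basic variables.  General-purpose dense solvers
# that pivot by steepest reduced cost can hit 0/0 ratio tests there; this
# implementation uses Bland's rule (lowest-index entering and leaving
# candidates), which cannot cycle, and an explicit tolerance on every
# comparison.  Solves min c'x  s.t.  Ax = b, x >= 0, with b >= 0 required.

.pivot <- function(tab, r, j) {
  prow <- tab[r, ] / tab[r, j]
  tab <- tab - outer(tab[, j], prow)
  tab[r, ] <- prow
  tab
}

# tab: m x (nv+1) tableau, last column the RHS, rows expressed in the
# current basis. Returns the optimal tableau/basis for objective obj.
.simplex_core <- function(tab, basis, obj, nv, tol = 1e-9, max_iter = 5000L) {
  for (it in seq_len(max_iter)) {
    cb <- obj[basis]
    red <- obj[seq_len(nv)] -
      as.vector(crossprod(tab[, seq_len(nv), drop = FALSE], cb))
    red[basis] <- 0
    ent <- which(red < -tol)
    if (!length(ent))
      return(list(tab = tab, basis = basis, status = "optimal",
                  value = sum(cb * tab[, nv + 1])))
    j <- ent[1L]                               # Bland: lowest index enters
    col <- tab[, j]
    rows <- which(col > tol)
    if (!length(rows))
      return(list(tab = tab, basis = basis, status = "unbounded",
                  value = -Inf))
    ratios <- tab[rows, nv + 1] / col[rows]
    rmin <- min(ratios)
    cand <- rows[ratios <= rmin + tol * max(1, abs(rmin))]
    r <- cand[which.min(basis[cand])]          # Bland: lowest basis leaves
    tab <- .pivot(tab, r, j)
    basis[r] <- j
  }
  list(tab = tab, basis = basis, status = "maxiter", value = NA_real_)
}

.simplex_solve <- function(cc, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(all(b >= -tol))
  b <- pmax(b, 0)
  # phase I: artificial basis
  tab <- cbind(A, diag(m), b, deparse.level = 0)
  basis <- n + seq_len(m)
  p1 <- .simplex_core(tab, basis, c(rep(0, n), rep(1, m)), n + m, tol)
  if (p1$status != "optimal" || p1$value > 1e-7)
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  tab <- p1$tab; basis <- p1$basis
  # pivot lingering zero-valued artificials out of the basis
  for (r in which(basis > n)) {
    piv <- which(abs(tab[r, seq_len(n)]) > tol)
    if (length(piv)) {
      tab <- .pivot(tab, r, piv[1L])
      basis[r] <- piv[1L]
    }
  }
  keep <- basis <= n                    # remaining artificial rows are redundant
  tab <- tab[keep, c(seq_len(n), n + m + 1L), drop = FALSE]
  basis <- basis[keep]
  p2 <- .simplex_core(tab, basis, cc, n, tol)
  if (p2$status != "optimal")
    return(list(status = p2$status, x = NULL, value = NA_real_))
  x <- numeric(n)
  x[p2$basis] <- p2$tab[, n + 1L]
  x[x < 0] <- 0                         # clip numerical dust
  list(status = "optimal", x = x, value = sum(cc * x))
}
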