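# Independent brute-force oracle for the output-oriented VRS program:
# maximises phi(lambda) = min_r (sum_j lambda_j y_rj) / y_rk over the peer
# simplex subject to sum_j lambda_j x_ij <= x_ik, by exhaustive grid search
# with local refinement.  phi(lambda) is concave on a convex feasible set,
# so shrinking refinement around the coarse-grid optimum converges to the
# global maximum.  Shares no code with the LP path in the package.

simplex_grid <- function(n, N) {
  # all compositions of N into n nonnegative parts, divided by N
  if (n == 1) return(matrix(1, 1, 1))
  rows <- list()
  rec <- function(prefix, remaining, slots) {
    if (slots == 1) {
      rows[[length(rows) + 1L]] <<- c(prefix, remaining)
      return(invisible())
    }
    for (v in 0:remaining) rec(c(prefix, v), remaining - v, slots - 1)
  }
  rec(integer(0), N, n)
  do.call(rbind, rows) / N
}

phi_eval <- function(lam, Xm, Ym, k) {
  if (any(drop(crossprod(Xm, lam)) > Xm[k, ] + 1e-12)) return(-Inf)
  min(drop(crossprod(Ym, lam)) / Ym[k, ])
}

phi_oracle <- function(Xm, Ym, k, coarse_N = 20, refine_N = 8, levels = 7) {
  n <- nrow(Xm)
  grid <- simplex_grid(n, coarse_N)
  vals <- apply(grid, 1, phi_eval, Xm = Xm, Ym = Ym, k = k)
  best <- grid[which.max(vals), ]
  bestval <- max(vals)
  width <- 1
  local <- simplex_grid(n, refine_N)
  centre <- rep(1 / n, n)
  for (l in seq_len(levels)) {
    cand <- sweep(sweep(local, 2, centre) * width, 2, best, `+`)
    cand[cand < 0] <- 0
    cand <- cand / rowSums(cand)
    vals <- apply(cand, 1, phi_eval, Xm = Xm, Ym = Ym, k = k)
    if (max(vals) > bestval) {
      bestval <- max(vals)
      best <- cand[which.max(vals), ]
    }
    width <- width / 2.5
  }
  bestval
}
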