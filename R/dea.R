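#' Output-oriented, variable-returns-to-scale DEA for one unit
#'
#' Solves the envelopment (primal) linear program for one decision-making
#' unit against a reference set. With needs `x` as inputs and services `y` as
#' outputs, the program finds the largest radial expansion `phi` of the
#' target's services that a convex combination of observed units can deliver
#' without exceeding the target's needs:
#'
#' \deqn{\max \phi \quad s.t. \quad \sum_j \lambda_j x_j \le x_0,\;
#'       \sum_j \lambda_j y_j \ge \phi\, y_0,\; \sum_j \lambda_j = 1,\;
#'       \lambda \ge 0.}
#'
#' The convexity constraint on the peer weights gives variable returns to
#' scale. A second phase fixes `phi` at its optimum and maximises the total
#' input and output slack, so the reported peer target is the Pareto-optimal
#' frontier point. The equity index is `1/phi`: 1 on the frontier, below 1
#' for units whose service coverage falls short of what peers with no
#' greater needs achieve.
#'
#' Feasibility is guaranteed (the unit can always reference itself, giving
#' `phi = 1`), and the solve is deterministic for a fixed unit ordering. Peer
#' weights need not be unique at the optimum; only `phi`, the equity index,
#' and the projected service vector are contractual.
#'
#' @param dataset a [dmu_dataset()].
#' @param dmu the target unit: a `dmu_id` string or an index.
#' @param needs,services optional character vectors selecting a subset of
#'   need / service columns; default is all columns.
#' @param two_phase if `TRUE` (default) run the slack-maximising second
#'   phase; `FALSE` reports residual slacks of the first-phase solution.
#' @return An object of class `dea_fit` with elements `dmu_id`, `phi`, `ei`,
#'   `lambda` (named peer weights), `input_slacks`, `output_slacks`,
#'   `projected` (peer-combined services for the selected subset),
#'   `effective` (observed services), `on_frontier`, `degenerate`, and the
#'   selected variable names.
#' @examples
#' d <- dmu_dataset(c("A", "B", "C"),
#'                  needs = cbind(x = c(1, 2, 2)),
#'                  services = cbind(y = c(1, 4, 2)))
#' dea(d, "C")  # phi = 2: peers deliver double C's service at C's need level
#' @seealso [mdea()] for the subset-ensemble index, [peer_target()]
#' @export
dea <- function(dataset, dmu, needs = NULL, services = NULL, two_phase = TRUE) {
  stopifnot(inherits(dataset, "dmu_dataset"))
  k <- if (is.character(dmu)) match(dmu, dataset$dmu_id) else as.integer(dmu)
  if (is.na(k) || k < 1 || k > length(dataset$dmu_id))
    stop("unknown dmu: ", dmu, call. = FALSE)
  if (is.null(needs)) needs <- dataset$needs_names
  if (is.null(services)) services <- dataset$services_names
  if (!length(needs) || !length(services))
    stop("needs and services subsets must be non-empty", call. = FALSE)
  if (length(bad <- setdiff(needs, dataset$needs_names)))
    stop("unknown need column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (length(bad <- setdiff(services, dataset$services_names)))
    stop("unknown service column(s): ", paste(bad, collapse = ", "), call. = FALSE)

  X <- dataset$needs[, needs, drop = FALSE]
  Y <- dataset$services[, services, drop = FALSE]
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  x0 <- X[k, ]; y0 <- Y[k, ]
  id <- dataset$dmu_id

  if (all(y0 == 0)) {
    # no radial expansion of a zero service vector is defined
    res <- list(dmu_id = id[k], phi = Inf, ei = 0,
                lambda = stats::setNames(numeric(n), id),
                input_slacks = stats::setNames(rep(NA_real_, m), needs),
                output_slacks = stats::setNames(rep(NA_real_, s), services),
                projected = stats::setNames(rep(NA_real_, s), services),
                effective = y0, on_frontier = FALSE, degenerate = TRUE,
                needs = needs, services = services)
    return(structure(res, class = "dea_fit"))
  }

  # phase 1: max phi over (lambda, phi, slacks), envelopment equalities
  A <- rbind(
    cbind(t(X), 0, diag(m), matrix(0, m, s)),
    cbind(t(Y), -y0, matrix(0, s, m), -diag(s)),
    c(rep(1, n), rep(0, 1 + m + s))
  )
  b <- c(x0, rep(0, s), 1)
  p1 <- .simplex_solve(c(rep(0, n), -1, rep(0, m + s)), A, b)
  if (p1$status != "optimal")
    stop("LP solve failed on dmu ", id[k], " (phase 1: ", p1$status, ")",
         call. = FALSE)
  phi <- -p1$value
  if (abs(phi - 1) <= 1e-9) phi <- 1   # frontier snap at solver tolerance
  lambda <- p1$x[seq_len(n)]

  if (two_phase) {
    p2 <- .dea_phase2(X, Y, x0, y0, phi)
    if (!is.null(p2)) {
      lambda <- p2$lambda
      sin_ <- p2$sin; sout <- p2$sout
    } else {
      sin_ <- pmax(x0 - drop(crossprod(X, lambda)), 0)
      sout <- pmax(drop(crossprod(Y, lambda)) - phi * y0, 0)
    }
  } else {
    sin_ <- pmax(x0 - drop(crossprod(X, lambda)), 0)
    sout <- pmax(drop(crossprod(Y, lambda)) - phi * y0, 0)
  }
  lambda[lambda < 1e-10] <- 0
  lambda <- lambda / sum(lambda)
  projected <- phi * y0 + sout
  tol <- 1e-6
  structure(list(
    dmu_id = id[k], phi = phi, ei = equity_index(phi),
    lambda = stats::setNames(lambda, id),
    input_slacks = stats::setNames(sin_, needs),
    output_slacks = stats::setNames(sout, services),
    projected = stats::setNames(projected, services),
    effective = y0, on_frontier = phi <= 1 + tol && all(sin_ <= tol) &&
      all(sout <= tol),
    degenerate = FALSE, needs = needs, services = services
  ), class = "dea_fit")
}

# phase 2: at fixed phi, maximise total slack subject to the envelopment
# equalities.  phi is backed off by a whisker if the fixed value is
# infeasible at the solver's tolerance.
.dea_phase2 <- function(X, Y, x0, y0, phi) {
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  cc <- c(rep(0, n), rep(-1, m + s))
  A <- rbind(
    cbind(t(X), diag(m), matrix(0, m, s)),
    cbind(t(Y), matrix(0, s, m), -diag(s)),
    c(rep(1, n), rep(0, m + s))
  )
  for (shrink in c(1, 1 - 1e-10, 1 - 1e-8)) {
    b <- c(x0, phi * shrink * y0, 1)
    p <- .simplex_solve(cc, A, b)
    if (p$status == "optimal")
      return(list(lambda = p$x[seq_len(n)],
                  sin = p$x[n + seq_len(m)],
                  sout = p$x[n + m + seq_len(s)]))
  }
  NULL
}

#' Equity index from a radial expansion factor
#'
#' The equity index is the reciprocal of the output-expansion factor:
#' `ei = 1/phi`, equal to 1 on the frontier and measuring the relative
#' deficit in service coverage below it (a unit with `ei = 0.5` receives
#' half of what the frontier says it could, given its needs).
#'
#' @param phi radial expansion factor, `phi >= 1`.
#' @return `1/phi`, in (0, 1].
#' @examples
#' equity_index(1)   # frontier
#' equity_index(2)   # half coverage
#' @export
equity_index <- function(phi) {
  if (any(!is.finite(phi) & !is.infinite(phi)))
    stop("phi must be numeric", call. = FALSE)
  if (any(phi < 1 - 1e-9))
    stop("phi must be >= 1 (radial expansion factor)", call. = FALSE)
  pmin(1 / phi, 1)
}

#' Projected (frontier) service vector of a solved unit
#'
#' The peer target is the frontier point the unit is compared against:
#' radial expansion of its observed services plus any remaining output
#' slack, equal to the peer-weighted combination of observed services. It is
#' the "optimal" transfer value the unit would need to sit on the equity
#' frontier; it never falls below the observed value.
#'
#' @param fit a `dea_fit` from [dea()].
#' @return named numeric vector of projected services (selected subset).
#' @export
peer_target <- function(fit) {
  stopifnot(inherits(fit, "dea_fit"))
  fit$projected
}

#' @export
print.dea_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("DEA (output-oriented, VRS) for %s: degenerate (all-zero services), ei = 0\n",
                x$dmu_id))
    return(invisible(x))
  }
  cat(sprintf("DEA (output-oriented, VRS) for %s\n", x$dmu_id))
  cat(sprintf("  phi = %.6f, equity index = %.6f%s\n", x$phi, x$ei,
              if (x$on_frontier) " (on frontier)" else ""))
  peers <- x$lambda[x$lambda > 1e-8]
  cat("  peers:", paste(sprintf("%s (%.3f)", names(peers), peers),
                        collapse = ", "), "\n")
  invisible(x)
}
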