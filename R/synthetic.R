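#' Simulate state-level needs/services data with a planted frontier
#'
#' Generates a dataset shaped like the 2013 Brazilian state table — five
#' right-skewed need indicators and two service (transfer) variables — with
#' a known efficiency frontier, so the whole pipeline can be validated
#' against planted truth.
#'
#' Frontier units draw needs log-normally (per-variable location/spread
#' chosen to match the bundled descriptive table in order of magnitude) and
#' receive services as a concave increasing function of an aggregate need
#' score, so that no convex combination of frontier units can dominate
#' another (they all sit on the frontier). Every non-frontier unit copies a
#' frontier anchor's needs, jittered multiplicatively upward by at most
#' `jitter` (default 1%), and receives the frontier services at its own
#' jittered needs scaled by a planted radial inefficiency `true_u` drawn
#' uniformly from `inefficiency_range`. Because the jitter is upward, the
#' anchor always remains a feasible peer, making `true_u` identifiable: the
#' full-model equity index of a scaled unit equals `true_u` up to a term of
#' order `jitter` (exactly when `jitter = 0`), and a unit with `true_u = 1`
#' lies exactly on the frontier.
#'
#' @param n_dmus number of units (>= 3); default 27 (26 states + the
#'   Federal District).
#' @param n_frontier number of planted-efficient units (>= 2); default 5.
#' @param inefficiency_range interval within (0, 1] for `true_u`; default
#'   `c(0.6, 1)`, matching the spread of published state-level indices.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @param frontier_shape `"concave_power"` (default, exponent 0.6) or
#'   `"linear"` mapping aggregate need to services.
#' @param needs_meanlog,needs_sdlog per-variable log-normal parameters
#'   (length 5); defaults give medians near 1200, 340, 240, 980, 0.4 with
#'   heavier skew on the prevalence counts.
#' @param jitter maximum upward multiplicative perturbation of copied needs;
#'   default 0.01. Larger values void the exact-recovery guarantee.
#' @return list with `dataset` (a [dmu_dataset()]) and `truth` (data.frame
#'   with `dmu_id`, `true_u`, `is_frontier`, `anchor`).
#' @examples
#' sim <- simulate_states(n_dmus = 6, n_frontier = 3, seed = 1)
#' sim$truth
#' @seealso [simulate_pharmacy_ratio()]
#' @export
simulate_states <- function(n_dmus = 27, n_frontier = 5,
                            inefficiency_range = c(0.6, 1), seed = 1,
                            frontier_shape = c("concave_power", "linear"),
                            needs_meanlog = log(c(1200, 340, 240, 980, 0.4)),
                            needs_sdlog = c(1, 1, 1, 0.4, 0.8),
                            jitter = 0.01) {
  frontier_shape <- match.arg(frontier_shape)
  stopifnot(n_dmus >= 3, n_frontier >= 2, n_frontier <= n_dmus,
            length(inefficiency_range) == 2,
            inefficiency_range[1] <= inefficiency_range[2],
            inefficiency_range[1] > 0, inefficiency_range[2] <= 1,
            jitter >= 0, length(needs_meanlog) == 5, length(needs_sdlog) == 5)
  set.seed(as.integer(seed))
  m <- 5
  needs_names <- c("hypertension_thousands", "diabetics_thousands",
                   "asthmatics_thousands", "elderly_thousands",
                   "negative_income_index")
  ids <- sprintf("S%02d", seq_len(n_dmus))
  front_ids <- seq_len(n_frontier)

  # frontier needs, drawn per variable
  Xf <- sapply(seq_len(m), function(j)
    stats::rlnorm(n_frontier, needs_meanlog[j], needs_sdlog[j]))
  Xf <- matrix(Xf, n_frontier, m)

  # aggregate need score: arithmetic mean of needs normalised by their
  # per-variable median scale; linear in X, so the aggregate of a convex
  # peer combination never exceeds the target's own aggregate
  agg <- function(X) {
    Z <- sweep(X, 2, exp(needs_meanlog), "/")
    rowSums(Z) / m
  }
  g <- function(a) {
    p <- if (frontier_shape == "concave_power") 0.6 else 1
    cbind(bppp_value_millions = 120 * a^p,
          bcpa_value_millions = 60 * a^p)
  }
  Yf <- g(agg(Xf))

  X <- matrix(NA_real_, n_dmus, m, dimnames = list(ids, needs_names))
  Y <- matrix(NA_real_, n_dmus, 2)
  colnames(Y) <- colnames(Yf)
  true_u <- rep(1, n_dmus)
  anchor <- rep(NA_character_, n_dmus)
  X[front_ids, ] <- Xf
  Y[front_ids, ] <- Yf
  if (n_dmus > n_frontier) {
    scaled <- (n_frontier + 1):n_dmus
    anc <- rep_len(front_ids, length(scaled))
    u <- stats::runif(length(scaled), inefficiency_range[1],
                      inefficiency_range[2])
    jit <- matrix(stats::runif(length(scaled) * m, 1, 1 + jitter),
                  length(scaled), m)
    X[scaled, ] <- Xf[anc, , drop = FALSE] * jit
    # services sit on the frontier curve at the unit's own (jittered) needs,
    # scaled down by the planted inefficiency: a unit with true_u = 1 is
    # exactly efficient, and with jitter = 0 the full-model equity index
    # recovers true_u exactly
    Y[scaled, ] <- g(agg(X[scaled, , drop = FALSE])) * u
    true_u[scaled] <- u
    anchor[scaled] <- ids[anc]
  }
  list(
    dataset = dmu_dataset(ids, X, Y),
    truth = data.frame(dmu_id = ids, true_u = true_u,
                       is_frontier = seq_len(n_dmus) <= n_frontier,
                       anchor = anchor, row.names = NULL)
  )
}

#' Simulate an accredited-pharmacy share correlated with planted inefficiency
#'
#' Produces a per-unit covariate `ratio = clip(a + slope * (1 - true_u) +
#' noise, 0, 1)` with the intercept `a` chosen so the ratios centre at 0.4
#' (roughly the national average adhesion of private pharmacies). With a
#' negative slope, units with larger planted coverage deficits have fewer
#' accredited pharmacies, emulating the empirical dispersion pattern.
#'
#' @param truth the `truth` data.frame from [simulate_states()].
#' @param slope linear effect of the deficit `1 - true_u`; default -0.5.
#' @param noise_sd Gaussian noise SD (>= 0); default 0.02.
#' @param seed integer seed.
#' @return named numeric vector of ratios in `[0, 1]`.
#' @export
simulate_pharmacy_ratio <- function(truth, slope = -0.5, noise_sd = 0.02,
                                    seed = 1) {
  stopifnot(noise_sd >= 0, all(c("dmu_id", "true_u") %in% names(truth)))
  set.seed(as.integer(seed))
  deficit <- 1 - truth$true_u
  a <- 0.4 - slope * mean(deficit)
  raw <- a + slope * deficit + stats::rnorm(nrow(truth), 0, noise_sd)
  stats::setNames(pmin(pmax(raw, 0), 1), truth$dmu_id)
}
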