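test_that("toy instance solves to the values found by exhaustive search", {
  d <- toy_abc()
  # frozen oracle values: C is dominated by B (x=2, y=4), so phi=2, ei=0.5;
  # A and B are on the frontier
  fC <- dea(d, "C")
  expect_equal(fC$phi, 2, tolerance = 1e-9)
  expect_equal(fC$ei, 0.5, tolerance = 1e-9)
  expect_equal(unname(fC$lambda["B"]), 1, tolerance = 1e-9)
  expect_equal(unname(fC$projected), 4, tolerance = 1e-9)
  expect_equal(dea(d, "A")$ei, 1, tolerance = 1e-9)
  expect_equal(dea(d, "B")$ei, 1, tolerance = 1e-9)
  expect_true(dea(d, "B")$on_frontier)
  # cross-check against the independent grid oracle
  expect_equal(fC$phi, phi_oracle(d$needs, d$services, 3), tolerance = 1e-3)
})

test_that("self-reference and convex-hull edge cases", {
  single <- dmu_dataset("A", cbind(x = 3), cbind(y = 2))
  f <- dea(single, "A")
  expect_equal(f$phi, 1, tolerance = 1e-9)
  expect_equal(unname(f$lambda["A"]), 1)
  expect_true(f$on_frontier)

  # duplicating an efficient unit changes nothing
  d <- toy_abc()
  d2 <- dmu_dataset(c(d$dmu_id, "B2"),
                    rbind(d$needs, 2), rbind(d$services, 4))
  expect_equal(dea(d2, "B")$ei, 1, tolerance = 1e-9)
  expect_equal(dea(d2, "B2")$ei, 1, tolerance = 1e-9)
  expect_equal(dea(d2, "C")$ei, dea(d, "C")$ei, tolerance = 1e-9)
  expect_equal(dea(d2, "A")$ei, dea(d, "A")$ei, tolerance = 1e-9)
})

test_that("solver agrees with the grid oracle on randomized small instances", {
  for (seed in 1:20) {
    n <- sample(2:5, 1)
    m <- sample(1:2, 1)
    s <- sample(1:2, 1)
    d <- random_instance(seed * 100 + n, n = n, m = m, s = s)
    k <- sample(n, 1)
    phi_lp <- dea(d, k)$phi
    phi_gs <- phi_oracle(d$needs, d$services, k)
    expect_equal(phi_lp, phi_gs, tolerance = 1e-3,
                 label = sprintf("phi (seed %d, n=%d m=%d s=%d k=%d)",
                                 seed, n, m, s, k))
  }
})

test_that("solution satisfies the envelopment constraints and VRS convexity", {
  for (seed in 1:5) {
    d <- random_instance(seed, n = 6, m = 3, s = 2)
    for (k in seq_len(6)) {
      f <- dea(d, k)
      expect_gte(f$phi, 1 - 1e-9)
      expect_equal(sum(f$lambda), 1, tolerance = 1e-7)
      peer_in <- drop(crossprod(d$needs, f$lambda))
      peer_out <- drop(crossprod(d$services, f$lambda))
      expect_true(all(peer_in <= d$needs[k, ] + 1e-7))
      expect_true(all(peer_out >= f$phi * d$services[k, ] - 1e-7))
      expect_true(all(f$projected >= f$phi * d$services[k, ] - 1e-7))
      expect_equal(f$ei, 1 / f$phi, tolerance = 1e-12)
    }
  }
})

test_that("units invariance: rescaling any one column leaves ei unchanged", {
  d <- random_instance(42, n = 6, m = 3, s = 2)
  base <- vapply(1:6, function(k) dea(d, k)$ei, numeric(1))
  for (cfg in list(list(col = "x2", c = 1000), list(col = "y1", c = 0.004))) {
    needs <- d$needs; services <- d$services
    if (cfg$col %in% colnames(needs)) needs[, cfg$col] <- needs[, cfg$col] * cfg$c
    else services[, cfg$col] <- services[, cfg$col] * cfg$c
    ds <- dmu_dataset(d$dmu_id, needs, services)
    scaled <- vapply(1:6, function(k) dea(ds, k)$ei, numeric(1))
    expect_equal(scaled, base, tolerance = 1e-9)
  }
})

test_that("reference-set monotonicity and frontier existence", {
  for (seed in 1:8) {
    d <- random_instance(seed + 300, n = 5, m = 2, s = 2)
    ei5 <- vapply(1:5, function(k) dea(d, k)$ei, numeric(1))
    # at least one unit on the frontier
    expect_gte(max(ei5), 1 - 1e-9)
    # adding a unit never increases anyone's ei
    set.seed(seed + 900)
    d6 <- dmu_dataset(c(d$dmu_id, "NEW"),
                      rbind(d$needs, runif(2, 0.5, 10)),
                      rbind(d$services, runif(2, 0.5, 10)))
    ei6 <- vapply(1:5, function(k) dea(d6, k)$ei, numeric(1))
    expect_true(all(ei6 <= ei5 + 1e-9))
  }
  # removing a unit with zero peer weight everywhere changes nothing
  d <- toy_abc()
  fits <- lapply(1:3, function(k) dea(d, k))
  wC <- vapply(fits, function(f) unname(f$lambda["C"]), numeric(1))
  expect_true(all(wC < 1e-9))
  dAB <- d[c("A", "B")]
  expect_equal(dea(dAB, "A")$ei, fits[[1]]$ei, tolerance = 1e-9)
  expect_equal(dea(dAB, "B")$ei, fits[[2]]$ei, tolerance = 1e-9)
})

test_that("dimension monotonicity: enlarging variable subsets never lowers ei", {
  d <- random_instance(7, n = 6, m = 3, s = 2)
  for (k in 1:6) {
    e_small <- dea(d, k, needs = "x1", services = "y1")$ei
    e_mid <- dea(d, k, needs = c("x1", "x2"), services = "y1")$ei
    e_full <- dea(d, k)$ei
    expect_lte(e_small, e_mid + 1e-9)
    expect_lte(e_mid, e_full + 1e-9)
  }
})

test_that("equity_index contract and printed round trip", {
  expect_equal(equity_index(1), 1)
  expect_equal(equity_index(2), 0.5)
  expect_equal(equity_index(1 / 0.6788), 0.6788, tolerance = 1e-12)
  expect_error(equity_index(0.9), ">= 1")
})

test_that("all-zero selected services yields flagged ei = 0", {
  d <- dmu_dataset(c("Z", "B"), cbind(x = c(1, 2)), cbind(y = c(0, 3)))
  f <- dea(d, "Z")
  expect_true(f$degenerate)
  expect_equal(f$ei, 0)
  expect_false(f$on_frontier)
})

test_that("selecting a missing column errors with its name", {
  d <- toy_abc()
  expect_error(dea(d, "A", needs = "nope"), "nope")
  expect_error(dea(d, "A", needs = character(0)), "non-empty")
})
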