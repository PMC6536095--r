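# shared toy instances

toy_abc <- function() {
  # 1 need, 1 service; B dominates C, A anchors the lower scale
  dmu_dataset(c("A", "B", "C"),
              needs = cbind(x = c(1, 2, 2)),
              services = cbind(y = c(1, 4, 2)))
}

random_instance <- function(seed, n = 4, m = 2, s = 2) {
  set.seed(seed)
  dmu_dataset(sprintf("D%d", seq_len(n)),
              needs = matrix(runif(n * m, 0.5, 10), n, m,
                             dimnames = list(NULL, paste0("x", seq_len(m)))),
              services = matrix(runif(n * s, 0.5, 10), n, s,
                                dimnames = list(NULL, paste0("y", seq_len(s)))))
}

write_state_csv <- function(path, n = 27, seed = 1) {
  sim <- simulate_states(n_dmus = n, n_frontier = 5, seed = seed)
  write_dmu_dataset(sim$dataset, path)
  sim
}
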