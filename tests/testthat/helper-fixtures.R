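# Shared fixtures for the test suite. All randomness is seeded.

# Published parameter pairs used throughout: disulfide substrate, persulfide
# branch, free-H2S branch (Km uM, Vmax nmol/min/mg).
truth_na2s2 <- function() mm_truth(km = 331, vmax = 260)
truth_gss <- function() mm_truth(km = 209, vmax = 392)
truth_h2s <- function() mm_truth(km = 1978, vmax = 5.37)

# Planted PIE fixture: k clusters with well-separated total-PIE means.
planted_pie <- function(k, n_fragments = 10, per_cluster = 15,
                        sep = 40, within_sd = 1, seed = 42) {
  profiles <- lapply(seq_len(k), function(i) {
    rep(-i * sep / n_fragments, n_fragments)
  })
  gen_pie_matrix(pie_cluster_spec(profiles, rep(per_cluster, k),
                                  within_sd = within_sd, seed = seed))
}

# Geometry table built directly (bypasses coordinates) for filter tests.
geom_table <- function(d1, theta, phi) {
  n <- max(length(d1), length(theta), length(phi))
  data.frame(frame = seq_len(n), d1 = rep_len(d1, n), d2 = rep_len(d1, n) + 1,
             d_diff = -1, theta = rep_len(theta, n),
             theta2 = rep_len(theta, n), phi = rep_len(phi, n))
}

expect_same_partition <- function(a, b) {
  # identical partitions up to label renaming
  expect_equal(length(a), length(b))
  map_ab <- tapply(b, a, function(x) length(unique(x)))
  map_ba <- tapply(a, b, function(x) length(unique(x)))
  expect_true(all(map_ab == 1) && all(map_ba == 1))
}
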