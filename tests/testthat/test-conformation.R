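test_that("per-conformation totals and fragment profiles match brute-force sums", {
  expect_equal(unname(total_pie_per_conformation(
    pie_matrix(matrix(0, 3, 4)))), rep(0, 3))
  expect_equal(unname(total_pie_per_conformation(
    pie_matrix(matrix(c(-10, -5, 1), 1, 3)))), -14)

  set.seed(8)
  m <- pie_matrix(matrix(rnorm(20 * 15), 20, 15))
  # element-by-element oracle
  oracle <- vapply(1:20, function(i) {
    s <- 0
    for (j in 1:15) s <- s + unclass(m)[i, j]
    s
  }, numeric(1))
  expect_equal(unname(total_pie_per_conformation(m)), oracle, tolerance = 1e-12)

  prof <- fragment_pie_profile(m)
  oracle_cols <- vapply(1:15, function(j) sum(unclass(m)[, j]), numeric(1))
  expect_equal(unname(prof), oracle_cols, tolerance = 1e-12)
  # conservation: fragment sums and conformation sums agree
  expect_equal(sum(prof), sum(total_pie_per_conformation(m)),
               tolerance = 1e-9 * abs(sum(prof)) + 1e-12)
})

test_that("fragment profile over a planted cluster equals its mean profile", {
  spec <- pie_cluster_spec(list(c(-8, -2, -1), c(-1, 0, 0)), c(4, 5),
                           within_sd = 0, seed = 3)
  g <- gen_pie_matrix(spec)
  prof <- fragment_pie_profile(g$matrix, labels = g$true_labels, cluster = 1,
                               average = TRUE)
  expect_equal(unname(prof), c(-8, -2, -1))
  expect_error(fragment_pie_profile(g$matrix, labels = g$true_labels,
                                    cluster = 99), "unknown cluster")
  expect_error(fragment_pie_profile(g$matrix, cluster = 1), "labels")
})

test_that("well-separated planted clusters are recovered exactly", {
  skip_if_not_installed("mclust")
  for (k in c(3, 6, 9)) {
    g <- planted_pie(k, sep = 60, within_sd = 1, seed = 100 + k)
    res <- cluster_conformations(g$matrix, n_clusters = k)
    ari <- mclust::adjustedRandIndex(res$labels, g$true_labels)
    expect_equal(ari, 1)
    # automatic dendrogram-gap rule finds the same partition
    auto <- cluster_conformations(g$matrix)
    expect_equal(mclust::adjustedRandIndex(auto$labels, g$true_labels), 1)
  }
})

test_that("clustering is invariant to row order and positive energy rescaling", {
  g <- planted_pie(4, sep = 50, seed = 77)
  res <- cluster_conformations(g$matrix, n_clusters = 4)

  set.seed(5)
  perm <- sample(nrow(g$matrix))
  mp <- pie_matrix(unclass(g$matrix)[perm, ], rownames(g$matrix)[perm])
  res_p <- cluster_conformations(mp, n_clusters = 4)
  expect_same_partition(res$labels[perm], res_p$labels)

  ms <- pie_matrix(unclass(g$matrix) * 3.7, rownames(g$matrix))
  res_s <- cluster_conformations(ms, n_clusters = 4)
  expect_same_partition(res$labels, res_s$labels)

  expect_error(cluster_conformations(g$matrix, n_clusters = 1000),
               "n_clusters")
  expect_error(cluster_conformations(g$matrix, n_clusters = 2, cut_height = 1),
               "at most one")
})

test_that("identical rows collapse to a single cluster", {
  m <- pie_matrix(matrix(-2, 6, 3))
  res <- cluster_conformations(m, n_clusters = 1)
  expect_true(all(res$labels == 1))
})

test_that("two-group studentized-range statistic matches hand computation", {
  g1 <- c(-102, -98, -101, -99, -100)
  g2 <- c(-90, -92, -88, -91)
  tk <- tukey_kramer(list(a = g1, b = g2), alpha = 0.05)
  n1 <- length(g1); n2 <- length(g2)
  s2 <- (sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)) / (n1 + n2 - 2)
  q_hand <- abs(mean(g1) - mean(g2)) / sqrt(s2 / 2 * (1 / n1 + 1 / n2))
  expect_equal(tk$table$q_statistic, q_hand, tolerance = 1e-12)
  # rejection agrees with the tabulated critical value of the studentized range
  q_crit <- qtukey(0.95, nmeans = 2, df = n1 + n2 - 2)
  expect_identical(tk$table$reject, q_hand > q_crit)
  expect_equal(tk$df, n1 + n2 - 2)
})

test_that("pairwise p-values agree with the base-R Tukey HSD oracle", {
  set.seed(12)
  vals <- c(rnorm(8, -100, 3), rnorm(5, -95, 3), rnorm(10, -80, 3))
  grp <- factor(rep(c("g1", "g2", "g3"), c(8, 5, 10)))
  tk <- tukey_kramer(split(vals, grp), alpha = 0.05)
  hsd <- TukeyHSD(aov(vals ~ grp))$grp
  for (r in seq_len(nrow(tk$table))) {
    key_ab <- paste0(tk$table$cluster_b[r], "-", tk$table$cluster_a[r])
    key_ba <- paste0(tk$table$cluster_a[r], "-", tk$table$cluster_b[r])
    key <- if (key_ab %in% rownames(hsd)) key_ab else key_ba
    expect_equal(tk$table$p_adjusted[r], unname(hsd[key, "p adj"]),
                 tolerance = 1e-6)
  }
})

test_that("compact letters are a valid cover of the pairwise decisions", {
  set.seed(23)
  for (rep in 1:10) {
    k <- sample(3:6, 1)
    means <- sort(runif(k, -120, -60))
    groups <- lapply(means, function(m) rnorm(sample(4:8, 1), m, 6))
    names(groups) <- paste0("c", seq_len(k))
    tk <- tukey_kramer(groups, alpha = 0.05)
    share <- function(a, b) {
      la <- strsplit(tk$letters[[a]], "")[[1]]
      lb <- strsplit(tk$letters[[b]], "")[[1]]
      length(intersect(la, lb)) > 0
    }
    for (r in seq_len(nrow(tk$table))) {
      a <- tk$table$cluster_a[r]; b <- tk$table$cluster_b[r]
      expect_identical(!share(a, b), tk$table$reject[r])
    }
    expect_true(all(nchar(tk$letters) >= 1))
  }
})

test_that("letter display spans the extremes correctly", {
  # identical constant groups: a single shared letter
  tk_same <- tukey_kramer(list(a = c(-5, -5, -5), b = c(-5, -5, -5)), 0.05)
  expect_identical(unname(tk_same$letters), c("a", "a"))
  # zero variance with unequal means: all pairs rejected
  tk_det <- tukey_kramer(list(a = c(-5, -5), b = c(-7, -7)), 0.05)
  expect_true(all(tk_det$table$reject))
  # huge separation: three distinct letters ordered by ascending mean
  tk3 <- tukey_kramer(list(hi = rnorm(5, 0, 0.1), lo = rnorm(5, -200, 0.1),
                           mid = rnorm(5, -100, 0.1)), 0.05)
  expect_setequal(unname(tk3$letters), c("a", "b", "c"))
  expect_identical(unname(tk3$letters["lo"]), "a")
  expect_identical(unname(tk3$letters["hi"]), "c")
  expect_error(tukey_kramer(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("family-wise type-I error of the all-pairs test is controlled", {
  set.seed(99)
  k <- 5; n <- 6; alpha <- 0.05
  reps <- 1000
  rejections <- vapply(seq_len(reps), function(i) {
    groups <- split(rnorm(k * n, -100, 5), rep(seq_len(k), each = n))
    any(tukey_kramer(groups, alpha = alpha)$table$reject)
  }, logical(1))
  fwer <- mean(rejections)
  mc_se <- sqrt(alpha * (1 - alpha) / reps)
  expect_lte(fwer, alpha + 3 * mc_se)
})

test_that("stable-cluster selection returns the strongest indistinguishable group", {
  stats_df <- data.frame(cluster = 1:3, n = 5, mean = c(-120, -80, -119), sd = 2)
  res <- list(per_cluster_stats = stats_df)
  # one strictly strongest cluster with a distinct letter
  expect_identical(select_stable_clusters(res, c(`1` = "a", `2` = "b", `3` = "b")), 1L)
  # tie at the minimum sharing a letter
  expect_identical(select_stable_clusters(res, c(`1` = "a", `2` = "b", `3` = "a")),
                   c(1L, 3L))
})

test_that("planted strong clusters are selected as the stable set end-to-end", {
  # 4 indistinguishable strong clusters + 5 clearly weaker ones
  set.seed(41)
  strong <- lapply(1:4, function(i) rep(-20, 8))
  weak <- lapply(1:5, function(i) rep(-8 - i, 8))
  profiles <- lapply(c(strong, weak), function(base) {
    # distinct fragment shapes (zero-mean, so per-cluster totals are kept)
    # let clustering separate clusters whose totals are deliberately equal
    v <- rnorm(8, 0, 2)
    base + v - mean(v)
  })
  spec <- pie_cluster_spec(profiles, rep(12, 9), within_sd = 0.4, seed = 14)
  g <- gen_pie_matrix(spec)
  res <- identify_stable_conformations(g$matrix, n_clusters = 9, alpha = 0.05)
  # map recovered clusters back to planted ids via majority vote
  planted_of <- vapply(sort(unique(res$labels)), function(cl) {
    as.integer(names(which.max(table(g$true_labels[res$labels == cl]))))
  }, integer(1))
  expect_setequal(planted_of[res$stable_ids], 1:4)
})

test_that("binding-energy bookkeeping matches independent arithmetic", {
  expect_equal(delta_g_bind(-1000, -900, -6), -94)
  expect_equal(delta_g_bind(-500, -480, -20), 0)
  set.seed(3)
  for (i in 1:25) {
    e <- rnorm(3, -500, 200)
    expect_equal(delta_g_bind(e[1], e[2], e[3]), e[1] - e[2] - e[3],
                 tolerance = 1e-12)
  }
  expect_error(delta_g_bind(NA, 1, 2), "finite")
})
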