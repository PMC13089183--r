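test_that("frame geometry reproduces simple constructed arrangements", {
  # collinear in-line attack: theta = 180, d1 = 3.5
  coords <- rbind(S_SAM = c(0, 0, -1.8), C_SAM = c(0, 0, 0),
                  S1 = c(0, 0, 3.5), S2 = c(0, 1.9, 3.5))
  g <- frame_geometry(coords, atom_map(1, 2, 3, 4))
  expect_equal(g$theta, 180)
  expect_equal(g$d1, 3.5)
  expect_equal(g$phi, 90)  # substituent orthogonal to the attack vector
  expect_equal(g$d_diff, g$d1 - g$d2)

  # coincident vertex atoms are undefined
  bad <- rbind(c(0, 0, -1.8), c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))
  expect_error(frame_geometry(bad, atom_map(1, 2, 3, 4)), "coincident")
})

test_that("geometry fields are invariant under rigid motions and reflection", {
  tr <- gen_trajectory(geom_spec(10,
    d_dist = list(dist = "uniform", min = 3, max = 5),
    theta_dist = list(dist = "uniform", min = 100, max = 180),
    phi_dist = list(dist = "uniform", min = 10, max = 170), seed = 4))
  g0 <- trajectory_geometry(tr)
  set.seed(6)
  for (i in seq_along(tr$frames)) {
    rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(rot) < 0) rot[, 1] <- -rot[, 1]
    shift <- runif(3, -50, 50)
    moved <- tr$frames[[i]] %*% t(rot) + matrix(shift, 4, 3, byrow = TRUE)
    gm <- frame_geometry(moved, atom_map(1, 2, 3, 4))
    for (f in c("d1", "d2", "theta", "theta2", "phi")) {
      expect_lt(abs(gm[[f]] - g0[[f]][i]), 1e-9)
    }
    # mirror image: unsigned angles and distances unchanged
    mirrored <- tr$frames[[i]] %*% diag(c(-1, 1, 1))
    gr <- frame_geometry(mirrored, atom_map(1, 2, 3, 4))
    for (f in c("d1", "d2", "theta", "theta2", "phi")) {
      expect_lt(abs(gr[[f]] - g0[[f]][i]), 1e-9)
    }
  }
})

test_that("nm-scaled input recovers the same geometry via the scale flag", {
  tr <- gen_trajectory(geom_spec(3, seed = 2))
  g_a <- trajectory_geometry(tr)
  tr_nm <- tr
  tr_nm$frames <- lapply(tr$frames, function(fr) fr / 10)
  g_nm <- trajectory_geometry(tr_nm, scale = 10)
  expect_equal(g_nm$d1, g_a$d1, tolerance = 1e-12)
  expect_equal(g_nm$phi, g_a$phi, tolerance = 1e-9)
})

test_that("reactive-frame extraction applies inclusive boundary semantics", {
  g <- geom_table(d1 = c(3.9, 4.1, 3.9, 4.0, 3.0),
                  theta = c(160, 160, 149, 150, 180),
                  phi = 120)
  kept <- extract_reactive_frames(g)
  expect_identical(kept$frame, c(1L, 4L, 5L))  # 4.0 and 150 and 180 inclusive
  # brute-force frame-by-frame oracle on random series
  set.seed(10)
  gr <- geom_table(d1 = runif(500, 2, 6), theta = runif(500, 90, 180),
                   phi = runif(500, 0, 180))
  kept_r <- extract_reactive_frames(gr)
  oracle <- gr[sapply(seq_len(nrow(gr)), function(i) {
    gr$d1[i] <= 4 && gr$theta[i] >= 150 && gr$theta[i] <= 180
  }), ]
  expect_identical(kept_r$frame, oracle$frame)
})

test_that("extraction is monotone in its cutoffs", {
  set.seed(15)
  g <- geom_table(d1 = runif(300, 2, 6), theta = runif(300, 90, 180),
                  phi = runif(300, 0, 180))
  n_base <- nrow(extract_reactive_frames(g, d_max = 4, theta_range = c(150, 180)))
  expect_gte(nrow(extract_reactive_frames(g, d_max = 5, theta_range = c(150, 180))), n_base)
  expect_gte(nrow(extract_reactive_frames(g, d_max = 4, theta_range = c(140, 180))), n_base)
})

test_that("phi histogram bins [0,180) with a closed last bin", {
  g <- geom_table(d1 = 3, theta = 170, phi = c(135, 135, 180, 0))
  h <- phi_histogram(g)
  expect_equal(nrow(h), 18)
  expect_equal(sum(h$count), 4)
  expect_equal(h$count[h$lower == 130], 2)
  expect_equal(h$count[h$lower == 170], 1)  # phi = 180 falls in the last bin
  expect_equal(h$count[h$lower == 0], 1)
  expect_error(phi_histogram(g, bin_width = 7), "divide 180")

  # multinomial expectation under uniform phi
  set.seed(44)
  gu <- geom_table(d1 = 3, theta = 170, phi = runif(1e5, 0, 180))
  hu <- phi_histogram(gu)
  expected <- 1e5 / 18
  expect_true(all(abs(hu$count - expected) < 4 * sqrt(expected)))
})

test_that("optimal-phi fraction applies inclusive bounds and handles emptiness", {
  expect_equal(optimal_phi_fraction(geom_table(3, 170, 135))$optimal_fraction, 100)
  expect_equal(optimal_phi_fraction(geom_table(3, 170, 75))$optimal_fraction, 0)
  expect_equal(optimal_phi_fraction(geom_table(3, 170, 100))$optimal_fraction, 100)
  s <- optimal_phi_fraction(geom_table(3, 170, numeric(0))[0, ])
  expect_true(is.na(s$optimal_fraction))
  expect_identical(s$n_extracted, 0L)
})

test_that("concentrated phi distributions reproduce the hindered/unhindered contrast", {
  mk <- function(center, seed) {
    tr <- gen_trajectory(geom_spec(3000,
      d_dist = list(dist = "normal", mean = 3.6, sd = 0.3),
      theta_dist = list(dist = "normal", mean = 165, sd = 10),
      phi_dist = list(dist = "normal", mean = center, sd = 15),
      seed = seed))
    steric_summary(trajectory_geometry(tr))$optimal_fraction
  }
  expect_gt(mk(135, 51), 75)  # unhindered persulfide-like geometry
  expect_lt(mk(75, 52), 25)   # hindered methylselenide-like geometry
})
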