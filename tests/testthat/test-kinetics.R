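test_that("single-substrate rate prediction matches hand substitution", {
  tr <- truth_na2s2()
  expect_equal(predict_mm(tr, 331), 130)          # half-saturation at S = Km
  expect_equal(predict_mm(tr, 0), 0)
  expect_equal(predict_mm(tr, 200), 260 * 200 / 531, tolerance = 1e-12)
  expect_error(predict_mm(tr, -1), ">= 0")
})

test_that("catalytic efficiency reproduces published values and rejects bad Km", {
  expect_equal(catalytic_efficiency(392, 209), 392 / 209)
  expect_equal(round(catalytic_efficiency(392, 209), 1), 1.9)
  expect_equal(catalytic_efficiency(0, 50), 0)
  expect_equal(round(catalytic_efficiency(16.2, 15.5), 1), 1.0)
  expect_error(catalytic_efficiency(100, 0), "km")
})

test_that("noiseless fits recover generating parameters to high relative accuracy", {
  for (pars in list(c(331, 260), c(6005, 412), c(15.5, 16.2))) {
    tr <- mm_truth(pars[1], pars[2])
    d <- gen_mm_rates(tr, kinetic_design(c(0, 20, 200, 2000), n_rep = 3,
                                         noise_sd = 0))
    f <- fit_mm(d)
    expect_lt(abs(f$km - pars[1]) / pars[1], 1e-6)
    expect_lt(abs(f$vmax - pars[2]) / pars[2], 1e-6)
    expect_equal(f$efficiency, f$vmax / f$km)    # unit identity
    expect_true(f$converged)
  }
})

test_that("noiseless recovery holds across the parameter domain", {
  set.seed(31)
  for (i in 1:10) {
    km <- 10^runif(1, 1, 4)
    vmax <- 10^runif(1, 0, 3)
    d <- gen_mm_rates(mm_truth(km, vmax),
                      kinetic_design(km * c(0.1, 0.5, 1, 5, 20), n_rep = 1,
                                     noise_sd = 0))
    f <- fit_mm(d)
    expect_lt(abs(f$km - km) / km, 1e-6)
    expect_lt(abs(f$vmax - vmax) / vmax, 1e-6)
  }
})

test_that("least-squares fit agrees with an exhaustive grid-search oracle", {
  tr <- truth_na2s2()
  d <- gen_mm_rates(tr, kinetic_design(c(20, 100, 500, 2000), n_rep = 3,
                                       noise_sd = 10, seed = 7))
  f <- fit_mm(d)
  # brute force over a fine (km, vmax) lattice
  km_grid <- seq(200, 500, by = 1)
  vmax_grid <- seq(200, 320, by = 0.5)
  rss <- outer(km_grid, vmax_grid, Vectorize(function(km, vm) {
    sum((d$rate_nmol_min_mg - vm * d$substrate_uM / (km + d$substrate_uM))^2)
  }))
  best <- arrayInd(which.min(rss), dim(rss))
  expect_lt(abs(f$km - km_grid[best[1]]), 1)
  expect_lt(abs(f$vmax - vmax_grid[best[2]]), 0.5)
  expect_lte(f$residual_ss, min(rss) + 1e-9)
})

test_that("fitted Km has bounded bias under realistic assay noise", {
  set.seed(123)
  tr <- truth_na2s2()
  kms <- replicate(200, {
    seed <- sample.int(1e6, 1)
    d <- gen_mm_rates(tr, kinetic_design(c(0, 20, 200, 2000), n_rep = 3,
                                         noise_sd = 0.05 * 260, seed = seed))
    fit_mm(d)$km
  })
  expect_lt(abs(stats::median(kms) - 331) / 331, 0.10)
})

test_that("degenerate and unidentifiable kinetic inputs are handled", {
  all_zero <- data.frame(substrate_uM = c(0, 20, 200),
                         rate_nmol_min_mg = c(0, 0, 0),
                         replicate = 1, condition = "blank")
  f <- fit_mm(all_zero)
  expect_identical(f$vmax, 0)
  expect_false(f$km_identifiable)
  one_conc <- data.frame(substrate_uM = c(100, 100),
                         rate_nmol_min_mg = c(5, 6),
                         replicate = 1:2, condition = "x")
  expect_error(fit_mm(one_conc), "2 distinct positive")
})

test_that("dual-model prediction matches hand evaluation and branch semantics", {
  m <- dual_mm_model(truth_gss(), truth_h2s(), c1 = 50)
  expect_equal(predict_dual_mm(m, 2000),
               392 * 50 / 259 + 5.37 * 1950 / (1978 + 1950),
               tolerance = 1e-12)
  # below the breakpoint: pure persulfide branch
  expect_equal(predict_dual_mm(m, 30), predict_mm(truth_gss(), 30))
  # continuity at the breakpoint
  expect_equal(predict_dual_mm(m, 50), predict_mm(truth_gss(), 50))
})

test_that("dual model is continuous and nondecreasing in substrate over random draws", {
  set.seed(17)
  for (i in 1:20) {
    m <- dual_mm_model(mm_truth(runif(1, 50, 2000), runif(1, 10, 500)),
                       mm_truth(runif(1, 50, 5000), runif(1, 1, 100)),
                       c1 = runif(1, 0, 1000))
    eps <- 1e-7 * max(m$c1, 1)
    gap <- predict_dual_mm(m, m$c1 + eps) - predict_dual_mm(m, max(m$c1 - eps, 0))
    expect_lt(abs(gap), 1e-4)
    s <- sort(runif(50, 0, 3000))
    expect_true(all(diff(predict_dual_mm(m, s)) >= -1e-10))
  }
})

test_that("dual model collapses to single branches in the c1 limits", {
  s <- c(0, 10, 100, 1000, 2500)
  m0 <- dual_mm_model(truth_gss(), truth_h2s(), 0)
  expect_equal(predict_dual_mm(m0, s), predict_mm(truth_h2s(), s),
               tolerance = 1e-12)
  minf <- dual_mm_model(truth_gss(), truth_h2s(), 5000)
  expect_equal(predict_dual_mm(minf, s), predict_mm(truth_gss(), s),
               tolerance = 1e-12)
})

test_that("breakpoint fit recovers planted c1 and hits boundaries when appropriate", {
  des <- kinetic_design(seq(0, 2000, by = 20), n_rep = 1, noise_sd = 0)
  d50 <- gen_dual_mm_rates(truth_gss(), truth_h2s(), 50, des)
  f50 <- fit_c1(d50, truth_gss(), truth_h2s())
  expect_lt(abs(f50$c1 - 50), 0.1)

  # pure persulfide data (c1 beyond every concentration) drives c1 to the top
  dg <- gen_mm_rates(truth_gss(), des)
  fg <- fit_c1(dg, truth_gss(), truth_h2s())
  expect_equal(fg$c1, 2000, tolerance = 1e-6)

  # pure H2S data: c1 collapses to zero
  d0 <- gen_dual_mm_rates(truth_gss(), truth_h2s(), 0, des)
  f0 <- fit_c1(d0, truth_gss(), truth_h2s())
  expect_lt(f0$c1, 0.1)
})
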