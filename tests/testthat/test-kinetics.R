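test_that("chase fractions follow the printed formulas", {
  expect_equal(fraction_secreted(0, 10, 90), 0)
  expect_equal(fraction_secreted(30, 10, 90), 0.30)
  expect_error(fraction_secreted(10, 0, 0), "> 0")
  expect_equal(fraction_remaining(10, 90, 10, 90), 1) # t = 0 exactly
  expect_error(fraction_remaining(1, 1, 0, 0), "> 0")
  # noise-free simulator values at ks=0.3, kd=0.1, t=4
  m <- chase_model(0.3, 0.1, 4)
  expect_equal(fraction_secreted(m$E, 0, 100), 0.5985776,
               tolerance = 1e-6)
  expect_equal(fraction_remaining(m$E, m$I, 0, 100), 0.8004741,
               tolerance = 1e-6)
  # kd = 0: conservation keeps fraction remaining at 1 for any t
  m0 <- chase_model(0.4, 0, c(1, 3, 9))
  expect_equal(fraction_remaining(m0$E, m0$I, 0, 100), rep(1, 3),
               tolerance = 1e-12)
})

test_that("fractions are monotone in time on noise-free output", {
  t <- seq(0, 10, by = 0.5)
  m <- chase_model(0.25, 0.15, t)
  fs <- fraction_secreted(m$E, m$E[1], m$I[1])
  fr <- fraction_remaining(m$E, m$I, m$E[1], m$I[1])
  expect_true(all(diff(fs) >= 0))
  expect_true(all(diff(fr) <= 0))
})

test_that("normalize_to_vehicle is a guarded ratio", {
  expect_equal(normalize_to_vehicle(0.3, 0.3), 1)
  expect_equal(normalize_to_vehicle(0.165, 0.30), 0.55) # a 45% reduction
  expect_error(normalize_to_vehicle(0.3, 0), "> 0")
})

test_that("chx_fractions satisfies its algebraic identity", {
  got <- chx_fractions(20, 50, 90, 10)
  expect_equal(got$fraction_secreted, 0.5)
  expect_equal(got$intracellular_fraction, 0.2)
  expect_equal(got$fraction_remaining, 0.7)
  # t = 0 with empty media: everything intracellular
  expect_equal(unlist(chx_fractions(50, 0, 50, 0)),
               c(fraction_secreted = 0, intracellular_fraction = 1,
                 fraction_remaining = 1))
  set.seed(411)
  for (i in 1:20) {
    v <- runif(4, 0.1, 100)
    g <- chx_fractions(v[1], v[2], v[3], v[4])
    expect_equal(g$fraction_remaining,
                 g$fraction_secreted + g$intracellular_fraction,
                 tolerance = 1e-12)
  }
})

test_that("chase_fraction_table normalises against the vehicle series", {
  veh <- generate_chase_data(0.3, 0.1, c(0, 4), n_replicates = 2,
                             series_id = "vehicle")$series
  trt <- generate_chase_data(0.15, 0.25, c(0, 4), n_replicates = 2,
                             series_id = "treated")$series
  tab <- chase_fraction_table(rbind(veh, trt), vehicle = "vehicle")
  m_v <- chase_model(0.3, 0.1, 4); m_t <- chase_model(0.15, 0.25, 4)
  row <- tab[tab$series_id == "treated" & tab$t_hours == 4, ][1, ]
  expect_equal(row$fraction_secreted, m_t$E / 100, tolerance = 1e-12)
  expect_equal(row$norm_fraction_secreted, m_t$E / m_v$E,
               tolerance = 1e-12)
  expect_false(any(tab$qc_over_unity))
  expect_error(chase_fraction_table(veh, vehicle = "nope"), "not found")
})

test_that("4PL evaluation and fitting are self-consistent", {
  doses <- 10^seq(-8, -4, length.out = 8)
  resp <- four_pl(doses, bottom = 0, top = 100, ec50 = 1e-6, slope = 1)
  fit <- fit_4pl(doses, resp)
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
  expect_equal(fit$top, 100, tolerance = 1e-6)
  expect_equal(fit$ec50, 1e-6, tolerance = 1e-6)
  expect_equal(fit$slope, 1, tolerance = 1e-6)
  expect_false(fit$extrapolated)
  expect_false(fit$degenerate)
  # constrained fit
  fitc <- fit_4pl(doses, resp, constrain = list(bottom = 0, top = 100))
  expect_equal(fitc$ec50, 1e-6, tolerance = 1e-6)
  # flat response: EC50 unidentifiable
  flat <- fit_4pl(doses, rep(42, 8))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$ec50))
  expect_error(fit_4pl(doses[1:4], resp[1:4]), "5 distinct")
})

test_that("4PL fit is equivariant under dose-unit rescaling", {
  set.seed(412)
  doses <- rep(10^seq(-7.5, -4.5, length.out = 9), each = 2)
  resp <- four_pl(doses, 5, 95, 3e-6, 1.3) * rlnorm(18, 0, 0.03)
  f1 <- fit_4pl(doses, resp)
  f2 <- fit_4pl(doses * 1e3, resp) # molar -> millimolar
  expect_equal(f2$ec50 / f1$ec50, 1e3, tolerance = 1e-3)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-3)
  expect_equal(f2$top, f1$top, tolerance = 1e-3)
  expect_equal(f2$bottom, f1$bottom, tolerance = 1e-2)
})

test_that("invert_4pl recovers doses inside the calibrated range only", {
  doses <- 10^seq(-8, -4, length.out = 10)
  fit <- fit_4pl(doses, four_pl(doses, 0, 100, 1e-6, 1))
  d0 <- c(1e-7, 5e-6)
  inv <- invert_4pl(fit, four_pl(d0, 0, 100, 1e-6, 1))
  expect_equal(inv$dose, d0, tolerance = 1e-5)
  expect_true(all(inv$in_range))
  # response implying a dose outside the standards range is flagged
  out <- invert_4pl(fit, four_pl(1e-10, 0, 100, 1e-6, 1))
  expect_false(out$in_range)
  expect_true(is.na(out$dose))
})

test_that("estimate_rates recovers planted kinetics", {
  nf <- generate_chase_data(0.3, 0.1, c(0, 1, 2, 4), n_replicates = 2)
  est <- estimate_rates(nf$series)
  expect_equal(est$ks, 0.3, tolerance = 1e-6)
  expect_equal(est$kd, 0.1, tolerance = 1e-6)
  expect_equal(est$label0, 100, tolerance = 1e-6)
  # kd = 0 boundary is reachable and bootstrap CI brackets it
  nz <- generate_chase_data(0.25, 0, c(0, 1, 2, 4), noise_cv = 0.03,
                            n_replicates = 4, seed = 31L)
  est0 <- estimate_rates(nz$series, n_boot = 50, seed = 31L)
  expect_lt(est0$kd, 0.02)
  expect_lte(est0$ci["kd", 1], 0.01)
  expect_error(estimate_rates(nf$series[nf$series$t_hours > 0, ]),
               "t = 0")
})
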