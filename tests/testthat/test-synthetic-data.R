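test_that("generators are deterministic under a fixed seed", {
  cfg <- screen_sim_config(n_plates = 2, wells_per_plate = 48,
                           n_high_controls = 4, n_low_controls = 4,
                           seed = 7L)
  expect_identical(generate_plate_set(cfg), generate_plate_set(cfg))
  tr <- generate_plate_set(cfg)$truth
  expect_identical(generate_replicate_activations(tr, cfg, "erse"),
                   generate_replicate_activations(tr, cfg, "erse"))
  expect_identical(
    generate_expression_profiles(c("global", "inactive"), seed = 7L),
    generate_expression_profiles(c("global", "inactive"), seed = 7L))
  expect_identical(generate_cell_ratios(2, 50, 0.3, seed = 7L),
                   generate_cell_ratios(2, 50, 0.3, seed = 7L))
  expect_identical(
    generate_chase_data(0.3, 0.1, c(0, 4), noise_cv = 0.05, seed = 7L),
    generate_chase_data(0.3, 0.1, c(0, 4), noise_cv = 0.05, seed = 7L))
  # different seeds diverge
  cfg2 <- screen_sim_config(n_plates = 2, wells_per_plate = 48,
                            n_high_controls = 4, n_low_controls = 4,
                            seed = 8L)
  expect_false(identical(generate_plate_set(cfg)$plates$raw_signal,
                         generate_plate_set(cfg2)$plates$raw_signal))
})

test_that("zero-noise limits of the plate generator are exact", {
  cfg <- screen_sim_config(n_plates = 1, wells_per_plate = 24,
                           n_high_controls = 4, n_low_controls = 4,
                           cv = 0, high_mean = 100, low_mean = 1,
                           class_fractions = c(global = 0,
                                               atf6_preferential = 0,
                                               inactive = 1))
  pl <- generate_plate_set(cfg)$plates
  expect_equal(pl$raw_signal[pl$role == "high_control"], rep(100, 4))
  expect_equal(pl$raw_signal[pl$role == "low_control"], rep(1, 4))
  # inactive compounds sit exactly at the low-control mean
  expect_equal(pl$raw_signal[pl$role == "compound"],
               rep(1, sum(pl$role == "compound")))
})

test_that("invalid screen configs are rejected", {
  expect_error(screen_sim_config(class_fractions = c(
    global = 0.5, atf6_preferential = 0.5, inactive = 0.5)), "sum to 1")
  expect_error(screen_sim_config(high_mean = 1, low_mean = 1),
               "high_mean")
  expect_error(screen_sim_config(low_mean = -1), "high_mean")
  expect_error(screen_sim_config(cv = -0.1), "cv")
  expect_error(screen_sim_config(n_high_controls = 1), "controls")
})

test_that("planted class counts are exact and recorded one-to-one", {
  cfg <- screen_sim_config(n_plates = 4, wells_per_plate = 96,
                           n_high_controls = 8, n_low_controls = 8)
  ps <- generate_plate_set(cfg)
  n_comp <- 4 * (96 - 16)
  expect_equal(nrow(ps$truth), n_comp)
  expect_equal(sum(duplicated(ps$truth$compound_id)), 0)
  # every compound well maps to exactly one truth entry
  wells <- ps$plates$compound_id[ps$plates$role == "compound"]
  expect_setequal(wells, ps$truth$compound_id)
  counts <- table(ps$truth$class)
  expect_equal(unname(counts[["inactive"]]), round(0.93 * n_comp))
  expect_equal(unname(counts[["atf6_preferential"]]), round(0.05 * n_comp))
})

test_that("expression generator honours noise-free class effects", {
  sets <- default_geneset_catalog()
  out <- generate_expression_profiles(c("global", "inactive"),
                                      genesets = sets, sd_log = 0,
                                      seed = 3L)
  expr <- out$expr
  upr_genes <- unlist(unclass(sets)[c("ATF6", "XBP1s", "PERK")])
  # global compound reproduces the reference induction gene by gene
  expect_equal(expr[upr_genes, 1], expr[upr_genes, "Tg"])
  # inactive compound: every gene at fold change 1
  expect_equal(unname(expr[, 2]), rep(1, nrow(expr)))
  # off-pathway genesets stay at baseline in every condition
  off <- unlist(unclass(sets)[c("HSR", "Nrf2", "NFkB")])
  expect_equal(unname(as.vector(expr[off, ])),
               rep(1, length(off) * ncol(expr)))
})

test_that("a gene in two genesets is rejected", {
  expect_error(geneset_catalog(list(ATF6 = sprintf("g%d", 1:5),
                                    XBP1s = sprintf("g%d", 5:9))),
               "two genesets")
  expect_error(geneset_catalog(list(ATF6 = c("a", "b"))), "< 5 genes")
})

test_that("cell-ratio mixture respects planted fractions at the extremes", {
  all_off <- generate_cell_ratios(2, 100, 0, contamination = 0, seed = 5L)
  expect_false(any(all_off$truth$activated))
  all_on <- generate_cell_ratios(2, 100, 1, seed = 5L)
  expect_true(all(all_on$truth$activated))
  expect_error(generate_cell_ratios(1, 10, 1.2), "activated_fraction")
  # resting mode < 1 < activated mode
  r_off <- with(all_off$cells, nuc_intensity / er_intensity)
  r_on <- with(all_on$cells, nuc_intensity / er_intensity)
  expect_lt(median(r_off), 1)
  expect_gt(median(r_on), 1)
})

test_that("chase model matches its closed form and conserves label", {
  m <- chase_model(0, 0, c(0, 1, 10), label0 = 50)
  expect_equal(m$I, rep(50, 3))
  expect_equal(m$E, rep(0, 3))
  # kd = 0, t -> infinity: everything is secreted
  m2 <- chase_model(0.3, 0, 1e6)
  expect_equal(m2$E / 100, 1, tolerance = 1e-9)
  # closed-form spot value, recomputed literally here
  m3 <- chase_model(0.3, 0.1, 4)
  expect_equal(m3$E, 100 * 0.3 / 0.4 * (1 - exp(-0.4 * 4)),
               tolerance = 1e-12)
  expect_equal(m3$I, 100 * exp(-0.4 * 4), tolerance = 1e-12)
  expect_equal(m3$E, 59.85776, tolerance = 1e-6)
  expect_equal(m3$I, 20.18965, tolerance = 1e-6)
  # conservation: I + E + degraded = label0, degraded = kd/k * (1 - e^-kt)
  for (ks in c(0, 0.2, 0.7)) {
    for (kd in c(0, 0.1, 0.5)) {
      t <- c(0, 0.5, 2, 8)
      m <- chase_model(ks, kd, t, label0 = 100)
      k <- ks + kd
      degraded <- if (k == 0) rep(0, length(t)) else
        100 * kd / k * (1 - exp(-k * t))
      expect_equal(m$I + m$E + degraded, rep(100, length(t)),
                   tolerance = 1e-9)
    }
  }
})

test_that("noise-free chase tables reproduce the model exactly", {
  out <- generate_chase_data(0.3, 0.1, c(0, 2, 4), label0 = 100,
                             noise_cv = 0, n_replicates = 2)
  s <- out$series
  m <- chase_model(0.3, 0.1, c(0, 2, 4), 100)
  for (i in seq_along(c(0, 2, 4))) {
    t <- c(0, 2, 4)[i]
    expect_equal(s$signal[s$compartment == "lysate" & s$t_hours == t],
                 rep(m$I[i], 2))
    expect_equal(s$signal[s$compartment == "media" & s$t_hours == t],
                 rep(m$E[i], 2))
  }
  expect_error(generate_chase_data(0.3, 0.1, c(1, 2)), "0")
})

test_that("plate generator matches the analytic Z' of its distributions", {
  cfg <- screen_sim_config(n_plates = 12, wells_per_plate = 96,
                           n_high_controls = 16, n_low_controls = 16,
                           high_mean = 100, low_mean = 1, cv = 0.05,
                           seed = 11L)
  qc <- plate_qc_report(generate_plate_set(cfg)$plates)
  analytic <- 1 - 3 * (0.05 * 100 + 0.05 * 1) / (100 - 1)
  expect_equal(mean(qc$z_prime), analytic, tolerance = 0.05)
})
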