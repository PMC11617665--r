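test_that("percent inhibition arithmetic and guards", {
  expect_equal(percent_inhibition(0.5, 1.0), 50)
  expect_equal(percent_inhibition(1.0, 1.0), 0)
  expect_equal(percent_inhibition(0, 0.8), 100)
  # invariant under common rescaling of both absorbances
  expect_equal(percent_inhibition(0.3 * 7, 0.9 * 7),
               percent_inhibition(0.3, 0.9))
  expect_error(percent_inhibition(0.5, 0), "positive")
})

test_that("dose-response model hits its anchor points and is monotone", {
  expect_equal(dose_response_model(0.044, 100, 0.044, 1), 50)
  expect_equal(dose_response_model(0.044, 90, 0.044, 1), 45)
  expect_equal(dose_response_model(0, 100, 0.044, 1), 0)
  expect_equal(dose_response_model(1e9, 100, 0.044, 1), 100, tolerance = 1e-6)
  I <- exp(seq(log(1e-4), log(10), length.out = 50))
  y <- dose_response_model(I, 100, 0.044, 1.3)
  expect_true(all(diff(y) > 0))
  expect_true(all(y <= 100))
  # log-concentration symmetry about IC50 when s = 1:
  # response(IC50*k) + response(IC50/k) = A100
  k <- c(2, 5, 10)
  expect_equal(dose_response_model(0.044 * k, 100, 0.044, 1) +
                 dose_response_model(0.044 / k, 100, 0.044, 1),
               rep(100, 3))
  expect_error(dose_response_model(1, 100, -1, 1), "positive")
})

test_that("rate laws obey their closed-form anchor points", {
  expect_equal(competitive_rate(25.71, 0, 36.06, 25.71, 0.0234), 36.06 / 2)
  expect_equal(competitive_rate(25.71, 0.0234, 36.06, 25.71, 0.0234),
               36.06 / 3)
  expect_equal(competitive_rate(1e9, 0.06, 36.06, 25.71, 0.0234), 36.06,
               tolerance = 1e-6)
  # all mechanisms reduce to Michaelis-Menten at I = 0
  mm <- 36.06 * 0.3 / (25.71 + 0.3)
  expect_equal(uncompetitive_rate(0.3, 0, 36.06, 25.71, 0.0234), mm)
  expect_equal(noncompetitive_rate(0.3, 0, 36.06, 25.71, 0.0234), mm)
  expect_equal(mixed_rate(0.3, 0, 36.06, 25.71, 0.0234, 0.01), mm)
  expect_error(competitive_rate(0.3, 0, -1, 25.71, 0.0234), "positive")
})

test_that("Cheng-Prusoff relation and its limits", {
  expect_equal(cheng_prusoff_ic50(0.0234, 1e-9, 25.71), 0.0234,
               tolerance = 1e-6)
  expect_equal(cheng_prusoff_ic50(0.0234, 25.71, 25.71), 2 * 0.0234)
})

test_that("dose-response fitting recovers generating parameters", {
  # zero noise: exact recovery
  d0 <- gen_dose_response(noise_cv = 0, seed = 1)
  f0 <- fit_ic50(d0)
  p0 <- setNames(f0$parameters$estimate, f0$parameters$parameter)
  expect_equal(p0[["A100"]], 100, tolerance = 1e-6)
  expect_equal(p0[["IC50"]], 0.044, tolerance = 1e-6)
  expect_equal(p0[["s"]], 1, tolerance = 1e-6)

  # fixed A100 variant
  ff <- fit_ic50(d0, fix_A100 = 100)
  expect_equal(ff$parameters$estimate[ff$parameters$parameter == "IC50"],
               0.044, tolerance = 1e-6)
  expect_equal(ff$n_par, 2L)

  # bias shrinks with the noise level
  err_at <- function(cv) {
    d <- gen_dose_response(noise_cv = cv, seed = 17)
    f <- fit_ic50(d)
    abs(f$parameters$estimate[f$parameters$parameter == "IC50"] - 0.044) / 0.044
  }
  errs <- vapply(c(0, 0.01, 0.02, 0.05), err_at, 0)
  expect_lt(errs[1], 1e-8)
  expect_lt(errs[2], 0.05)
  expect_lt(errs[4], 0.25)

  # defined failures
  flat <- data.frame(inhibitor_mM = c(0.01, 0.02, 0.04, 0.08, 0.16),
                     response = rep(0, 5))
  expect_error(fit_ic50(flat), "flat")
  inv <- data.frame(inhibitor_mM = c(0.01, 0.02, 0.04, 0.08, 0.16),
                    response = c(80, 60, 40, 20, 10))
  expect_error(fit_ic50(inv), "increase")
  expect_error(fit_ic50(data.frame(inhibitor_mM = c(0.01, 0.02, 0.04),
                                   response = c(10, 20, 40))), "4 distinct")
})

test_that("global inhibition fitting recovers parameters and reports SEs", {
  d0 <- gen_rate_data(noise_cv = 0, seed = 1)
  f0 <- fit_inhibition(d0, "competitive")
  p0 <- setNames(f0$parameters$estimate, f0$parameters$parameter)
  expect_equal(p0[["Vmax"]], 36.06, tolerance = 1e-6)
  expect_equal(p0[["Km"]], 25.71, tolerance = 1e-6)
  expect_equal(p0[["Ki"]], 0.0234, tolerance = 1e-6)
  expect_true(all(f0$parameters$se >= 0))

  # Ki is precisely identified at 2% noise on this design; the bench
  # substrate range sits far below Km, so Vmax and Km are only weakly
  # identified individually (their ratio is what the data pin down)
  d2 <- gen_rate_data(noise_cv = 0.02, seed = 17)
  f2 <- fit_inhibition(d2, "competitive")
  p2 <- setNames(f2$parameters$estimate, f2$parameters$parameter)
  expect_equal(p2[["Ki"]], 0.0234, tolerance = 0.15)
  expect_equal(p2[["Vmax"]] / p2[["Km"]], 36.06 / 25.71, tolerance = 0.05)

  expect_error(fit_inhibition(d0[d0$inhibitor_mM > 0, ], "competitive"),
               "I = 0")
  expect_error(fit_inhibition(d0[d0$substrate_mM < 0.4, ], "competitive"),
               "4 substrate")
})

test_that("AICc prefers the generating mechanism over alternatives", {
  du <- gen_rate_data(Km = 0.3, mechanism = "uncompetitive", seed = 23)
  fu_wrong <- fit_inhibition(du, "competitive")
  fu_right <- fit_inhibition(du, "uncompetitive")
  expect_gt(fu_wrong$aicc, fu_right$aicc)

  auto <- fit_inhibition(du, "auto")
  expect_equal(auto$model, "uncompetitive")
  expect_s3_class(auto$aicc_table, "data.frame")
  expect_equal(auto$aicc_table$model[1], "uncompetitive")
})

test_that("Lineweaver-Burk fits satisfy the competitive-algebra identities", {
  d <- gen_rate_data(noise_cv = 0, seed = 1)
  lb <- lineweaver_burk(d)
  # shared ordinate intercept = 1/Vmax
  expect_equal(lb$lines$intercept, rep(1 / 36.06, 4), tolerance = 1e-8)
  expect_lt(lb$spreads[["intercept"]], 1e-8)
  # slope at level I equals (Km/Vmax) * (1 + I/Ki)
  expect_equal(lb$lines$slope,
               (25.71 / 36.06) * (1 + lb$lines$inhibitor_mM / 0.0234),
               tolerance = 1e-8)
  expect_equal(lb$classification, "competitive")

  # single-level Michaelis-Menten data: slope Km/Vmax, intercept 1/Vmax
  d0 <- d[d$inhibitor_mM == 0, ]
  lb0 <- lineweaver_burk(d0)
  expect_equal(lb0$lines$slope, 25.71 / 36.06, tolerance = 1e-8)
  expect_equal(lb0$lines$intercept, 1 / 36.06, tolerance = 1e-8)
  expect_true(is.na(lb0$classification))

  bad <- d; bad$velocity[1] <- 0
  expect_error(lineweaver_burk(bad), "positive")
})

test_that("uncompetitive and noncompetitive patterns classify correctly", {
  du <- gen_rate_data(Km = 0.3, mechanism = "uncompetitive", noise_cv = 0,
                      seed = 1)
  lbu <- lineweaver_burk(du)
  expect_lt(lbu$spreads[["slope"]], 1e-8) # parallel lines
  expect_equal(lbu$classification, "uncompetitive")

  dn <- gen_rate_data(Km = 0.3, mechanism = "noncompetitive", noise_cv = 0,
                      seed = 1)
  lbn <- lineweaver_burk(dn)
  expect_lt(lbn$spreads[["x_intercept"]], 1e-8)
  expect_equal(lbn$classification, "noncompetitive")
})

test_that("Cheng-Prusoff links the Ki fit to a simulated IC50 assay", {
  # dose-response data generated from the competitive mechanism itself:
  # %inh = 100 * (1 - v(I)/v(0)) at fixed substrate concentration
  S <- 0.4; Vmax <- 36.06; Km <- 25.71; Ki <- 0.0234
  conc <- exp(seq(log(0.002), log(0.5), length.out = 8))
  pct <- 100 * (1 - competitive_rate(S, conc, Vmax, Km, Ki) /
                  competitive_rate(S, 0, Vmax, Km, Ki))
  fit <- fit_ic50(data.frame(inhibitor_mM = conc, response = pct))
  ic50_hat <- fit$parameters$estimate[fit$parameters$parameter == "IC50"]
  expect_equal(ic50_hat, cheng_prusoff_ic50(Ki, S, Km), tolerance = 0.01)
})
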