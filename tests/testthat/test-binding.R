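test_that("dilution ladders are exactly geometric with n_steps + 1 entries", {
  lad <- dilution_ladder(40e-6, 2, 16)
  expect_length(lad$concentrations_M, 17L)
  expect_equal(lad$concentrations_M[1], 40e-6)
  expect_equal(lad$concentrations_M[17], 40e-6 / 2^16) # ~610 pM
  expect_equal(lad$concentrations_M[17] * 1e12, 610.3515625)
  ratios <- lad$concentrations_M[-17] / lad$concentrations_M[-1]
  expect_equal(ratios, rep(2, 16))
  expect_equal(dilution_ladder(8e-6, 2, 3)$concentrations_M, c(8, 4, 2, 1) * 1e-6)
  expect_equal(dilution_ladder(5e-6, 3, 0)$concentrations_M, 5e-6)
  expect_error(dilution_ladder(-1, 2, 4), "top_conc")
  expect_error(dilution_ladder(1e-6, 1, 4), "fold")
  expect_error(dilution_ladder(1e-6, 2, 2.5), "n_steps")
})

test_that("the quadratic mass-action model behaves at its limits", {
  expect_equal(binding_model(0, 5e-6, 50e-9), 0)
  expect_equal(binding_model(1, 5e-6, 50e-9), 1, tolerance = 1e-4) # c >> kd
  # ct << kd limit reduces to c / (c + kd)
  expect_equal(binding_model(5e-6, 5e-6, 0.05e-6), 0.5, tolerance = 1e-2)
  kd <- 3e-6
  cs <- 10^seq(-9, -3, length.out = 50)
  fb <- binding_model(cs, kd, kd * 1e-6)
  expect_equal(fb, cs / (cs + kd), tolerance = 1e-4)
  expect_true(all(diff(fb) >= 0))                      # monotone in c
  expect_true(all(fb >= 0 & fb <= 1))
  fb_hi_kd <- binding_model(cs, 10 * kd, kd * 1e-6)
  expect_true(all(fb_hi_kd <= fb + 1e-12))             # non-increasing in kd
  expect_error(binding_model(1e-6, 1e-6, 0), "ct")
  expect_error(binding_model(-1, 1e-6, 1e-9), ">= 0")
})

test_that("binding curves validate ordering and fraction-bound range", {
  conc <- dilution_ladder(40e-6, 2, 8)$concentrations_M
  expect_s3_class(binding_curve(conc, rep(0.5, 9), 50e-9), "binding_curve")
  expect_error(binding_curve(conc[c(2, 1, 3)], rep(0.5, 3), 50e-9), "ordered")
  expect_error(binding_curve(conc, rep(2, 9), 50e-9), "raw trace")
  expect_error(binding_curve(conc, rep(0.5, 9), 0), "target_conc")
})

test_that("a noiseless curve recovers its dissociation constant nearly exactly", {
  cfg <- synthetic_binding_config(kd_M = 5e-6, ct_M = 50e-9, binding_noise_sd = 0, seed = 1)
  fit <- fit_kd(simulate_binding(cfg))
  expect_equal(fit$kd_M, 5e-6, tolerance = 1e-4)
  expect_true(fit$converged)
  expect_true(fit$saturation_ok)
  expect_false(fit$at_bound)
})

test_that("fitting is equivariant under a joint concentration rescaling", {
  curve <- simulate_binding(synthetic_binding_config(seed = 3, n_replicates = 1L))
  f1 <- fit_kd(curve)
  for (s in c(10, 0.1)) {
    scaled <- binding_curve(curve$ligand_conc_M * s, curve$response,
                            curve$target_conc_M * s)
    f2 <- fit_kd(scaled)
    expect_equal(f2$kd_M, s * f1$kd_M, tolerance = 1e-6)
  }
})

test_that("raw-response fits recover fraction bound under affine transforms", {
  cfg <- synthetic_binding_config(kd_M = 2e-6, binding_noise_sd = 0, seed = 2)
  clean <- simulate_binding(cfg)
  raw_vals <- 850 + 120 * clean$response  # arbitrary fluorescence scale
  raw <- binding_curve(clean$ligand_conc_M, raw_vals, clean$target_conc_M,
                       response_is_fraction_bound = FALSE)
  norm <- fraction_bound_from_raw(raw)
  expect_equal(norm$response, clean$response, tolerance = 1e-6)
  fit <- attr(norm, "fit")
  expect_equal(fit$kd_M, 2e-6, tolerance = 1e-4)
  expect_equal(fit$baseline, 850, tolerance = 1e-3)
  expect_equal(fit$plateau, 970, tolerance = 1e-3)
  # an already-normalized curve passes through unchanged
  norm2 <- fraction_bound_from_raw(
    binding_curve(clean$ligand_conc_M, clean$response, clean$target_conc_M,
                  response_is_fraction_bound = FALSE)
  )
  expect_equal(norm2$response, clean$response, tolerance = 1e-6)
})

test_that("flat curves are refused as having no binding signal", {
  conc <- dilution_ladder(40e-6, 2, 10)$concentrations_M
  flat <- binding_curve(conc, rep(500, 11), 50e-9, response_is_fraction_bound = FALSE)
  expect_error(fraction_bound_from_raw(flat), "no binding signal")
})

test_that("saturation diagnostics gate on concentration margin and top fraction bound", {
  # 40 uM top vs kd = 3.85 uM passes both margins
  cfg <- synthetic_binding_config(kd_M = 3.85e-6, binding_noise_sd = 0, seed = 1)
  fit <- fit_kd(simulate_binding(cfg))
  expect_true(fit$saturation_ok)
  expect_gte(fit$saturation$conc_ratio, 5)
  expect_gte(fit$saturation$fb_top, 0.8)
  expect_equal(fit$saturation$fb_top, binding_model(40e-6, fit$kd_M, 50e-9))
  # top concentration equal to kd fails
  cfg2 <- synthetic_binding_config(kd_M = 40e-6, binding_noise_sd = 0, seed = 1)
  fit2 <- fit_kd(simulate_binding(cfg2))
  expect_false(fit2$saturation_ok)
  expect_match(fit2$saturation$reason, "K_D")
  # a truncated titration far below kd is flagged
  cfg3 <- synthetic_binding_config(kd_M = 5e-6, ladder = dilution_ladder(0.5e-6, 2, 8),
                                   binding_noise_sd = 0, seed = 1)
  fit3 <- fit_kd(simulate_binding(cfg3))
  expect_false(fit3$saturation_ok)
  expect_true(all(simulate_binding(cfg3)$response < 0.2))
})

test_that("K_D results serialize with diagnostics, blanking non-saturating values", {
  fit <- fit_kd(simulate_binding(synthetic_binding_config(kd_M = 40e-6, binding_noise_sd = 0, seed = 1)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_kd_csv(fit, f)
  tab <- utils::read.csv(f)
  expect_true(is.na(tab$kd_M))       # unsaturated: no K_D reported
  expect_false(tab$saturation_ok)
  expect_true(nzchar(tab$reason))
  fit2 <- fit_kd(simulate_binding(synthetic_binding_config(binding_noise_sd = 0, seed = 1)))
  write_kd_csv(fit2, f)
  expect_equal(utils::read.csv(f)$kd_M, 5e-6, tolerance = 1e-3)
})

test_that("binding data round-trips through long-format CSV with replicate averaging", {
  f <- withr::local_tempfile(fileext = ".csv")
  conc <- dilution_ladder(40e-6, 2, 6)$concentrations_M
  long <- data.frame(
    ligand_conc_M = rep(conc, 2),
    response = c(binding_model(conc, 5e-6, 50e-9) + 0.01,
                 binding_model(conc, 5e-6, 50e-9) - 0.01),
    replicate = rep(1:2, each = length(conc))
  )
  utils::write.csv(long, f, row.names = FALSE)
  curve <- read_binding_csv(f, target_conc_M = 50e-9)
  expect_equal(curve$response, binding_model(conc, 5e-6, 50e-9), tolerance = 1e-9)
  expect_equal(curve$replicate_sd, rep(stats::sd(c(0.01, -0.01)), length(conc)))
  expect_equal(curve$n_replicates, 2L)
})
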