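test_that("every generator is a pure function of its config seed", {
  s1 <- generate_sequence(synthetic_sequence_config(seed = 9))
  s2 <- generate_sequence(synthetic_sequence_config(seed = 9))
  expect_identical(s1$residues, s2$residues)
  expect_false(identical(s1$residues,
                         generate_sequence(synthetic_sequence_config(seed = 10))$residues))
  c1 <- simulate_cd(synthetic_cd_config(seed = 9))
  c2 <- simulate_cd(synthetic_cd_config(seed = 9))
  expect_identical(c1$values, c2$values)
  m1 <- simulate_mixture(null_mixture_config(noise_sd = 0.3, seed = 9))
  m2 <- simulate_mixture(null_mixture_config(noise_sd = 0.3, seed = 9))
  expect_identical(m1$a$values, m2$a$values)
  expect_identical(m1$b$values, m2$b$values)
  expect_identical(m1$mixture$values, m2$mixture$values)
  b1 <- simulate_binding(synthetic_binding_config(seed = 9))
  b2 <- simulate_binding(synthetic_binding_config(seed = 9))
  expect_identical(b1$response, b2$response)
  expect_identical(b1$replicate_sd, b2$replicate_sd)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_sequence(synthetic_sequence_config(seed = 5)))
  invisible(simulate_binding(synthetic_binding_config(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("sequence composition tracks the disorder bias", {
  all_dis <- generate_sequence(synthetic_sequence_config(length = 500, disorder_bias = 1, seed = 2))
  chars <- strsplit(all_dis$residues, "")[[1]]
  expect_true(all(chars %in% RESIDUE_CLASSES$disorder))
  cfg <- synthetic_sequence_config(length = 10000L, disorder_bias = 0.8, seed = 3)
  chars <- strsplit(generate_sequence(cfg)$residues, "")[[1]]
  expected_freq <- 0.8 + 0.2 * 8 / 20
  expect_equal(mean(chars %in% RESIDUE_CLASSES$disorder), expected_freq, tolerance = 0.02 / expected_freq)
  expect_error(synthetic_sequence_config(disorder_bias = 1.2), "disorder_bias")
  expect_error(synthetic_sequence_config(length = 0), "length")
})

test_that("noiseless simulated CD inverts exactly back to the basis mixture", {
  b <- default_basis()
  f <- c(helix = 0.3, sheet = 0.2, turn = 0.1, disordered = 0.4)
  cfg <- synthetic_cd_config(fractions = f, noise_sd = 0, seed = 1)
  spec <- simulate_cd(cfg, b)
  expect_equal(spec$unit, "millidegrees")
  mre <- to_mre(spec)
  expect_equal(mre$values, as.numeric(b$matrix %*% f[b$classes]), tolerance = 1e-12)
  r <- deconvolve(mre, b)
  expect_equal(as.numeric(r$fractions[names(f)]), as.numeric(f), tolerance = 1e-6)
  expect_error(synthetic_cd_config(fractions = c(helix = 0.5, sheet = 0.6)), "sum to 1")
  expect_error(simulate_cd(synthetic_cd_config(fractions = c(a = 0.5, b = 0.5)), b),
               "match basis classes")
})

test_that("a non-interacting mixture yields a zero difference spectrum", {
  trio <- simulate_mixture(null_mixture_config(noise_sd = 0))
  ma <- meta_a(); mb <- meta_b()
  expected <- expected_noninteracting(to_mre(trio$a), to_mre(trio$b), "weighted")
  mixture <- to_mre_mixture(trio$mixture, mixture_meta(ma, mb), "total-residue")
  d <- difference_spectrum(expected, mixture)
  expect_equal(max(abs(d$values)), 0, tolerance = 1e-9)
})

test_that("partner-induced helix gain scales with the bound fraction", {
  delta <- c(helix = 0.25, sheet = 0, turn = 0, disordered = -0.25)
  diff_magnitude <- function(kd) {
    cfg <- synthetic_mixture_config(
      config_a = synthetic_cd_config(noise_sd = 0),
      config_b = synthetic_cd_config(
        fractions = c(helix = 0.25, sheet = 0.35, turn = 0.2, disordered = 0.2),
        meta = meta_b(), noise_sd = 0
      ),
      kd_M = kd, induced_delta = delta, seed = 1
    )
    trio <- simulate_mixture(cfg)
    expected <- expected_noninteracting(to_mre(trio$a), to_mre(trio$b), "weighted")
    mixture <- to_mre_mixture(trio$mixture, mixture_meta(meta_a(), meta_b()), "total-residue")
    list(mag = max(abs(difference_spectrum(expected, mixture)$values)),
         fb = attr(trio, "bound_fraction"))
  }
  tight <- diff_magnitude(1e-7)   # nearly all bound
  weak <- diff_magnitude(1e-4)    # mostly free
  expect_gt(tight$fb, weak$fb)
  expect_gt(tight$mag, weak$mag)
  expect_gt(tight$mag, 0)
  expect_error(
    synthetic_mixture_config(induced_delta = c(helix = 0.1, sheet = 0, turn = 0, disordered = 0)),
    "sum to 0"
  )
  expect_error(
    synthetic_mixture_config(induced_delta = c(helix = 0.45, sheet = 0, turn = -0.25, disordered = -0.2)),
    "below 0"
  )
})

test_that("noiseless binding simulation equals the model; replicates populate SDs", {
  cfg0 <- synthetic_binding_config(binding_noise_sd = 0, seed = 4)
  curve <- simulate_binding(cfg0)
  expect_equal(curve$response,
               binding_model(cfg0$ladder$concentrations_M, cfg0$kd_M, cfg0$ct_M))
  cfg2 <- synthetic_binding_config(seed = 4, n_replicates = 2L)
  curve2 <- simulate_binding(cfg2)
  expect_length(curve2$replicate_sd, 17L)
  expect_true(any(curve2$replicate_sd > 0))
  fit <- fit_kd(curve2)
  expect_equal(fit$kd_M, 5e-6, tolerance = 0.1)
})

test_that("estimator error grows with the configured noise level", {
  noise_levels <- rep(c(0.005, 0.02, 0.08), length.out = 21)
  errs <- vapply(seq_along(noise_levels), function(i) {
    cfg <- synthetic_binding_config(binding_noise_sd = noise_levels[i],
                                    n_replicates = 1L, seed = 500 + i)
    abs(fit_kd(simulate_binding(cfg))$kd_M - 5e-6)
  }, numeric(1))
  expect_gt(stats::cor(noise_levels, errs, method = "spearman"), 0)
})
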