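test_that("cd_spectrum enforces grid monotonicity, range and unit state", {
  expect_error(cd_spectrum(c(190, 195, 192), c(1, 2, 3)), "monotonic")
  expect_error(cd_spectrum(c(150, 200), c(1, 2)), "170")
  expect_error(cd_spectrum(190:192, 1:2), "equal length")
  desc <- cd_spectrum(c(250, 249, 248), c(3, 2, 1), unit = "MRE")
  expect_equal(desc$wavelengths, c(248, 249, 250)) # stored ascending
  expect_equal(desc$values, c(1, 2, 3))
})

test_that("blank subtraction is pointwise and refuses mismatched grids or units", {
  wl <- 190:250
  s <- cd_spectrum(wl, rep(5, length(wl)))
  b <- cd_spectrum(wl, rep(1.5, length(wl)))
  expect_equal(subtract_blank(s, b)$values, rep(3.5, length(wl)))
  expect_equal(subtract_blank(s, s)$values, rep(0, length(wl)))
  b2 <- cd_spectrum(195:250, rep(1.5, 56))
  expect_error(subtract_blank(s, b2), "different wavelength grids")
  mre <- cd_spectrum(wl, rep(1, length(wl)), unit = "MRE")
  expect_error(subtract_blank(s, mre), "unit")
})

test_that("millidegree-to-MRE conversion follows 1/(10 l M n) and is linear", {
  wl <- c(200, 222)
  meta <- sample_meta(0.1, 1e-5, 100L)
  s <- cd_spectrum(wl, c(1, 0))
  m <- to_mre(s, meta)
  expect_equal(m$values, c(1000, 0)) # 1 / (10 * 0.1 * 1e-5 * 100)
  expect_equal(m$unit, "MRE")
  s2 <- cd_spectrum(wl, c(2, 0))
  expect_equal(to_mre(s2, meta)$values, 2 * m$values)
  expect_error(sample_meta(0, 1e-5, 100), "pathlength")
  expect_error(sample_meta(0.1, -1, 100), "molarity")
  expect_error(sample_meta(0.1, 1e-5, 0), "peptide_bonds")
  expect_error(to_mre(m, meta), "unit") # already MRE
})

test_that("sample_meta_from_sequence sets n to residue count minus one", {
  s <- protein_sequence(strrep("A", 112))
  expect_equal(sample_meta_from_sequence(s, 0.1, 1e-5)$n_peptide_bonds, 111L)
})

test_that("mixture MRE: printed convention reproduced bit-for-bit, and reduces to the single-species formula", {
  wl <- c(210, 220)
  ma <- sample_meta(0.1, 1e-5, 111L)
  mb <- sample_meta(0.1, 1e-5, 227L)
  mix <- mixture_meta(ma, mb)
  s <- cd_spectrum(wl, c(2, 2))
  paper <- to_mre_mixture(s, mix, convention = "paper")
  expect_equal(paper$values, rep(2 / (10 * 0.1 * 1e-5 * 169), 2)) # 1183.43
  # equal molarity and length: the printed formula equals the single-species one
  mix_eq <- mixture_meta(ma, ma)
  expect_equal(to_mre_mixture(s, mix_eq, convention = "paper")$values,
               to_mre(s, ma)$values)
  expect_error(mixture_meta(ma, sample_meta(0.05, 1e-5, 227L)), "path length")
})

test_that("total-residue convention recovers the weighted mean of components in an additive mixture", {
  wl <- 190:250
  ma <- meta_a(); mb <- meta_b()
  set.seed(8)
  mdeg_a <- rnorm(length(wl), 0, 5)
  mdeg_b <- rnorm(length(wl), 0, 5)
  mre_a <- to_mre(cd_spectrum(wl, mdeg_a), ma)
  mre_b <- to_mre(cd_spectrum(wl, mdeg_b), mb)
  mixture <- to_mre_mixture(cd_spectrum(wl, mdeg_a + mdeg_b), mixture_meta(ma, mb),
                            convention = "total-residue")
  weighted <- expected_noninteracting(mre_a, mre_b, mode = "weighted",
                                      meta_a = ma, meta_b = mb)
  expect_equal(mixture$values, weighted$values, tolerance = 1e-12)
})

test_that("MRE/ME conversion is the 3298 ratio with an exact round trip", {
  wl <- c(200, 210, 222)
  mre <- cd_spectrum(wl, c(3298, 0, -6596), unit = "MRE")
  me <- convert_mre_me(mre, "MRE_to_ME")
  expect_equal(me$values, c(1, 0, -2))
  expect_equal(me$unit, "ME")
  back <- convert_mre_me(me, "ME_to_MRE")
  expect_identical(back$values, mre$values)
  expect_error(convert_mre_me(me, "MRE_to_ME"), "unit")
})

test_that("replicate averaging is pointwise, idempotent, and noise-reducing", {
  wl <- 190:250
  s1 <- cd_spectrum(wl, rep(2, length(wl)))
  s2 <- cd_spectrum(wl, rep(4, length(wl)))
  expect_equal(average_spectra(list(s1, s2))$values, rep(3, length(wl)))
  expect_equal(average_spectra(list(s1))$values, s1$values)
  expect_equal(average_spectra(list(s2, s2, s2))$values, s2$values)
  expect_error(average_spectra(list()), "empty")
  expect_error(average_spectra(list(s1, cd_spectrum(wl, rep(1, length(wl)), unit = "MRE"))),
               "mixed units")
  # i.i.d. noise variance drops roughly by the replicate count
  set.seed(12)
  n_rep <- 8L
  reps <- lapply(1:n_rep, function(i) cd_spectrum(wl, rnorm(length(wl), 0, 1)))
  v1 <- mean(vapply(reps, function(s) var(s$values), numeric(1)))
  v2 <- var(average_spectra(reps)$values)
  expect_lt(v2, 2.5 * v1 / n_rep)
  expect_gt(v2, 0.3 * v1 / n_rep)
})

test_that("non-interacting expectation supports arithmetic and weighted modes", {
  wl <- c(200, 222)
  a <- cd_spectrum(wl, c(-10000, -8000), unit = "MRE")
  b <- cd_spectrum(wl, c(-2000, -1000), unit = "MRE")
  expect_equal(expected_noninteracting(a, b)$values, c(-6000, -4500))
  expect_equal(expected_noninteracting(a, a)$values, a$values)
  # equal M*n weights make the weighted mode coincide with arithmetic
  m <- sample_meta(0.1, 1e-5, 100L)
  expect_equal(expected_noninteracting(a, b, "weighted", meta_a = m, meta_b = m)$values,
               expected_noninteracting(a, b, "arithmetic")$values)
  # unequal weights pull towards the heavier component
  m2 <- sample_meta(0.1, 1e-5, 300L)
  w <- expected_noninteracting(a, b, "weighted", meta_a = m, meta_b = m2)$values
  expect_equal(w, (1 * a$values + 3 * b$values) / 4)
})

test_that("difference spectra subtract the mixture from the expectation", {
  wl <- c(200, 222)
  expected <- cd_spectrum(wl, c(-6000, -5000), unit = "MRE")
  mixture <- cd_spectrum(wl, c(-7000, -5000), unit = "MRE")
  d <- difference_spectrum(expected, mixture)
  expect_equal(d$values, c(1000, 0))
  expect_equal(difference_spectrum(expected, expected)$values, c(0, 0))
  # antisymmetry under argument swap
  expect_equal(difference_spectrum(mixture, expected)$values, -d$values)
  short <- cd_spectrum(c(200, 221), c(-7000, -5000), unit = "MRE")
  expect_error(difference_spectrum(expected, short), "different wavelength grids")
})

test_that("resampling interpolates linearly and refuses extrapolation", {
  s <- cd_spectrum(c(199, 201), c(4, 6), unit = "MRE")
  expect_equal(resample_spectrum(s, 200)$values, 5)
  expect_error(resample_spectrum(s, c(198, 200)), "exceeds measured span")
})

test_that("co-solvent dilution plans follow conservation of moles and volume", {
  p20 <- plan_dilution(320, 12.5, 80)
  expect_equal(p20$final_conc_uM, 10)
  expect_equal(p20$additive_pct_vv, 20)
  p40 <- plan_dilution(240, 17, 160)
  expect_equal(p40$final_conc_uM, 10.2)
  expect_equal(p40$additive_pct_vv, 40)
  none <- plan_dilution(100, 7, 0)
  expect_equal(none$final_conc_uM, 7)
  expect_equal(none$additive_pct_vv, 0)
  expect_error(plan_dilution(0, 5, 0), "total volume")
  expect_error(plan_dilution(100, -1, 10), "concentration")
})

test_that("spectral text dialects round-trip and enforce wavelength order", {
  wl <- 190:250
  set.seed(4)
  s <- cd_spectrum(wl, rnorm(length(wl)), unit = "millidegrees", id = "demo")
  f_txt <- withr::local_tempfile(fileext = ".txt")
  f_gen <- withr::local_tempfile(fileext = ".gen")
  write_cd_spectrum(s, f_txt)
  write_cd_spectrum(s, f_gen)
  # .gen stores descending wavelengths on disk
  first_data <- as.numeric(strsplit(grep("^#", readLines(f_gen), value = TRUE, invert = TRUE)[1], "\t")[[1]][1])
  expect_equal(first_data, 250)
  for (f in c(f_txt, f_gen)) {
    back <- read_cd_spectrum(f)
    expect_equal(back$wavelengths, s$wavelengths)
    expect_equal(back$values, s$values, tolerance = 1e-9)
  }
  # dialect mismatch is rejected
  expect_error(read_cd_spectrum(f_gen, dialect = "txt"), "ascending")
  expect_error(read_cd_spectrum(f_txt, dialect = "gen"), "descending")
  # header lines and comments are skipped in .txt
  f_hdr <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("wavelength value", "# comment", "200 1.5", "201 2.5"), f_hdr)
  h <- read_cd_spectrum(f_hdr)
  expect_equal(h$wavelengths, c(200, 201))
  expect_equal(h$values, c(1.5, 2.5))
})

test_that("CSV export writes wavelength, value, and unit columns", {
  s <- cd_spectrum(c(200, 222), c(-1, -2), unit = "MRE")
  f <- withr::local_tempfile(fileext = ".csv")
  write_cd_csv(s, f)
  tab <- utils::read.csv(f)
  expect_equal(tab$wavelength_nm, c(200, 222))
  expect_equal(tab$value, c(-1, -2))
  expect_equal(unique(tab$unit), "MRE")
})
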