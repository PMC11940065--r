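#' Sample metadata for mean-residue-ellipticity conversion
#'
#' The three quantities needed to normalize an instrument signal in
#' millidegrees to mean residue ellipticity: cuvette path length `l` (cm),
#' molar concentration `M` (mol/L), and the number of peptide bonds
#' `n` (residue count minus one).
#'
#' @param pathlength_cm path length in cm, > 0.
#' @param molarity_M molar concentration in mol/L, > 0.
#' @param n_peptide_bonds integer >= 1; for a sequence of `L` residues this is
#'   `L - 1` (see [sample_meta_from_sequence()]).
#' @return An object of class `sample_meta`.
#' @export
sample_meta <- function(pathlength_cm, molarity_M, n_peptide_bonds) {
  if (pathlength_cm <= 0) stop("pathlength_cm must be > 0")
  if (molarity_M <= 0) stop("molarity_M must be > 0")
  if (n_peptide_bonds < 1 || n_peptide_bonds != round(n_peptide_bonds)) {
    stop("n_peptide_bonds must be an integer >= 1")
  }
  structure(
    list(pathlength_cm = pathlength_cm, molarity_M = molarity_M,
         n_peptide_bonds = as.integer(n_peptide_bonds)),
    class = "sample_meta"
  )
}

#' @rdname sample_meta
#' @param seq a [protein_sequence()]; supplies `n_peptide_bonds = length - 1`.
#' @export
sample_meta_from_sequence <- function(seq, pathlength_cm, molarity_M) {
  stopifnot(inherits(seq, "protein_sequence"))
  sample_meta(pathlength_cm, molarity_M, nchar(seq$residues) - 1L)
}

#' Metadata for a two-component mixture
#'
#' @param component_a,component_b [sample_meta()] for the two species; they
#'   must share the cuvette path length.
#' @return An object of class `mixture_meta`.
#' @export
mixture_meta <- function(component_a, component_b) {
  stopifnot(inherits(component_a, "sample_meta"), inherits(component_b, "sample_meta"))
  if (abs(component_a$pathlength_cm - component_b$pathlength_cm) > 1e-12) {
    stop("mixture components must share the cuvette path length")
  }
  structure(list(component_a = component_a, component_b = component_b),
            class = "mixture_meta")
}

CD_UNITS <- c("millidegrees", "MRE", "ME")

#' Construct a CD spectrum
#'
#' A wavelength-indexed far-UV circular dichroism signal with an explicit
#' unit state. All spectral arithmetic in the package refuses to mix units or
#' wavelength grids, so the unit tag travels with the object from raw
#' millidegrees through mean residue ellipticity (MRE, deg cm^2 dmol^-1) to
#' the molar-extinction scale (ME = MRE / 3298).
#'
#' @param wavelengths strictly monotonic numeric grid in nm, within
#'   \[170, 300\].
#' @param values one signal value per wavelength.
#' @param unit one of `"millidegrees"`, `"MRE"`, `"ME"`.
#' @param meta optional [sample_meta()].
#' @param id text label.
#' @return An object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelengths, values, unit = "millidegrees", meta = NULL, id = "spectrum") {
  unit <- match.arg(unit, CD_UNITS)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values)) {
    stop("wavelengths and values must have equal length")
  }
  if (length(wavelengths) < 1L) stop("spectrum must contain at least one point")
  d <- diff(wavelengths)
  if (length(d) > 0 && !(all(d > 0) || all(d < 0))) {
    stop("wavelength grid must be strictly monotonic")
  }
  if (any(wavelengths < 170 | wavelengths > 300)) {
    stop("wavelengths must lie within [170, 300] nm")
  }
  # store ascending internally; I/O dialects handle ordering
  if (length(d) > 0 && all(d < 0)) {
    ord <- order(wavelengths)
    wavelengths <- wavelengths[ord]
    values <- values[ord]
  }
  if (!is.null(meta)) stopifnot(inherits(meta, "sample_meta") || inherits(meta, "mixture_meta"))
  structure(
    list(wavelengths = wavelengths, values = values, unit = unit, meta = meta, id = id),
    class = "cd_spectrum"
  )
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf("<cd_spectrum> %s: %d points, %.0f-%.0f nm, unit %s\n",
              x$id, length(x$wavelengths), min(x$wavelengths), max(x$wavelengths), x$unit))
  invisible(x)
}

# grid and unit mismatches are input-validation failures: they carry a
# condition class so the pipeline driver can map them to exit status 1
input_error <- function(msg) {
  stop(structure(class = c("idrflex_validation_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

check_same_grid <- function(a, b, what = "spectra") {
  if (length(a$wavelengths) != length(b$wavelengths) ||
      any(abs(a$wavelengths - b$wavelengths) > 1e-9)) {
    input_error(sprintf(
      "%s are on different wavelength grids (%.6g-%.6g nm, %d pts vs %.6g-%.6g nm, %d pts); resample explicitly first",
      what,
      min(a$wavelengths), max(a$wavelengths), length(a$wavelengths),
      min(b$wavelengths), max(b$wavelengths), length(b$wavelengths)
    ))
  }
}

check_unit <- function(spec, unit) {
  if (!identical(spec$unit, unit)) {
    input_error(sprintf("expected unit '%s' but spectrum '%s' is in '%s'", unit, spec$id, spec$unit))
  }
}

#' Subtract a blank spectrum
#'
#' Pointwise sample minus blank, both in millidegrees on the same grid; the
#' standard baseline correction applied before any unit conversion.
#'
#' @param sample,blank `cd_spectrum` objects in millidegrees on one grid.
#' @export
subtract_blank <- function(sample, blank) {
  stopifnot(inherits(sample, "cd_spectrum"), inherits(blank, "cd_spectrum"))
  check_unit(sample, "millidegrees"); check_unit(blank, "millidegrees")
  check_same_grid(sample, blank, "sample and blank")
  cd_spectrum(sample$wavelengths, sample$values - blank$values,
              unit = "millidegrees", meta = sample$meta,
              id = paste0(sample$id, "_blanked"))
}

#' Convert millidegrees to mean residue ellipticity
#'
#' `MRE = m° / (10 * l * M * n)` with path length `l` in cm, molarity `M`
#' in mol/L and `n` peptide bonds; the result is in deg cm^2 dmol^-1.
#'
#' @param spectrum `cd_spectrum` in millidegrees.
#' @param meta [sample_meta()]; defaults to the spectrum's own metadata.
#' @export
to_mre <- function(spectrum, meta = spectrum$meta) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  check_unit(spectrum, "millidegrees")
  if (!inherits(meta, "sample_meta")) stop("to_mre requires sample_meta")
  denom <- 10 * meta$pathlength_cm * meta$molarity_M * meta$n_peptide_bonds
  cd_spectrum(spectrum$wavelengths, spectrum$values / denom,
              unit = "MRE", meta = meta, id = spectrum$id)
}

#' Convert a mixture signal in millidegrees to MRE
#'
#' Two normalization conventions are provided for a 1:1 two-component
#' mixture. `"paper"` divides by
#' `10 * l * ((M_A + M_B)/2) * ((n_A + n_B)/2)`, the printed mixture
#' formula. `"total-residue"` (the default) divides by
#' `10 * l * (M_A n_A + M_B n_B)`, which makes a strictly non-interacting
#' mixture reproduce the concentration-weighted mean of the component MRE
#' spectra exactly. The printed convention instead returns the *sum* of the
#' component MREs for an equimolar, equal-length non-interacting pair, so
#' the two conventions differ by a known factor; see the methods vignette.
#'
#' @param spectrum `cd_spectrum` in millidegrees.
#' @param mix [mixture_meta()].
#' @param convention `"total-residue"` or `"paper"`.
#' @export
to_mre_mixture <- function(spectrum, mix, convention = c("total-residue", "paper")) {
  stopifnot(inherits(spectrum, "cd_spectrum"), inherits(mix, "mixture_meta"))
  convention <- match.arg(convention)
  check_unit(spectrum, "millidegrees")
  a <- mix$component_a; b <- mix$component_b
  denom <- if (convention == "paper") {
    10 * a$pathlength_cm * ((a$molarity_M + b$molarity_M) / 2) *
      ((a$n_peptide_bonds + b$n_peptide_bonds) / 2)
  } else {
    10 * a$pathlength_cm *
      (a$molarity_M * a$n_peptide_bonds + b$molarity_M * b$n_peptide_bonds)
  }
  cd_spectrum(spectrum$wavelengths, spectrum$values / denom,
              unit = "MRE", meta = mix, id = spectrum$id)
}

#' Convert between MRE and the molar-extinction scale
#'
#' `ME = MRE / 3298`; the inverse multiplies by 3298. The round trip is the
#' identity to machine precision.
#'
#' @param spectrum `cd_spectrum` in the unit matching `direction`.
#' @param direction `"MRE_to_ME"` or `"ME_to_MRE"`.
#' @export
convert_mre_me <- function(spectrum, direction = c("MRE_to_ME", "ME_to_MRE")) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  direction <- match.arg(direction)
  if (direction == "MRE_to_ME") {
    check_unit(spectrum, "MRE")
    cd_spectrum(spectrum$wavelengths, spectrum$values / 3298,
                unit = "ME", meta = spectrum$meta, id = spectrum$id)
  } else {
    check_unit(spectrum, "ME")
    cd_spectrum(spectrum$wavelengths, spectrum$values * 3298,
                unit = "MRE", meta = spectrum$meta, id = spectrum$id)
  }
}

#' Average replicate spectra
#'
#' Pointwise arithmetic mean of replicate acquisitions sharing a grid and
#' unit.
#'
#' @param spectra non-empty list of `cd_spectrum`.
#' @export
average_spectra <- function(spectra) {
  if (length(spectra) == 0L) stop("cannot average an empty list of spectra")
  lapply(spectra, function(s) stopifnot(inherits(s, "cd_spectrum")))
  ref <- spectra[[1]]
  for (s in spectra[-1]) {
    if (!identical(s$unit, ref$unit)) stop("cannot average spectra with mixed units")
    check_same_grid(ref, s)
  }
  vals <- rowMeans(vapply(spectra, function(s) s$values, numeric(length(ref$values))))
  cd_spectrum(ref$wavelengths, vals, unit = ref$unit, meta = ref$meta,
              id = paste0(ref$id, "_avg", length(spectra)))
}

#' Expected spectrum of a non-interacting mixture
#'
#' The spectrum one would expect if both proteins were in solution but not
#' interacting. `"arithmetic"` takes the pointwise mean of the two MRE
#' spectra (the convention of the source workflow); `"weighted"` weights each
#' component by its molar concentration times residue-bond count,
#' `(M_A n_A MRE_A + M_B n_B MRE_B) / (M_A n_A + M_B n_B)`, which is the
#' physically additive expectation.
#'
#' @param spec_a,spec_b `cd_spectrum` in MRE on one grid.
#' @param mode `"arithmetic"` or `"weighted"`.
#' @param meta_a,meta_b [sample_meta()] needed for `"weighted"`; default to
#'   each spectrum's own metadata.
#' @export
expected_noninteracting <- function(spec_a, spec_b, mode = c("arithmetic", "weighted"),
                                    meta_a = spec_a$meta, meta_b = spec_b$meta) {
  stopifnot(inherits(spec_a, "cd_spectrum"), inherits(spec_b, "cd_spectrum"))
  mode <- match.arg(mode)
  check_unit(spec_a, "MRE"); check_unit(spec_b, "MRE")
  check_same_grid(spec_a, spec_b)
  if (mode == "arithmetic") {
    vals <- (spec_a$values + spec_b$values) / 2
  } else {
    if (!inherits(meta_a, "sample_meta") || !inherits(meta_b, "sample_meta")) {
      stop("weighted mode requires sample_meta for both components")
    }
    wa <- meta_a$molarity_M * meta_a$n_peptide_bonds
    wb <- meta_b$molarity_M * meta_b$n_peptide_bonds
    vals <- (wa * spec_a$values + wb * spec_b$values) / (wa + wb)
  }
  cd_spectrum(spec_a$wavelengths, vals, unit = "MRE",
              id = sprintf("expected_%s(%s,%s)", mode, spec_a$id, spec_b$id))
}

#' Partner-induced difference spectrum
#'
#' Expected non-interacting spectrum minus the measured 1:1 mixture spectrum
#' (the mixture is subtracted *from* the expectation). Deviations from zero
#' denote secondary structure not predicted from a non-interacting mixture.
#'
#' @param expected,experimental_mixture `cd_spectrum` in MRE on one grid.
#' @export
difference_spectrum <- function(expected, experimental_mixture) {
  stopifnot(inherits(expected, "cd_spectrum"), inherits(experimental_mixture, "cd_spectrum"))
  check_unit(expected, "MRE"); check_unit(experimental_mixture, "MRE")
  check_same_grid(expected, experimental_mixture, "expected and mixture spectra")
  cd_spectrum(expected$wavelengths, expected$values - experimental_mixture$values,
              unit = "MRE",
              id = sprintf("diff(%s-%s)", expected$id, experimental_mixture$id))
}

#' Resample a spectrum onto a new grid by linear interpolation
#'
#' Arithmetic operations never interpolate silently; call this first when
#' grids differ. Extrapolation outside the measured span is refused.
#'
#' @param spectrum a `cd_spectrum`.
#' @param wavelengths target grid, within the measured span.
#' @export
resample_spectrum <- function(spectrum, wavelengths) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  wavelengths <- as.numeric(wavelengths)
  if (min(wavelengths) < min(spectrum$wavelengths) - 1e-9 ||
      max(wavelengths) > max(spectrum$wavelengths) + 1e-9) {
    stop(sprintf("target grid %.6g-%.6g nm exceeds measured span %.6g-%.6g nm",
                 min(wavelengths), max(wavelengths),
                 min(spectrum$wavelengths), max(spectrum$wavelengths)))
  }
  vals <- stats::approx(spectrum$wavelengths, spectrum$values, xout = wavelengths)$y
  cd_spectrum(wavelengths, vals, unit = spectrum$unit, meta = spectrum$meta,
              id = spectrum$id)
}

#' Plan a co-solvent dilution
#'
#' Mixing `additive_volume` of a co-solvent (e.g. TFE) into `sample_volume`
#' of protein at `sample_conc` dilutes the protein to
#' `sample_conc * sample_volume / (sample_volume + additive_volume)` and
#' gives an additive fraction of `100 * additive_volume / total` percent v/v.
#'
#' @param sample_volume_uL,additive_volume_uL volumes in microlitres, >= 0.
#' @param sample_conc_uM protein concentration in micromolar, > 0.
#' @return A list of class `dilution_plan` with the inputs plus
#'   `final_conc_uM` and `additive_pct_vv`.
#' @examples
#' plan_dilution(320, 12.5, 80) # 10 uM final, 20% v/v
#' @export
plan_dilution <- function(sample_volume_uL, sample_conc_uM, additive_volume_uL) {
  if (sample_volume_uL < 0 || additive_volume_uL < 0) stop("volumes must be >= 0")
  if (sample_conc_uM <= 0) stop("sample concentration must be > 0")
  total <- sample_volume_uL + additive_volume_uL
  if (total <= 0) stop("total volume must be > 0")
  structure(
    list(
      sample_volume_uL = sample_volume_uL,
      sample_conc_uM = sample_conc_uM,
      additive_volume_uL = additive_volume_uL,
      final_conc_uM = sample_conc_uM * sample_volume_uL / total,
      additive_pct_vv = 100 * additive_volume_uL / total
    ),
    class = "dilution_plan"
  )
}

#' @export
print.dilution_plan <- function(x, ...) {
  cat(sprintf(
    "<dilution_plan> %g uL additive into %g uL of %g uM sample -> %.4g uM final, %.4g%% v/v\n",
    x$additive_volume_uL, x$sample_volume_uL, x$sample_conc_uM,
    x$final_conc_uM, x$additive_pct_vv
  ))
  invisible(x)
}
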