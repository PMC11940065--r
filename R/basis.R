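gauss_band <- function(wl, center, width, amplitude) {
  amplitude * exp(-(wl - center)^2 / (2 * width^2))
}

#' Reference basis set for secondary-structure deconvolution
#'
#' A basis set holds one reference MRE spectrum per secondary-structure
#' class on a shared wavelength grid. [default_basis()] builds a parametric
#' synthetic basis from sums of Gaussian bands at the canonical far-UV CD
#' positions: the helix spectrum has a positive band near 193 nm and the
#' 208/222 nm double minimum; sheet a positive band near 195 nm and a single
#' minimum near 218 nm; turn a weak positive near 206 nm; and the disordered
#' class the deep minimum near 198 nm typical of unordered chains.
#' Amplitudes approximate the magnitudes of fully formed structure in
#' deg cm^2 dmol^-1. Any user basis on the same layout can be supplied via
#' [basis_set()] or [read_basis_csv()].
#'
#' @param wavelengths shared grid in nm.
#' @param spectra named list (class label -> numeric vector on the grid) of
#'   reference MRE spectra; >= 2 unique labels.
#' @return An object of class `basis_set` with fields `wavelengths`,
#'   `classes`, and `matrix` (wavelength x class).
#' @export
basis_set <- function(wavelengths, spectra) {
  wavelengths <- as.numeric(wavelengths)
  if (length(spectra) < 2L) stop("basis needs at least 2 classes")
  labels <- names(spectra)
  if (is.null(labels) || anyDuplicated(labels) || any(!nzchar(labels))) {
    stop("basis class labels must be unique and non-empty")
  }
  mat <- vapply(spectra, function(v) {
    v <- as.numeric(v)
    if (length(v) != length(wavelengths)) {
      stop("every reference spectrum must be on the shared wavelength grid")
    }
    v
  }, numeric(length(wavelengths)))
  if (qr(mat)$rank < ncol(mat)) stop("basis spectra are collinear/duplicated")
  structure(list(wavelengths = wavelengths, classes = labels, matrix = mat),
            class = "basis_set")
}

#' @rdname basis_set
#' @export
default_basis <- function(wavelengths = 190:250) {
  wl <- as.numeric(wavelengths)
  basis_set(wl, list(
    helix      = gauss_band(wl, 193, 6, 70000) + gauss_band(wl, 208, 7, -32000) +
                 gauss_band(wl, 222, 8, -32000),
    sheet      = gauss_band(wl, 195, 6, 32000) + gauss_band(wl, 218, 9, -18000),
    turn       = gauss_band(wl, 206, 8, 9000)  + gauss_band(wl, 190, 5, -12000),
    disordered = gauss_band(wl, 198, 7, -42000) + gauss_band(wl, 222, 12, 2500)
  ))
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<basis_set> %d classes (%s), %d points %.0f-%.0f nm\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Read/write basis sets as multi-column CSV
#'
#' Column 1 is `wavelength_nm`; every further column is one class spectrum.
#' @param path CSV file.
#' @export
read_basis_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (ncol(tab) < 3L) stop("basis CSV needs wavelength_nm plus >= 2 class columns")
  basis_set(tab[[1]], as.list(tab[-1]))
}

#' @rdname read_basis_csv
#' @param basis a `basis_set`.
#' @export
write_basis_csv <- function(basis, path) {
  stopifnot(inherits(basis, "basis_set"))
  tab <- data.frame(wavelength_nm = basis$wavelengths, basis$matrix, check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
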