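#' Read a two-column CD spectral text file
#'
#' Two dialects are supported: `.txt` files carry ascending wavelengths and
#' may start with a non-numeric header line; `.gen` files carry the same two
#' columns with wavelengths in descending order. Lines beginning with `#`
#' are ignored in both. The dialect is inferred from the file extension
#' unless given explicitly.
#'
#' @param path input file.
#' @param unit unit of the value column (the file formats do not record it).
#' @param dialect `"txt"`, `"gen"`, or `"auto"` (by extension).
#' @param meta optional [sample_meta()] to attach.
#' @return A [cd_spectrum()] (stored with ascending wavelengths).
#' @export
read_cd_spectrum <- function(path, unit = "millidegrees",
                             dialect = c("auto", "txt", "gen"), meta = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gen$", path, ignore.case = TRUE)) "gen" else "txt"
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop(sprintf("no data lines in '%s'", path))
  fields <- strsplit(lines, "[,;[:space:]]+")
  is_numeric_row <- vapply(fields, function(f) {
    length(f) >= 2L && !anyNA(suppressWarnings(as.numeric(f[1:2])))
  }, logical(1))
  fields <- fields[is_numeric_row] # non-numeric header rows dropped
  if (length(fields) == 0L) stop(sprintf("no numeric wavelength/value rows in '%s'", path))
  wl <- vapply(fields, function(f) as.numeric(f[1]), numeric(1))
  val <- vapply(fields, function(f) as.numeric(f[2]), numeric(1))
  d <- diff(wl)
  if (dialect == "gen" && length(d) > 0 && any(d > 0)) {
    stop(sprintf("'%s': .gen dialect requires descending wavelengths", path))
  }
  if (dialect == "txt" && length(d) > 0 && any(d < 0)) {
    stop(sprintf("'%s': .txt dialect requires ascending wavelengths", path))
  }
  cd_spectrum(wl, val, unit = unit, meta = meta,
              id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a CD spectrum as two-column text
#'
#' `.txt` writes ascending wavelengths; `.gen` writes the same columns in
#' descending wavelength order.
#'
#' @param spectrum a [cd_spectrum()].
#' @param path output file.
#' @param dialect `"txt"`, `"gen"`, or `"auto"` (by extension).
#' @export
write_cd_spectrum <- function(spectrum, path, dialect = c("auto", "txt", "gen")) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gen$", path, ignore.case = TRUE)) "gen" else "txt"
  }
  ord <- if (dialect == "gen") order(spectrum$wavelengths, decreasing = TRUE) else order(spectrum$wavelengths)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s unit=%s", spectrum$id, spectrum$unit), con)
  writeLines(sprintf("%.6g\t%.10g", spectrum$wavelengths[ord], spectrum$values[ord]), con)
  invisible(path)
}

#' Export a spectrum as CSV
#'
#' Columns `wavelength_nm`, `value`, `unit`.
#' @param spectrum a [cd_spectrum()].
#' @param path output file.
#' @export
write_cd_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  utils::write.csv(
    data.frame(wavelength_nm = spectrum$wavelengths,
               value = spectrum$values,
               unit = spectrum$unit),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
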