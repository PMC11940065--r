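#' Residue propensity scale
#'
#' A named mapping from each of the twenty canonical residues to a real
#' number, e.g. a hydropathy or charge scale.
#'
#' @param values named numeric vector with exactly one finite entry per
#'   canonical residue.
#' @param name text label.
#' @return An object of class `propensity_scale`.
#' @export
propensity_scale <- function(values, name = "scale") {
  values <- unlist(values)
  if (length(values) != 20L || !setequal(names(values), AMINO_ACIDS)) {
    stop("scale must map exactly the 20 canonical residues")
  }
  if (any(!is.finite(values))) stop("scale values must all be finite")
  structure(list(name = name, values = values[AMINO_ACIDS]), class = "propensity_scale")
}

#' Read a propensity scale from a two-column TSV
#'
#' Expects columns `residue` and `value`.
#' @param path TSV file.
#' @param name label; defaults to the file stem.
#' @export
read_propensity_scale <- function(path, name = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  propensity_scale(stats::setNames(tab$value, tab$residue), name = name)
}

#' Default scales shipped with the package
#'
#' `default_hydropathy_scale()` is the Kyte--Doolittle hydropathy index;
#' `default_charge_scale()` assigns +1 to K/R, -1 to D/E and 0 elsewhere.
#' Both are read from plain-text files under `inst/extdata` so they can be
#' inspected or swapped.
#' @return A [propensity_scale()].
#' @export
default_hydropathy_scale <- function() {
  read_propensity_scale(
    system.file("extdata", "kyte_doolittle.tsv", package = "idrflex"),
    name = "kyte_doolittle"
  )
}

#' @rdname default_hydropathy_scale
#' @export
default_charge_scale <- function() {
  read_propensity_scale(
    system.file("extdata", "net_charge.tsv", package = "idrflex"),
    name = "net_charge"
  )
}

windowed_mean <- function(x, halfwidth) {
  L <- length(x)
  if (halfwidth == 0L) return(x)
  out <- numeric(L)
  for (i in seq_len(L)) {
    lo <- max(1L, i - halfwidth)
    hi <- min(L, i + halfwidth)
    out[i] <- mean(x[lo:hi])
  }
  out
}

#' Per-residue disorder scores
#'
#' A closed-form charge/hydropathy disorder predictor in the FoldIndex and
#' TopIDP tradition. For each residue a window of `2*window_halfwidth + 1`
#' positions (truncated at the termini) yields the mean hydropathy
#' (Kyte--Doolittle rescaled to \[0, 1\]) and the magnitude of the mean net
#' charge; these are combined linearly and squashed through a logistic so
#' that scores lie in \[0, 1\] with higher = more disordered. Positions with
#' score >= 0.5 are labelled disordered.
#'
#' The default coefficients (`weight_charge = 0.75`, `weight_hydropathy = 3`,
#' `intercept = 1.2`, `steepness = 4`) orient and calibrate the score so that
#' disorder-biased compositions (charged/hydrophilic) fall above 0.5 and
#' order-biased compositions (aromatic/aliphatic) fall below it. They also
#' guarantee that replacing a glutamate with tryptophan can never increase
#' the score: the hydropathy gain per window position,
#' `weight_hydropathy * 2.6/9 = 0.867`, strictly exceeds the largest possible
#' rise in the charge term, `weight_charge = 0.75`.
#'
#' @param seq a [protein_sequence()].
#' @param scale hydropathy-like [propensity_scale()]; default Kyte--Doolittle.
#' @param charge_scale charge [propensity_scale()]; default +1 K/R, -1 D/E.
#' @param window_halfwidth non-negative integer; 0 makes each score depend
#'   only on its own residue.
#' @param weight_charge,weight_hydropathy,intercept,steepness coefficients of
#'   the logistic combination.
#' @return An object of class `disorder_profile`: list with `sequence_id`,
#'   `window_halfwidth`, `scores` (one per residue, in \[0, 1\]) and
#'   `disordered` (logical, `scores >= 0.5`).
#' @examples
#' p <- score_disorder(protein_sequence(strrep("E", 20)))
#' mean(p$scores) # well above 0.5: poly-E is strongly disorder-promoting
#' @export
score_disorder <- function(seq,
                           scale = default_hydropathy_scale(),
                           charge_scale = default_charge_scale(),
                           window_halfwidth = 10L,
                           weight_charge = 0.75,
                           weight_hydropathy = 3,
                           intercept = 1.2,
                           steepness = 4) {
  stopifnot(inherits(seq, "protein_sequence"))
  if (window_halfwidth < 0 || window_halfwidth != round(window_halfwidth)) {
    stop("window_halfwidth must be a non-negative integer")
  }
  chars <- seq_chars(seq)
  hvals <- scale$values[chars]
  hspan <- diff(range(scale$values))
  hnorm <- if (hspan > 0) (hvals - min(scale$values)) / hspan else rep(0, length(hvals))
  cvals <- charge_scale$values[chars]
  hbar <- windowed_mean(hnorm, as.integer(window_halfwidth))
  cbar <- windowed_mean(cvals, as.integer(window_halfwidth))
  raw <- intercept + weight_charge * abs(cbar) - weight_hydropathy * hbar
  scores <- stats::plogis(steepness * raw)
  structure(
    list(
      sequence_id = seq$id,
      window_halfwidth = as.integer(window_halfwidth),
      scores = unname(scores),
      disordered = unname(scores >= 0.5)
    ),
    class = "disorder_profile"
  )
}

#' @export
print.disorder_profile <- function(x, ...) {
  cat(sprintf(
    "<disorder_profile> %s: %d residues, mean score %.3f, %d disordered (>= 0.5)\n",
    x$sequence_id, length(x$scores), mean(x$scores), sum(x$disordered)
  ))
  invisible(x)
}

#' Mean disorder over a residue interval
#'
#' Arithmetic mean of per-residue disorder scores over the closed interval
#' `[start, end]` (1-based), the statistic conventionally reported as a
#' region's average disorder.
#'
#' @param profile a `disorder_profile`.
#' @param start,end interval bounds, `1 <= start <= end <= L`.
#' @export
region_mean_disorder <- function(profile, start, end) {
  stopifnot(inherits(profile, "disorder_profile"))
  L <- length(profile$scores)
  if (start < 1 || end > L || start > end ||
      start != round(start) || end != round(end)) {
    stop(sprintf("invalid interval [%s, %s] for profile of length %d",
                 format(start), format(end), L))
  }
  mean(profile$scores[start:end])
}

#' Exhaustive disorder-to-order substitution scan
#'
#' Replace-and-test scanning: every scanned position is substituted with each
#' of the other 19 residues, the full variant sequence is re-scored, and the
#' change in mean disorder (`delta_mean_disorder` = wild mean minus variant
#' mean, so positive = order-conferring) is recorded. Results are ranked by
#' order gain, the ranking used to nominate disorder-to-order candidate
#' variants.
#'
#' @param seq a [protein_sequence()].
#' @param positions positions to scan; default all.
#' @param window `"sequence"` scores the delta over the whole sequence
#'   (default); `"local"` restricts the mean to the window
#'   `position +/- window_halfwidth`.
#' @param ... passed to [score_disorder()] (scales, window, coefficients).
#' @return An object of class `scan_result`: a list with `effects` (a
#'   data.frame with columns `position`, `wild`, `substitute`,
#'   `delta_mean_disorder`, `rank`, sorted descending by order gain, ties by
#'   position then substitute) and `scope`.
#' @export
scan_substitutions <- function(seq, positions = NULL, window = c("sequence", "local"), ...) {
  stopifnot(inherits(seq, "protein_sequence"))
  window <- match.arg(window)
  L <- nchar(seq$residues)
  if (is.null(positions)) positions <- seq_len(L)
  positions <- as.integer(positions)
  if (length(positions) == 0L) stop("empty position subset")
  if (any(positions < 1L | positions > L)) stop("scan positions out of sequence bounds")
  dots <- list(...)
  hw <- if (!is.null(dots$window_halfwidth)) as.integer(dots$window_halfwidth) else 10L
  wt_profile <- score_disorder(seq, ...)
  chars <- seq_chars(seq)
  local_mean <- function(scores, pos) {
    lo <- max(1L, pos - hw); hi <- min(L, pos + hw)
    mean(scores[lo:hi])
  }
  rows <- vector("list", length(positions) * 19L)
  k <- 0L
  for (pos in positions) {
    wild <- chars[pos]
    wt_mean <- if (window == "sequence") mean(wt_profile$scores) else local_mean(wt_profile$scores, pos)
    for (sub in setdiff(AMINO_ACIDS, wild)) {
      var_seq <- apply_substitution(seq, pos, sub)
      var_profile <- score_disorder(var_seq, ...)
      var_mean <- if (window == "sequence") mean(var_profile$scores) else local_mean(var_profile$scores, pos)
      k <- k + 1L
      rows[[k]] <- data.frame(
        position = pos, wild = wild, substitute = sub,
        delta_mean_disorder = wt_mean - var_mean,
        stringsAsFactors = FALSE
      )
    }
  }
  effects <- do.call(rbind, rows)
  ord <- order(-effects$delta_mean_disorder, effects$position, effects$substitute)
  effects <- effects[ord, , drop = FALSE]
  rownames(effects) <- NULL
  effects$rank <- seq_len(nrow(effects))
  structure(
    list(effects = effects, scope = positions, window = window,
         sequence_id = seq$id),
    class = "scan_result"
  )
}

#' @export
print.scan_result <- function(x, n = 5L, ...) {
  cat(sprintf("<scan_result> %s: %d substitutions over %d positions (%s delta)\n",
              x$sequence_id, nrow(x$effects), length(x$scope), x$window))
  print(utils::head(x$effects, n))
  invisible(x)
}

#' Write scan results as TSV
#'
#' Columns: position, wild, substitute, delta_mean_disorder, rank.
#' @param scan a `scan_result`.
#' @param path output file.
#' @export
write_scan_tsv <- function(scan, path) {
  stopifnot(inherits(scan, "scan_result"))
  utils::write.table(scan$effects, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
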