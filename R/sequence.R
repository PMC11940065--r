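#' Canonical amino-acid alphabet
#'
#' The twenty one-letter codes accepted throughout the package.
#' @export
AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Residue sets promoting order or disorder
#'
#' Conventional partition of residues by their tendency to promote fixed
#' structure (order) or conformational flexibility (disorder). Used by the
#' synthetic sequence generator and available for composition summaries.
#' @format A list with elements `order` and `disorder`, each a character vector.
#' @export
RESIDUE_CLASSES <- list(
  order    = c("W", "C", "F", "I", "Y", "V", "L", "N"),
  disorder = c("A", "R", "G", "Q", "S", "P", "E", "K")
)

#' Construct a protein sequence
#'
#' @param residues single string over the 20 canonical one-letter codes.
#' @param id text label.
#' @return An object of class `protein_sequence` with fields `id` and
#'   `residues`.
#' @examples
#' protein_sequence("MKEEVQA", id = "demo")
#' @export
protein_sequence <- function(residues, id = "seq") {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) < 1L) stop("sequence must contain at least one residue")
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% AMINO_ACIDS)
  if (length(bad) > 0L) {
    stop(sprintf(
      "non-canonical residue '%s' at position %d of sequence '%s'",
      chars[bad[1]], bad[1], id
    ))
  }
  structure(list(id = id, residues = residues), class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s (%d aa)\n", x$id, nchar(x$residues)))
  cat(x$residues, "\n")
  invisible(x)
}

#' @export
length.protein_sequence <- function(x) nchar(x$residues)

seq_chars <- function(seq) strsplit(seq$residues, "")[[1]]

#' Substitute one residue of a sequence
#'
#' Returns a copy of `seq` with the residue at `position` replaced by
#' `residue`. Substituting a residue with itself is permitted but flagged via
#' the `no_op` attribute, since an exhaustive substitution scan excludes such
#' identities.
#'
#' @param seq a [protein_sequence()].
#' @param position 1-based residue index.
#' @param residue canonical one-letter code to substitute in.
#' @return A `protein_sequence`; attribute `no_op` is `TRUE` when the
#'   substitution leaves the sequence unchanged.
#' @examples
#' apply_substitution(protein_sequence("ACD"), 2, "W")
#' @export
apply_substitution <- function(seq, position, residue) {
  stopifnot(inherits(seq, "protein_sequence"))
  L <- nchar(seq$residues)
  if (!is.numeric(position) || length(position) != 1L ||
      position < 1L || position > L || position != round(position)) {
    stop(sprintf("position must be an integer in [1, %d], got %s", L, format(position)))
  }
  residue <- toupper(residue)
  if (!residue %in% AMINO_ACIDS) stop(sprintf("non-canonical residue '%s'", residue))
  chars <- seq_chars(seq)
  wild <- chars[position]
  chars[position] <- residue
  out <- protein_sequence(
    paste(chars, collapse = ""),
    id = sprintf("%s_%s%d%s", seq$id, wild, position, residue)
  )
  attr(out, "no_op") <- identical(wild, residue)
  out
}

#' Read protein sequences from FASTA
#'
#' Aligned FASTA (with `-` gap characters) is accepted when `aligned = TRUE`;
#' gaps are preserved in the returned strings for downstream conservation
#' scoring.
#'
#' @param path FASTA file.
#' @param aligned keep gap characters rather than rejecting them.
#' @return A list of `protein_sequence` objects (`aligned = FALSE`) or a named
#'   character vector of gapped rows (`aligned = TRUE`).
#' @export
read_fasta_sequences <- function(path, aligned = FALSE) {
  raw <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE, forceDNAtolower = FALSE)
  strings <- toupper(vapply(raw, function(s) as.character(s)[1], character(1)))
  if (aligned) {
    return(strings)
  }
  mapply(function(s, nm) protein_sequence(gsub("-", "", s), id = nm),
         strings, names(strings), SIMPLIFY = FALSE)
}

#' Write protein sequences to FASTA
#'
#' @param seqs a `protein_sequence`, list of them, or named character vector
#'   (which may include `-` gaps for alignments).
#' @param path output file.
#' @export
write_fasta_sequences <- function(seqs, path) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  if (is.character(seqs)) {
    nms <- names(seqs)
    if (is.null(nms)) nms <- paste0("seq", seq_along(seqs))
    seqinr::write.fasta(as.list(seqs), names = nms, file.out = path, as.string = TRUE)
  } else {
    seqinr::write.fasta(
      lapply(seqs, function(s) s$residues),
      names = vapply(seqs, function(s) s$id, character(1)),
      file.out = path, as.string = TRUE
    )
  }
  invisible(path)
}

#' Alignment column conservation by Shannon entropy
#'
#' For each column of a multiple alignment the score is `1 - H / log(20)`,
#' where `H` is the Shannon entropy of the residue frequencies in the column
#' after removing gaps. A fully conserved column scores 1; a column in which
#' all twenty residues are equally frequent scores 0. All-gap columns have no
#' defined score and are reported as `NA`; columns with more than 50% gaps are
#' flagged.
#'
#' @param alignment named character vector or list of equal-length sequence
#'   strings, `-` as the gap character.
#' @return A data.frame with columns `column`, `score`, `gap_fraction`,
#'   `flagged_gappy`.
#' @export
column_conservation <- function(alignment) {
  if (inherits(alignment, "protein_sequence")) alignment <- list(alignment)
  strings <- vapply(alignment, function(s) {
    if (inherits(s, "protein_sequence")) s$residues else as.character(s)
  }, character(1))
  if (length(strings) < 2L) stop("alignment needs at least 2 sequences")
  lens <- nchar(strings)
  if (length(unique(lens)) != 1L) {
    stop(sprintf("ragged alignment: row lengths %s", paste(unique(lens), collapse = ", ")))
  }
  mat <- do.call(rbind, strsplit(toupper(strings), ""))
  ncolm <- ncol(mat)
  score <- numeric(ncolm)
  gapfrac <- numeric(ncolm)
  for (j in seq_len(ncolm)) {
    col <- mat[, j]
    gapfrac[j] <- mean(col == "-")
    res <- col[col != "-"]
    if (length(res) == 0L) {
      score[j] <- NA_real_
      next
    }
    bad <- setdiff(unique(res), AMINO_ACIDS)
    if (length(bad) > 0L) stop(sprintf("non-canonical residue '%s' in column %d", bad[1], j))
    p <- table(res) / length(res)
    H <- -sum(p * log(p))
    score[j] <- 1 - H / log(20)
  }
  data.frame(
    column = seq_len(ncolm),
    score = score,
    gap_fraction = gapfrac,
    flagged_gappy = gapfrac > 0.5
  )
}
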