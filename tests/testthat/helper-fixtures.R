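# Shared fixtures, built in code at test time.

# small 3-class basis with O(1) amplitudes for oracle comparisons
toy_basis <- function(wl = 190:240) {
  gb <- function(c0, w, a) a * exp(-(wl - c0)^2 / (2 * w^2))
  basis_set(wl, list(
    helix      = gb(193, 6, 7) + gb(222, 8, -4),
    sheet      = gb(195, 6, 3) + gb(218, 9, -2),
    disordered = gb(198, 7, -5)
  ))
}

# uniform-ish random point on the simplex
random_fractions <- function(k, classes = NULL) {
  f <- stats::rexp(k)
  f <- f / sum(f)
  if (!is.null(classes)) names(f) <- classes
  f
}

# brute-force substitution scan: independent re-implementation used as the
# oracle for scan_substitutions (string edits and ranking coded from scratch)
brute_force_scan <- function(seq, ...) {
  chars <- strsplit(seq$residues, "")[[1]]
  L <- length(chars)
  wt_mean <- mean(score_disorder(seq, ...)$scores)
  rows <- list()
  for (pos in 1:L) {
    for (aa in AMINO_ACIDS) {
      if (aa == chars[pos]) next
      v <- chars
      v[pos] <- aa
      vseq <- protein_sequence(paste(v, collapse = ""), id = "variant")
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos, wild = chars[pos], substitute = aa,
        delta_mean_disorder = wt_mean - mean(score_disorder(vseq, ...)$scores),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out[order(-out$delta_mean_disorder, out$position, out$substitute), , drop = FALSE]
}

# standard sample metadata used throughout the CD tests
meta_a <- function() sample_meta(0.1, 10e-6, 111L)
meta_b <- function() sample_meta(0.1, 10e-6, 227L)

null_mixture_config <- function(noise_sd = 0, seed = 1L) {
  synthetic_mixture_config(
    config_a = synthetic_cd_config(noise_sd = noise_sd, seed = seed),
    config_b = synthetic_cd_config(
      fractions = c(helix = 0.25, sheet = 0.35, turn = 0.2, disordered = 0.2),
      meta = meta_b(), noise_sd = noise_sd, seed = seed
    ),
    induced_delta = c(helix = 0, sheet = 0, turn = 0, disordered = 0),
    seed = seed
  )
}
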