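PIPELINE_SUBCOMMANDS <- c("scan", "cd-normalize", "cd-diff", "deconvolve",
                          "classify", "mst-fit", "simulate")

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "idrflex_out",
    log_level = "info",
    window_halfwidth = 10L,
    convention = "total-residue",
    expectation_mode = "weighted",
    ridge_lambda = 0,
    ct_M = 50e-9,
    pathlength_cm = 0.1,
    molarity_M = 10e-6,
    n_peptide_bonds = 111L,
    fit_range = c(190, 240),
    unit = "millidegrees"
  )
}

validation_error <- function(msg) {
  stop(structure(class = c("idrflex_validation_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

log_msg <- function(level, fmt, ..., threshold = "info") {
  levels <- c(debug = 1, info = 2, warning = 3, error = 4)
  if (levels[[level]] >= levels[[threshold]]) {
    message(sprintf("[%s] %s", toupper(level), sprintf(fmt, ...)))
  }
}

require_path <- function(path, what) {
  if (is.null(path)) validation_error(sprintf("missing required input: %s", what))
  if (!file.exists(path)) {
    validation_error(sprintf("%s does not exist: '%s'", what, path))
  }
  path
}

file_checksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0L) return(list())
  as.list(tools::md5sum(paths))
}

#' Run a pipeline stage
#'
#' Orchestrates the analysis stages as named subcommands over file inputs,
#' with a plain-text YAML configuration, explicit seeding, and a run
#' manifest. Parameter precedence is `overrides` (the CLI layer) over the
#' YAML `config_file` over package defaults; the fully resolved
#' configuration, package version, input/output checksums and any warnings
#' are written to `manifest.json` in the output directory for every run,
#' including failed ones, so each result file is reproducible from its
#' manifest alone. Inputs are never mutated.
#'
#' Subcommands and their main config keys:
#' \describe{
#'   \item{simulate}{writes a complete demo dataset (sequence FASTA, CD
#'     spectra, mixture triple, binding CSV) generated from `seed`.}
#'   \item{scan}{`fasta`: exhaustive substitution scan, TSV output.}
#'   \item{cd-normalize}{`spectrum` (+ optional `blank`), sample meta keys:
#'     blank subtraction and MRE conversion, CSV/text output.}
#'   \item{cd-diff}{`spectrum_a`, `spectrum_b`, `spectrum_mix` in
#'     millidegrees plus both sample metas: non-interacting expectation and
#'     difference spectrum under `convention`/`expectation_mode`.}
#'   \item{deconvolve}{`spectrum` in MRE (+ optional `basis`): fractions and
#'     NRMSD.}
#'   \item{classify}{`spectrum` in MRE + `reference` CSV: two-wavelength
#'     cohort assignment.}
#'   \item{mst-fit}{`binding` CSV + `ct_M`: K_D fit with saturation
#'     diagnostics.}
#' }
#'
#' @param subcommand one of `"scan"`, `"cd-normalize"`, `"cd-diff"`,
#'   `"deconvolve"`, `"classify"`, `"mst-fit"`, `"simulate"`.
#' @param overrides named list of parameter overrides (highest precedence).
#' @param config_file optional YAML file.
#' @return Invisibly, a list with `status` (0 success, 1 validation error,
#'   2 numerical failure), `outputs` (paths), `manifest` (path), and
#'   `result` (stage-specific object). Warnings and progress go to standard
#'   error.
#' @export
run_pipeline <- function(subcommand, overrides = list(), config_file = NULL) {
  subcommand <- match.arg(subcommand, PIPELINE_SUBCOMMANDS)
  cfg <- pipeline_defaults()
  if (!is.null(config_file)) {
    require_path(config_file, "config file")
    from_yaml <- yaml::read_yaml(config_file)
    cfg[names(from_yaml)] <- from_yaml
  }
  cfg[names(overrides)] <- overrides
  cfg$seed <- as.integer(cfg$seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  warnings <- character()
  if (cfg$convention == "paper") {
    warnings <- c(warnings, paste(
      "convention='paper' reproduces the printed mixture normalization, which",
      "sums rather than averages component ellipticities for a non-interacting",
      "equimolar pair; 'total-residue' preserves the null-interaction invariant"
    ))
  }
  outputs <- character()
  inputs <- character()
  status <- 0L
  error_msg <- NULL
  result <- NULL

  run_stage <- function() {
    switch(
      subcommand,
      "simulate" = {
        log_msg("info", "generating demo dataset (seed %d)", cfg$seed, threshold = cfg$log_level)
        seqn <- generate_sequence(synthetic_sequence_config(seed = cfg$seed))
        f_fasta <- file.path(cfg$out_dir, "sequence.fasta")
        write_fasta_sequences(seqn, f_fasta)
        spec <- simulate_cd(synthetic_cd_config(seed = cfg$seed))
        f_txt <- file.path(cfg$out_dir, "spectrum.txt")
        write_cd_spectrum(spec, f_txt)
        mixcfg <- synthetic_mixture_config(seed = cfg$seed)
        trio <- simulate_mixture(mixcfg)
        f_a <- file.path(cfg$out_dir, "component_a.txt")
        f_b <- file.path(cfg$out_dir, "component_b.txt")
        f_m <- file.path(cfg$out_dir, "mixture.txt")
        write_cd_spectrum(trio$a, f_a); write_cd_spectrum(trio$b, f_b)
        write_cd_spectrum(trio$mixture, f_m)
        curve <- simulate_binding(synthetic_binding_config(seed = cfg$seed))
        f_bind <- file.path(cfg$out_dir, "binding.csv")
        write_binding_csv(curve, f_bind)
        outputs <<- c(f_fasta, f_txt, f_a, f_b, f_m, f_bind)
        list(sequence = seqn, spectrum = spec, mixture = trio, binding = curve)
      },
      "scan" = {
        path <- require_path(cfg$fasta, "input FASTA ('fasta')")
        inputs <<- path
        seqs <- read_fasta_sequences(path)
        scan <- scan_substitutions(seqs[[1]], window_halfwidth = cfg$window_halfwidth)
        f_out <- file.path(cfg$out_dir, "scan.tsv")
        write_scan_tsv(scan, f_out)
        outputs <<- f_out
        scan
      },
      "cd-normalize" = {
        path <- require_path(cfg$spectrum, "input spectrum ('spectrum')")
        inputs <<- path
        spec <- read_cd_spectrum(path, unit = "millidegrees")
        if (!is.null(cfg$blank)) {
          bpath <- require_path(cfg$blank, "blank spectrum ('blank')")
          inputs <<- c(inputs, bpath)
          spec <- subtract_blank(spec, read_cd_spectrum(bpath, unit = "millidegrees"))
        }
        meta <- sample_meta(cfg$pathlength_cm, cfg$molarity_M, cfg$n_peptide_bonds)
        mre <- to_mre(spec, meta)
        f_out <- file.path(cfg$out_dir, "spectrum_mre.csv")
        write_cd_csv(mre, f_out)
        outputs <<- f_out
        mre
      },
      "cd-diff" = {
        pa <- require_path(cfg$spectrum_a, "component A spectrum ('spectrum_a')")
        pb <- require_path(cfg$spectrum_b, "component B spectrum ('spectrum_b')")
        pm <- require_path(cfg$spectrum_mix, "mixture spectrum ('spectrum_mix')")
        inputs <<- c(pa, pb, pm)
        meta_a <- sample_meta(cfg$pathlength_cm, cfg$molarity_M, cfg$n_peptide_bonds)
        nb_b <- if (!is.null(cfg$n_peptide_bonds_b)) cfg$n_peptide_bonds_b else cfg$n_peptide_bonds
        mol_b <- if (!is.null(cfg$molarity_M_b)) cfg$molarity_M_b else cfg$molarity_M
        meta_b <- sample_meta(cfg$pathlength_cm, mol_b, nb_b)
        mre_a <- to_mre(read_cd_spectrum(pa), meta_a)
        mre_b <- to_mre(read_cd_spectrum(pb), meta_b)
        mre_mix <- to_mre_mixture(read_cd_spectrum(pm), mixture_meta(meta_a, meta_b),
                                  convention = cfg$convention)
        expected <- expected_noninteracting(mre_a, mre_b, mode = cfg$expectation_mode,
                                            meta_a = meta_a, meta_b = meta_b)
        diff <- difference_spectrum(expected, mre_mix)
        f_out <- file.path(cfg$out_dir, "difference_spectrum.csv")
        write_cd_csv(diff, f_out)
        outputs <<- f_out
        diff
      },
      "deconvolve" = {
        path <- require_path(cfg$spectrum, "input spectrum ('spectrum')")
        inputs <<- path
        spec <- read_cd_spectrum(path, unit = "MRE")
        basis <- if (!is.null(cfg$basis)) {
          bpath <- require_path(cfg$basis, "basis CSV ('basis')")
          inputs <<- c(inputs, bpath)
          read_basis_csv(bpath)
        } else default_basis()
        res <- deconvolve(spec, basis, ridge_lambda = cfg$ridge_lambda,
                          fit_range = cfg$fit_range)
        f_out <- file.path(cfg$out_dir, "fractions.csv")
        utils::write.csv(
          data.frame(class = names(res$fractions), fraction = as.numeric(res$fractions),
                     nrmsd = res$nrmsd, ridge_lambda = res$ridge_lambda),
          f_out, row.names = FALSE
        )
        outputs <<- f_out
        res
      },
      "classify" = {
        path <- require_path(cfg$spectrum, "input spectrum ('spectrum')")
        rpath <- require_path(cfg$reference, "reference points CSV ('reference')")
        inputs <<- c(path, rpath)
        spec <- read_cd_spectrum(path, unit = "MRE")
        pt <- two_wavelength(spec)
        cls <- classify_conformation(pt, read_reference_points_csv(rpath))
        f_out <- file.path(cfg$out_dir, "classification.csv")
        utils::write.csv(
          data.frame(theta_200 = pt$theta_200, theta_222 = pt$theta_222,
                     label = cls$label, tie = cls$tie,
                     t(as.matrix(cls$distances))),
          f_out, row.names = FALSE
        )
        outputs <<- f_out
        cls
      },
      "mst-fit" = {
        path <- require_path(cfg$binding, "binding CSV ('binding')")
        inputs <<- path
        curve <- read_binding_csv(path, target_conc_M = cfg$ct_M)
        fit <- fit_kd(curve)
        if (!isTRUE(fit$saturation_ok)) {
          warnings <<- c(warnings, sprintf("non-saturating titration: %s", fit$saturation$reason))
        }
        f_out <- file.path(cfg$out_dir, "kd_fit.csv")
        write_kd_csv(fit, f_out)
        outputs <<- f_out
        fit
      }
    )
  }

  result <- tryCatch(
    run_stage(),
    idrflex_validation_error = function(e) {
      status <<- 1L; error_msg <<- conditionMessage(e); NULL
    },
    error = function(e) {
      status <<- 2L; error_msg <<- conditionMessage(e); NULL
    }
  )
  if (!is.null(error_msg)) {
    log_msg("error", "%s", error_msg, threshold = cfg$log_level)
  }
  for (w in warnings) log_msg("warning", "%s", w, threshold = cfg$log_level)

  manifest <- list(
    subcommand = subcommand,
    package_version = as.character(utils::packageVersion("idrflex")),
    config = cfg,
    inputs = file_checksums(inputs),
    outputs = file_checksums(outputs),
    warnings = warnings,
    status = status,
    error = if (is.null(error_msg)) NULL else error_msg
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(list(status = status, outputs = outputs, manifest = manifest_path,
                 result = result, error = error_msg))
}
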