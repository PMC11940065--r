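# Evaluate expr under an explicit seed, leaving the caller's RNG state intact.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Synthetic-data configurations
#'
#' Plain validated parameter bundles for the seeded generators. Defaults
#' emulate the study design the analysis stages expect: a ~112-residue
#' disorder-biased construct measured at 10 uM in a 1 mm cuvette on a
#' 190-250 nm 1 nm grid, and a 16-step 2-fold titration from 40 uM read in
#' duplicate.
#'
#' @param length sequence length in residues.
#' @param disorder_bias probability mass shifted onto the disorder-promoting
#'   residue set, in \[0, 1\]; 0 is uniform over all twenty residues, 1 draws
#'   only disorder-promoting residues.
#' @param seed integer seed; every generator is a pure function of its
#'   config.
#' @return A config object of the corresponding class.
#' @export
synthetic_sequence_config <- function(length = 112L, disorder_bias = 0.8, seed = 1L) {
  if (length < 1 || length != round(length)) stop("length must be an integer >= 1")
  if (disorder_bias < 0 || disorder_bias > 1) stop("disorder_bias must be in [0, 1]")
  structure(list(length = as.integer(length), disorder_bias = disorder_bias,
                 seed = as.integer(seed)),
            class = "synthetic_sequence_config")
}

#' @rdname synthetic_sequence_config
#' @param fractions named fractions on the simplex (truth for recovery
#'   tests); names must match the basis classes.
#' @param meta [sample_meta()] used to convert the noiseless MRE model to
#'   instrument millidegrees.
#' @param noise_sd i.i.d. Gaussian noise SD in millidegrees.
#' @param grid wavelength grid, nm.
#' @export
synthetic_cd_config <- function(fractions = c(helix = 0.1, sheet = 0.1, turn = 0.2, disordered = 0.6),
                                meta = sample_meta(0.1, 10e-6, 111L),
                                noise_sd = 0.2,
                                grid = 190:250,
                                seed = 1L) {
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-6) {
    stop("fractions must be non-negative and sum to 1")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(inherits(meta, "sample_meta"))
  structure(list(fractions = fractions, meta = meta, noise_sd = noise_sd,
                 grid = as.numeric(grid), seed = as.integer(seed)),
            class = "synthetic_cd_config")
}

#' @rdname synthetic_sequence_config
#' @param config_a,config_b [synthetic_cd_config()] for the two components
#'   (equal grids and path lengths).
#' @param kd_M dissociation constant governing how much of component A is
#'   bound at the stated concentrations.
#' @param induced_delta named per-class fraction shift applied to the bound
#'   portion of component A; must sum to 0 and keep fractions >= 0.
#' @export
synthetic_mixture_config <- function(config_a = synthetic_cd_config(),
                                     config_b = synthetic_cd_config(
                                       fractions = c(helix = 0.25, sheet = 0.35, turn = 0.2, disordered = 0.2),
                                       meta = sample_meta(0.1, 10e-6, 227L)
                                     ),
                                     kd_M = 5e-6,
                                     induced_delta = c(helix = 0.2, sheet = 0, turn = 0, disordered = -0.2),
                                     seed = 1L) {
  stopifnot(inherits(config_a, "synthetic_cd_config"), inherits(config_b, "synthetic_cd_config"))
  if (abs(sum(induced_delta)) > 1e-9) stop("induced_delta must sum to 0")
  if (!setequal(names(induced_delta), names(config_a$fractions))) {
    stop("induced_delta classes must match component A fractions")
  }
  if (kd_M <= 0) stop("kd_M must be > 0")
  shifted <- config_a$fractions + induced_delta[names(config_a$fractions)]
  if (any(shifted < -1e-9)) stop("induced_delta drives a fraction below 0")
  if (abs(config_a$meta$pathlength_cm - config_b$meta$pathlength_cm) > 1e-12) {
    stop("components must share the cuvette path length")
  }
  structure(list(config_a = config_a, config_b = config_b, kd_M = kd_M,
                 induced_delta = induced_delta, seed = as.integer(seed)),
            class = "synthetic_mixture_config")
}

#' @rdname synthetic_sequence_config
#' @param kd_M,ct_M truth dissociation constant and labelled-target
#'   concentration, mol/L.
#' @param ladder a [dilution_ladder()].
#' @param binding_noise_sd Gaussian noise SD in fraction-bound units.
#' @param n_replicates replicates per concentration.
#' @export
synthetic_binding_config <- function(kd_M = 5e-6, ct_M = 50e-9,
                                     ladder = dilution_ladder(40e-6, 2, 16),
                                     binding_noise_sd = 0.02,
                                     n_replicates = 2L,
                                     seed = 1L) {
  if (kd_M <= 0 || ct_M <= 0) stop("kd_M and ct_M must be > 0")
  if (binding_noise_sd < 0) stop("binding_noise_sd must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  stopifnot(inherits(ladder, "dilution_ladder"))
  structure(list(kd_M = kd_M, ct_M = ct_M, ladder = ladder,
                 noise_sd = binding_noise_sd, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "synthetic_binding_config")
}

#' Generate a disorder-biased protein sequence
#'
#' Residues are drawn i.i.d.; with bias `b`, probability mass `(1-b)` is
#' spread uniformly over all twenty residues and mass `b` uniformly over the
#' eight disorder-promoting residues ([RESIDUE_CLASSES]`$disorder`), so
#' `b = 1` yields a purely disorder-promoting composition. Deterministic for
#' a fixed seed.
#'
#' @param cfg a [synthetic_sequence_config()].
#' @param id sequence label.
#' @return A [protein_sequence()].
#' @export
generate_sequence <- function(cfg, id = sprintf("synth_seq%d", cfg$seed)) {
  stopifnot(inherits(cfg, "synthetic_sequence_config"))
  p <- rep((1 - cfg$disorder_bias) / 20, 20)
  names(p) <- AMINO_ACIDS
  p[RESIDUE_CLASSES$disorder] <- p[RESIDUE_CLASSES$disorder] + cfg$disorder_bias / 8
  chars <- with_seed(cfg$seed, sample(AMINO_ACIDS, cfg$length, replace = TRUE, prob = p))
  protein_sequence(paste(chars, collapse = ""), id = id)
}

#' Simulate a far-UV CD acquisition
#'
#' Forward model of a CD measurement: the noiseless MRE spectrum is the
#' basis combination `sum_c f_c * basis_c` at the configured fractions,
#' converted to instrument millidegrees by inverting the MRE normalization
#' with the configured sample metadata, plus i.i.d. Gaussian noise in
#' millidegrees.
#'
#' @param cfg a [synthetic_cd_config()]; `cfg$fractions` names must match
#'   the basis classes.
#' @param basis a [basis_set()] (defaults to [default_basis()] on the config
#'   grid).
#' @param id spectrum label.
#' @return A [cd_spectrum()] in millidegrees with `cfg$meta` attached.
#' @export
simulate_cd <- function(cfg, basis = default_basis(cfg$grid), id = sprintf("synth_cd%d", cfg$seed)) {
  stopifnot(inherits(cfg, "synthetic_cd_config"), inherits(basis, "basis_set"))
  if (!setequal(names(cfg$fractions), basis$classes)) {
    stop("config fraction classes must match basis classes")
  }
  if (length(cfg$grid) != length(basis$wavelengths) ||
      any(abs(cfg$grid - basis$wavelengths) > 1e-9)) {
    stop("config grid must equal the basis grid")
  }
  mre <- as.numeric(basis$matrix %*% cfg$fractions[basis$classes])
  denom <- 10 * cfg$meta$pathlength_cm * cfg$meta$molarity_M * cfg$meta$n_peptide_bonds
  mdeg <- mre * denom
  noise <- with_seed(cfg$seed, stats::rnorm(length(mdeg), 0, cfg$noise_sd))
  if (cfg$noise_sd == 0) noise <- numeric(length(mdeg))
  cd_spectrum(cfg$grid, mdeg + noise, unit = "millidegrees", meta = cfg$meta, id = id)
}

#' Simulate a 1:1 mixture experiment
#'
#' Generates the three acquisitions of a difference-spectrum experiment:
#' component A alone, component B alone, and their 1:1 mixture, all in
#' millidegrees. The mixture signal is strictly additive
#' (`signal_A' + signal_B`) except that the bound portion of component A —
#' the fraction bound of A at the configured concentrations and K_D under
#' [binding_model()] — has its secondary-structure fractions shifted by
#' `induced_delta`, modelling partner-induced structure in a mixture that
#' contains both bound and free A. With `induced_delta = 0` additivity is
#' exact and the difference spectrum is zero up to noise.
#'
#' @param cfg a [synthetic_mixture_config()].
#' @param basis a [basis_set()] on the component grid.
#' @return A list `(a, b, mixture)` of [cd_spectrum()] in millidegrees;
#'   attribute `bound_fraction` records the bound fraction applied to A.
#' @export
simulate_mixture <- function(cfg, basis = default_basis(cfg$config_a$grid)) {
  stopifnot(inherits(cfg, "synthetic_mixture_config"))
  ca <- cfg$config_a; cb <- cfg$config_b
  # bound fraction of A with B as the titrated partner at its total conc
  fb <- binding_model(cb$meta$molarity_M, cfg$kd_M, ca$meta$molarity_M)
  delta <- cfg$induced_delta[names(ca$fractions)]
  frac_a_mix <- ca$fractions + fb * delta
  # all three acquisitions draw from streams derived from the mixture seed
  seeds <- cfg$seed + c(0L, 1L, 2L)
  ca2 <- ca; ca2$seed <- seeds[1]
  spec_a <- simulate_cd(ca2, basis, id = "component_a")
  cb2 <- cb; cb2$seed <- seeds[2]
  spec_b <- simulate_cd(cb2, basis, id = "component_b")
  # mixture: noiseless additive signal with A's bound portion restructured
  mre_a_mix <- as.numeric(basis$matrix %*% frac_a_mix[basis$classes])
  mre_b <- as.numeric(basis$matrix %*% cb$fractions[basis$classes])
  denom_a <- 10 * ca$meta$pathlength_cm * ca$meta$molarity_M * ca$meta$n_peptide_bonds
  denom_b <- 10 * cb$meta$pathlength_cm * cb$meta$molarity_M * cb$meta$n_peptide_bonds
  mdeg_mix <- mre_a_mix * denom_a + mre_b * denom_b
  noise_sd <- max(ca$noise_sd, cb$noise_sd)
  noise <- with_seed(seeds[3], stats::rnorm(length(mdeg_mix), 0, noise_sd))
  if (noise_sd == 0) noise <- numeric(length(mdeg_mix))
  mixture <- cd_spectrum(ca$grid, mdeg_mix + noise, unit = "millidegrees",
                         meta = mixture_meta(ca$meta, cb$meta), id = "mixture_1to1")
  out <- list(a = spec_a, b = spec_b, mixture = mixture)
  attr(out, "bound_fraction") <- fb
  out
}

#' Simulate a microscale-thermophoresis binding curve
#'
#' Fraction bound at every ladder concentration via [binding_model()], plus
#' i.i.d. Gaussian noise per replicate; per-point replicate mean and SD are
#' returned, as in a duplicate MST run.
#'
#' @param cfg a [synthetic_binding_config()].
#' @return A [binding_curve()] (fraction bound, descending concentrations);
#'   attribute `truth` carries the generating parameters.
#' @export
simulate_binding <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_binding_config"))
  conc <- cfg$ladder$concentrations_M
  fb_true <- binding_model(conc, cfg$kd_M, cfg$ct_M)
  reps <- with_seed(cfg$seed, matrix(
    stats::rnorm(length(conc) * cfg$n_replicates, mean = fb_true, sd = cfg$noise_sd),
    nrow = length(conc)
  ))
  if (cfg$noise_sd == 0) reps <- matrix(fb_true, nrow = length(conc), ncol = cfg$n_replicates)
  mean_fb <- rowMeans(reps)
  sd_fb <- if (cfg$n_replicates > 1) apply(reps, 1, stats::sd) else NULL
  curve <- binding_curve(conc, pmin(pmax(mean_fb, -0.2), 1.2), cfg$ct_M,
                         replicate_sd = sd_fb, n_replicates = cfg$n_replicates,
                         response_is_fraction_bound = TRUE)
  attr(curve, "truth") <- list(kd_M = cfg$kd_M, ct_M = cfg$ct_M, noise_sd = cfg$noise_sd)
  curve
}
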