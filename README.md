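# idrflex

Analysis tools for studying the conformational flexibility of intrinsically
disordered protein regions (IDRs) — how flexibility is encoded in sequence,
how point mutations shift it, and how partner binding induces structure.
The package targets the biophysics workflow built around three assays:

1. **Disorder-to-order substitution scanning.** A per-residue disorder
   score (composition-based: windowed hydropathy and net-charge magnitude
   squashed to \[0, 1\], with scores ≥ 0.5 called disordered) is recomputed
   for every possible single-residue variant — each of the *L* positions
   replaced by each of the other 19 residues — and variants are ranked by
   the drop in mean disorder they confer. Alignment-column conservation
   (1 − H/ln 20, with H the Shannon entropy of the column) flags whether
   candidate sites are evolutionarily constrained.

2. **Far-UV circular dichroism (CD) processing.** Instrument signal in
   millidegrees is blanked and normalized to mean residue ellipticity,
   MRE = m° / (10 · *l* · *M* · *n*) (pathlength *l* in cm, molarity *M*,
   *n* = residues − 1), with the molar-extinction scale ME = MRE / 3298.
   For 1:1 protein mixtures, the package computes the spectrum expected if
   the partners did not interact and subtracts the measured mixture from it;
   deviations of this *difference spectrum* from zero reveal partner-induced
   secondary structure. Secondary-structure fractions are estimated by a
   CONTIN-style constrained estimator: minimize ‖y − B·f‖² + λ‖f‖² over the
   probability simplex (f ≥ 0, Σf = 1) against a reference basis B, solved
   exactly by support enumeration. The θ₂₂₂-vs-θ₂₀₀ two-wavelength plot
   distinguishes random-coil from pre-molten-globule conformations by
   nearest-centroid assignment against labelled reference proteins.

3. **Microscale thermophoresis (MST) affinity estimation.** Fraction bound
   across a serial dilution ladder is fitted with the depletion-aware 1:1
   mass-action model
   fb = ((c + cₜ + K_D) − √((c + cₜ + K_D)² − 4·c·cₜ)) / (2·cₜ),
   by multi-start Levenberg–Marquardt least squares, with standard errors
   from the Jacobian and explicit saturation diagnostics that refuse to
   report a K_D from a titration that never approached saturation.

Because raw spectra and titrations from such studies are rarely deposited,
a seeded synthetic-data module generates sequences, CD spectra, mixtures,
and binding curves with known ground truth, so the whole pipeline is
testable end to end without downloads.

## Worked example

```r
library(idrflex)

# a disorder-biased 60-residue synthetic construct
seq <- generate_sequence(synthetic_sequence_config(length = 60, seed = 42))
scan <- scan_substitutions(seq)
print(scan, n = 3)
#> <scan_result> synth_seq42: 1140 substitutions over 60 positions (sequence delta)
#>   position wild substitute delta_mean_disorder rank
#> 1        9    R          I          0.05654675    1
#> 2        9    R          V          0.05513742    2
#> 3        9    R          L          0.05323448    3
```

The top-ranked variants replace a charged, disorder-promoting arginine with
aliphatic, order-promoting residues — the largest predicted
disorder-to-order effects, worth ~0.057 mean-disorder units each.

```r
# simulate a CD acquisition of a disorder-dominated protein and deconvolve it
basis <- default_basis()
mre <- to_mre(simulate_cd(synthetic_cd_config(seed = 42), basis))
deconvolve(mre, basis)
#> <deconvolution_result>
#>   helix       11.6%
#>   sheet        6.7%
#>   turn        22.4%
#>   disordered  59.3%
#>   nrmsd 0.01975 (lambda = 0, 51 points)
```

The recovered fractions sit close to the generating truth
(helix 0.10, sheet 0.10, turn 0.20, disordered 0.60); the NRMSD of 0.020
quantifies the residual misfit caused by measurement noise.

```r
# fit a simulated duplicate MST titration (truth: K_D = 5 uM)
fit_kd(simulate_binding(synthetic_binding_config(seed = 42)))
#> <kd_fit> K_D = 5.058e-06 +/- 8.7e-08 M (17 points, saturation ok)
```

A file-level driver `run_pipeline()` (subcommands `simulate`, `scan`,
`cd-normalize`, `cd-diff`, `deconvolve`, `classify`, `mst-fit`) runs the
same stages over FASTA/spectral-text/CSV inputs with a YAML config and
writes a JSON run manifest; `inst/exec/idrflex` is a thin shell wrapper
around it.

## Documentation

The methods vignette (`vignettes/idrflex-methods.Rmd`) describes the
models, the default parameters and why they were chosen, what the
synthetic generators do and do not emulate, and known limitations.
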