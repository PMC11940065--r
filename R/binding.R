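#' Serial dilution ladder
#'
#' A geometric ladder of `n_steps` successive `fold`-fold dilutions from a
#' top concentration, giving `n_steps + 1` concentrations
#' `top / fold^0 ... top / fold^n_steps`. The standard microscale-
#' thermophoresis design is 16 two-fold dilution steps from 40 uM, whose
#' lowest concentration is 40e-6 / 2^16 = 6.1035e-10 mol/L (~610 pM).
#'
#' @param top_conc_M top concentration, mol/L, > 0.
#' @param fold dilution factor, > 1.
#' @param n_steps number of dilution steps, integer >= 0.
#' @return An object of class `dilution_ladder` with `concentrations_M`
#'   (descending) and the inputs.
#' @examples
#' dilution_ladder(40e-6, 2, 16)$concentrations_M[17] # ~6.1e-10
#' @export
dilution_ladder <- function(top_conc_M, fold, n_steps) {
  if (top_conc_M <= 0) stop("top_conc_M must be > 0")
  if (fold <= 1) stop("fold must be > 1")
  if (n_steps < 0 || n_steps != round(n_steps)) stop("n_steps must be an integer >= 0")
  conc <- top_conc_M / fold^(0:n_steps)
  structure(
    list(top_conc_M = top_conc_M, fold = fold, n_steps = as.integer(n_steps),
         concentrations_M = conc),
    class = "dilution_ladder"
  )
}

#' @export
print.dilution_ladder <- function(x, ...) {
  cat(sprintf("<dilution_ladder> %d-step %g-fold from %.4g M (lowest %.4g M)\n",
              x$n_steps, x$fold, x$top_conc_M, min(x$concentrations_M)))
  invisible(x)
}

#' 1:1 mass-action fraction bound with target depletion
#'
#' The exact quadratic solution of single-site binding between a titrated
#' ligand at total concentration `c` and a labelled target at total
#' concentration `ct`:
#' `fb = ((c + ct + kd) - sqrt((c + ct + kd)^2 - 4 c ct)) / (2 ct)`.
#' As `ct -> 0` this reduces to the hyperbolic `c / (c + kd)`; at high `c`
#' it saturates at 1. Vectorized over `c`.
#'
#' @param c ligand concentration(s), mol/L, >= 0.
#' @param kd dissociation constant, mol/L, >= 0.
#' @param ct labelled target concentration, mol/L, > 0.
#' @return Fraction bound in \[0, 1\].
#' @export
binding_model <- function(c, kd, ct) {
  if (any(c < 0) || kd < 0) stop("concentrations and kd must be >= 0")
  if (ct <= 0) stop("target concentration ct must be > 0")
  s <- c + ct + kd
  disc <- pmax(s^2 - 4 * c * ct, 0)
  fb <- (s - sqrt(disc)) / (2 * ct)
  pmin(pmax(fb, 0), 1)
}

#' Construct a binding curve
#'
#' @param ligand_conc_M ligand concentrations, mol/L, positive and strictly
#'   ordered.
#' @param response per-point response; fraction bound when
#'   `response_is_fraction_bound = TRUE` (then loosely bounded to
#'   \[-0.2, 1.2\] to tolerate noise), otherwise raw normalized fluorescence.
#' @param target_conc_M labelled-species concentration `ct`, mol/L.
#' @param replicate_sd optional per-point standard deviation.
#' @param n_replicates replicate count behind each point.
#' @param response_is_fraction_bound flag; raw curves must be normalized by
#'   [fraction_bound_from_raw()] (or fitted directly with
#'   `fit_kd(..., raw = TRUE)`).
#' @return An object of class `binding_curve`.
#' @export
binding_curve <- function(ligand_conc_M, response, target_conc_M,
                          replicate_sd = NULL, n_replicates = 1L,
                          response_is_fraction_bound = TRUE) {
  ligand_conc_M <- as.numeric(ligand_conc_M)
  response <- as.numeric(response)
  if (length(ligand_conc_M) != length(response)) stop("concentration/response length mismatch")
  if (any(ligand_conc_M <= 0)) stop("ligand concentrations must be positive")
  d <- diff(ligand_conc_M)
  if (length(d) > 0 && !(all(d > 0) || all(d < 0))) {
    stop("ligand concentrations must be strictly ordered")
  }
  if (target_conc_M <= 0) stop("target_conc_M must be > 0")
  if (response_is_fraction_bound && any(response < -0.2 | response > 1.2)) {
    stop("fraction-bound responses outside [-0.2, 1.2]; is this a raw trace?")
  }
  if (!is.null(replicate_sd)) {
    replicate_sd <- as.numeric(replicate_sd)
    if (length(replicate_sd) != length(response) || any(replicate_sd < 0)) {
      stop("replicate_sd must be one non-negative value per point")
    }
  }
  structure(
    list(ligand_conc_M = ligand_conc_M, response = response,
         target_conc_M = target_conc_M, replicate_sd = replicate_sd,
         n_replicates = as.integer(n_replicates),
         response_is_fraction_bound = isTRUE(response_is_fraction_bound)),
    class = "binding_curve"
  )
}

#' @export
print.binding_curve <- function(x, ...) {
  cat(sprintf("<binding_curve> %d points, ligand %.3g-%.3g M, ct %.3g M (%s)\n",
              length(x$ligand_conc_M), min(x$ligand_conc_M), max(x$ligand_conc_M),
              x$target_conc_M,
              if (x$response_is_fraction_bound) "fraction bound" else "raw response"))
  invisible(x)
}

kd_model_residuals <- function(par, curve, raw) {
  kd <- exp(par[["log_kd"]])
  fb <- binding_model(curve$ligand_conc_M, kd, curve$target_conc_M)
  pred <- if (raw) par[["baseline"]] + (par[["plateau"]] - par[["baseline"]]) * fb else fb
  r <- curve$response - pred
  sdv <- curve$replicate_sd
  if (!is.null(sdv) && any(sdv > 0)) {
    # zero-SD points (e.g. identical replicates) get the median positive SD
    w <- 1 / ifelse(sdv > 0, sdv, stats::median(sdv[sdv > 0]))
    r <- r * w
  }
  r
}

#' Fit a dissociation constant to a binding curve
#'
#' Weighted nonlinear least squares of the depletion-aware 1:1 mass-action
#' model ([binding_model()]) to a fraction-bound curve, or jointly with an
#' affine baseline/plateau when the curve carries raw responses. Weights are
#' `1/sd^2` when per-point replicate SDs are available. The fit is
#' multi-started from `n_starts` log-spaced K_D initial values spanning
#' `start_range` (default 1e-9 to 1e-3 mol/L, 13 starts) and the solution
#' with the smallest final sum of squares is kept; the standard error comes
#' from the Jacobian at the optimum. A fitted K_D at the edge of the start
#' range is flagged unreliable, and [saturation_check()] populates the
#' saturation verdict.
#'
#' @param curve a [binding_curve()] with >= 5 points.
#' @param raw fit baseline/plateau jointly (for raw responses); defaults to
#'   the curve's own flag.
#' @param start_range,n_starts multi-start grid for K_D, mol/L.
#' @return An object of class `kd_fit`: `kd_M`, `kd_se_M`, `baseline`,
#'   `plateau` (raw fits), `saturation_ok`, `saturation` diagnostics,
#'   `n_points`, `converged`, `at_bound`, `rss`.
#' @export
fit_kd <- function(curve, raw = !curve$response_is_fraction_bound,
                   start_range = c(1e-9, 1e-3), n_starts = 13L) {
  stopifnot(inherits(curve, "binding_curve"))
  if (length(curve$ligand_conc_M) < 5L) stop("need at least 5 points to fit a K_D")
  starts <- exp(seq(log(start_range[1]), log(start_range[2]), length.out = n_starts))
  best <- NULL
  for (kd0 in starts) {
    par0 <- c(log_kd = log(kd0))
    if (raw) par0 <- c(par0, baseline = min(curve$response), plateau = max(curve$response))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = kd_model_residuals, curve = curve, raw = raw,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("K_D fit failed to converge from every start")
  fit <- best$fit
  par <- fit$par
  kd <- exp(par[["log_kd"]])
  # delta method: se(kd) = kd * se(log_kd), from the Jacobian at the optimum
  np <- length(par)
  dof <- length(fit$fvec) - np
  cov_ok <- dof > 0 && !is.null(fit$hessian) && all(is.finite(fit$hessian))
  se_logkd <- NA_real_
  if (cov_ok) {
    sigma2 <- best$rss / dof
    covm <- tryCatch(sigma2 * solve(fit$hessian / 2), error = function(e) NULL)
    if (!is.null(covm) && covm[1, 1] >= 0) se_logkd <- sqrt(covm[1, 1])
  }
  kd_se <- if (is.finite(se_logkd)) kd * se_logkd else NA_real_
  at_bound <- kd <= start_range[1] * 1.0001 || kd >= start_range[2] * 0.9999
  result <- structure(
    list(
      kd_M = kd, kd_se_M = kd_se,
      baseline = if (raw) par[["baseline"]] else 0,
      plateau = if (raw) par[["plateau"]] else 1,
      saturation_ok = NA, saturation = NULL,
      n_points = length(curve$ligand_conc_M),
      converged = fit$info %in% 1:4,
      at_bound = at_bound,
      rss = best$rss
    ),
    class = "kd_fit"
  )
  sat <- saturation_check(result, curve)
  result$saturation_ok <- sat$ok
  result$saturation <- sat
  result
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("<kd_fit> K_D = %.4g +/- %.2g M (%d points, saturation %s%s)\n",
              x$kd_M, x$kd_se_M, x$n_points,
              if (isTRUE(x$saturation_ok)) "ok" else "NOT reached",
              if (x$at_bound) ", AT SEARCH BOUND" else ""))
  invisible(x)
}

#' Saturation diagnostics for a K_D fit
#'
#' Guards against overestimating fraction bound when the titration does not
#' reach saturation. The verdict is `TRUE` iff the top ligand concentration
#' is at least `conc_margin` times the fitted K_D *and* the fitted fraction
#' bound at the top concentration reaches `fb_threshold`. Both margins are
#' always reported, with a reason string when the check fails.
#'
#' @param fit a `kd_fit`.
#' @param curve the fitted [binding_curve()].
#' @param conc_margin required `top_conc / kd` ratio (default 5).
#' @param fb_threshold required fitted fraction bound at the top (default
#'   0.8).
#' @return A list with `ok`, `conc_ratio`, `fb_top`, `reason`.
#' @export
saturation_check <- function(fit, curve, conc_margin = 5, fb_threshold = 0.8) {
  stopifnot(inherits(fit, "kd_fit"), inherits(curve, "binding_curve"))
  top <- max(curve$ligand_conc_M)
  conc_ratio <- top / fit$kd_M
  fb_top <- binding_model(top, fit$kd_M, curve$target_conc_M)
  ok <- conc_ratio >= conc_margin && fb_top >= fb_threshold
  reason <- if (ok) {
    "saturation reached"
  } else if (conc_ratio < conc_margin && fb_top < fb_threshold) {
    sprintf("top concentration only %.2g x K_D and fitted fb(top) = %.2f", conc_ratio, fb_top)
  } else if (conc_ratio < conc_margin) {
    sprintf("top concentration only %.2g x K_D (needs >= %g)", conc_ratio, conc_margin)
  } else {
    sprintf("fitted fb(top) = %.2f below %.2f", fb_top, fb_threshold)
  }
  list(ok = ok, conc_ratio = conc_ratio, fb_top = fb_top, reason = reason)
}

#' Normalize a raw response curve to fraction bound
#'
#' The unbound baseline and bound plateau are estimated jointly with the
#' K_D in the full model fit (not taken from the noisy extremes), and the
#' responses are then rescaled as
#' `(response - baseline) / (plateau - baseline)`. A curve whose fitted
#' plateau is indistinguishable from its baseline carries no binding signal
#' and is refused.
#'
#' @param curve a [binding_curve()] with raw responses, >= 5 points spanning
#'   >= 2 decades of concentration.
#' @param min_signal smallest |plateau - baseline| treated as signal.
#' @return A [binding_curve()] in fraction-bound units; the underlying
#'   `kd_fit` is attached as attribute `fit`.
#' @export
fraction_bound_from_raw <- function(curve, min_signal = 1e-6) {
  stopifnot(inherits(curve, "binding_curve"))
  if (length(curve$ligand_conc_M) < 5L) stop("need at least 5 points")
  span <- log10(max(curve$ligand_conc_M) / min(curve$ligand_conc_M))
  if (span < 2) stop("concentrations must span at least 2 decades")
  fit <- fit_kd(curve, raw = TRUE)
  amp <- fit$plateau - fit$baseline
  if (abs(amp) < min_signal) {
    stop(sprintf("no binding signal: fitted plateau - baseline = %.3g", amp))
  }
  fb <- (curve$response - fit$baseline) / amp
  sdscaled <- if (!is.null(curve$replicate_sd)) curve$replicate_sd / abs(amp) else NULL
  out <- binding_curve(curve$ligand_conc_M, pmin(pmax(fb, -0.2), 1.2),
                       curve$target_conc_M, replicate_sd = sdscaled,
                       n_replicates = curve$n_replicates,
                       response_is_fraction_bound = TRUE)
  attr(out, "fit") <- fit
  out
}

#' Read/write binding data as long-format CSV
#'
#' Columns `ligand_conc_M`, `response`, `replicate`. Replicates are averaged
#' per concentration; the per-point SD across replicates is retained.
#'
#' @param path CSV file.
#' @param target_conc_M labelled-species concentration, mol/L.
#' @param response_is_fraction_bound see [binding_curve()].
#' @return A [binding_curve()].
#' @export
read_binding_csv <- function(path, target_conc_M, response_is_fraction_bound = TRUE) {
  tab <- utils::read.csv(path)
  if (!all(c("ligand_conc_M", "response") %in% names(tab))) {
    stop("binding CSV needs columns ligand_conc_M, response (and optionally replicate)")
  }
  conc <- sort(unique(tab$ligand_conc_M), decreasing = TRUE)
  mean_r <- vapply(conc, function(cc) mean(tab$response[tab$ligand_conc_M == cc]), numeric(1))
  sd_r <- vapply(conc, function(cc) {
    x <- tab$response[tab$ligand_conc_M == cc]
    if (length(x) > 1) stats::sd(x) else 0
  }, numeric(1))
  nrep <- max(table(tab$ligand_conc_M))
  binding_curve(conc, mean_r, target_conc_M,
                replicate_sd = if (any(sd_r > 0)) sd_r else NULL,
                n_replicates = nrep,
                response_is_fraction_bound = response_is_fraction_bound)
}

#' @rdname read_binding_csv
#' @param curve a [binding_curve()].
#' @export
write_binding_csv <- function(curve, path) {
  stopifnot(inherits(curve, "binding_curve"))
  tab <- data.frame(
    ligand_conc_M = curve$ligand_conc_M,
    response = curve$response,
    replicate_sd = if (is.null(curve$replicate_sd)) NA_real_ else curve$replicate_sd
  )
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a K_D fit result as CSV
#'
#' One row: kd_M, kd_se_M, n_points, saturation_ok, at_bound, reason. A
#' non-saturating fit reports no K_D value (NA), only the diagnostics,
#' mirroring how unconverged titrations are tabulated.
#'
#' @param fit a `kd_fit`.
#' @param path output file.
#' @param suppress_kd_if_unsaturated blank the K_D when saturation failed.
#' @export
write_kd_csv <- function(fit, path, suppress_kd_if_unsaturated = TRUE) {
  stopifnot(inherits(fit, "kd_fit"))
  kd <- fit$kd_M; se <- fit$kd_se_M
  if (suppress_kd_if_unsaturated && !isTRUE(fit$saturation_ok)) {
    kd <- NA_real_; se <- NA_real_
  }
  utils::write.csv(
    data.frame(kd_M = kd, kd_se_M = se, n_points = fit$n_points,
               saturation_ok = fit$saturation_ok, at_bound = fit$at_bound,
               reason = fit$saturation$reason),
    path, row.names = FALSE
  )
  invisible(path)
}
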