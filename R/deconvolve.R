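#' Secondary-structure deconvolution by simplex-constrained ridge regression
#'
#' Estimates per-class secondary-structure fractions `f` from an MRE
#' spectrum `y` by minimizing
#' `|| y - B f ||^2 + lambda * || f ||^2` subject to `f >= 0` and
#' `sum(f) = 1`, where `B` is the basis matrix of reference spectra. This is
#' the constrained-regularized estimator family used by CONTIN-class CD
#' deconvolution programs. The solution is found exactly: the objective is
#' strictly convex on the simplex, so the optimum's support is one of the
#' `2^k - 1` non-empty class subsets; each subset's equality-constrained
#' solution is obtained from its KKT system, infeasible (negative) ones are
#' discarded, and the feasible candidate with the smallest objective is the
#' global optimum.
#'
#' The fit is restricted to `fit_range` (default 190-240 nm, the span over
#' which far-UV basis sets are informative); the spectrum is resampled onto
#' the basis grid within that range and must cover it.
#'
#' @param spectrum a [cd_spectrum()] in MRE whose span covers the fitted
#'   range of the basis grid.
#' @param basis a [basis_set()].
#' @param ridge_lambda ridge penalty `lambda >= 0`; 0 gives constrained
#'   least squares.
#' @param fit_range length-2 numeric, nm.
#' @return An object of class `deconvolution_result`: `fractions` (named,
#'   non-negative, summing to 1), `nrmsd`
#'   (`sqrt(sum((y - fit)^2) / sum(y^2))` over the fitted range),
#'   `ridge_lambda`, `fitted` ([cd_spectrum()] of the reconstruction), and
#'   `n_points`.
#' @examples
#' b <- default_basis()
#' y <- cd_spectrum(b$wavelengths, b$matrix %*% c(0.5, 0.2, 0.1, 0.2), unit = "MRE")
#' deconvolve(y, b)$fractions
#' @export
deconvolve <- function(spectrum, basis, ridge_lambda = 0, fit_range = c(190, 240)) {
  stopifnot(inherits(spectrum, "cd_spectrum"), inherits(basis, "basis_set"))
  check_unit(spectrum, "MRE")
  if (ridge_lambda < 0) stop("ridge_lambda must be >= 0")
  keep <- basis$wavelengths >= fit_range[1] & basis$wavelengths <= fit_range[2]
  if (sum(keep) < length(basis$classes)) stop("fit range covers too few basis points")
  wl <- basis$wavelengths[keep]
  if (min(wl) < min(spectrum$wavelengths) - 1e-9 ||
      max(wl) > max(spectrum$wavelengths) + 1e-9) {
    stop(sprintf("spectrum span %.6g-%.6g nm does not cover the fitted basis grid %.6g-%.6g nm",
                 min(spectrum$wavelengths), max(spectrum$wavelengths), min(wl), max(wl)))
  }
  y <- resample_spectrum(spectrum, wl)$values
  B <- basis$matrix[keep, , drop = FALSE]
  sol <- simplex_ridge_ls(y, B, ridge_lambda)
  fractions <- stats::setNames(sol$f, basis$classes)
  fitted_vals <- as.numeric(B %*% sol$f)
  denom <- sum(y^2)
  nrmsd <- if (denom > 0) sqrt(sum((y - fitted_vals)^2) / denom) else sqrt(sum((y - fitted_vals)^2))
  structure(
    list(
      fractions = fractions,
      nrmsd = nrmsd,
      ridge_lambda = ridge_lambda,
      fitted = cd_spectrum(wl, fitted_vals, unit = "MRE", id = paste0(spectrum$id, "_fit")),
      n_points = length(y)
    ),
    class = "deconvolution_result"
  )
}

# Exact minimizer of ||y - B f||^2 + lambda ||f||^2 on the probability simplex
# by enumeration of support subsets (k = ncol(B) is small).
simplex_ridge_ls <- function(y, B, lambda) {
  k <- ncol(B)
  # rescale signals to O(1) so the KKT system (which mixes B'B with the
  # sum-to-one constraint row) stays well conditioned; lambda scales with
  # the squared signal so the minimizer is unchanged
  s0 <- max(abs(B), abs(y), 1)
  B <- B / s0
  y <- y / s0
  lambda <- lambda / s0^2
  best <- NULL
  best_obj <- Inf
  for (mask in seq_len(2^k - 1L)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    Bs <- B[, S, drop = FALSE]
    m <- length(S)
    # KKT for min ||y - Bs f||^2 + lambda||f||^2 s.t. 1'f = 1
    A <- rbind(cbind(2 * (crossprod(Bs) + lambda * diag(m)), rep(1, m)),
               c(rep(1, m), 0))
    rhs <- c(2 * crossprod(Bs, y), 1)
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    f <- sol[seq_len(m)]
    if (any(f < -1e-9)) next
    f[f < 0] <- 0
    f <- f / sum(f)
    obj <- sum((y - Bs %*% f)^2) + lambda * sum(f^2)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      full <- numeric(k)
      full[S] <- f
      best <- full
    }
  }
  if (is.null(best)) stop("no feasible simplex solution found (degenerate basis?)")
  list(f = best, objective = best_obj)
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat("<deconvolution_result>\n")
  cat(paste(sprintf("  %-10s %5.1f%%", names(x$fractions), 100 * x$fractions), collapse = "\n"), "\n")
  cat(sprintf("  nrmsd %.4g (lambda = %g, %d points)\n", x$nrmsd, x$ridge_lambda, x$n_points))
  invisible(x)
}

#' Ellipticity at 200 and 222 nm
#'
#' Extracts the two coordinates of the double-wavelength plot used to
#' distinguish random-coil from pre-molten-globule conformations. Values are
#' linearly interpolated when the grid lacks exact 200/222 nm points.
#'
#' @param spectrum a [cd_spectrum()] in MRE spanning both wavelengths.
#' @param label optional cohort label to attach.
#' @return A list of class `two_wavelength_point` with `theta_200`,
#'   `theta_222`, `label`.
#' @export
two_wavelength <- function(spectrum, label = NA_character_) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  check_unit(spectrum, "MRE")
  span <- range(spectrum$wavelengths)
  if (span[1] > 200 || span[2] < 222) {
    stop(sprintf("spectrum span %.6g-%.6g nm does not cover 200 and 222 nm", span[1], span[2]))
  }
  v <- stats::approx(spectrum$wavelengths, spectrum$values, xout = c(200, 222))$y
  structure(list(theta_200 = v[1], theta_222 = v[2], label = label),
            class = "two_wavelength_point")
}

#' Classify a conformation on the double-wavelength plot
#'
#' Nearest-centroid assignment of a (theta_200, theta_222) point against
#' labelled reference cohorts (e.g. previously characterized random-coil and
#' pre-molten-globule proteins). Axes are standardized by the pooled
#' within-cohort standard deviation so the two wavelengths contribute
#' comparably. Per-cohort distances are returned so that partial membership
#' ("to varying degrees") is quantifiable; an exact tie is reported as such
#' rather than silently broken.
#'
#' @param point a [two_wavelength_point()] or list with `theta_200`,
#'   `theta_222`.
#' @param reference data.frame with columns `theta_200`, `theta_222`,
#'   `label`; >= 1 point per cohort and >= 2 cohorts.
#' @return A list of class `conformation_class`: `label` (NA on a tie),
#'   `tie`, `distances` (named, standardized distance to each cohort
#'   centroid).
#' @export
classify_conformation <- function(point, reference) {
  stopifnot(is.data.frame(reference),
            all(c("theta_200", "theta_222", "label") %in% names(reference)))
  labs <- unique(reference$label)
  if (length(labs) < 2L) stop("reference must contain at least two cohorts")
  counts <- table(reference$label)
  if (any(counts < 1L)) stop("every cohort needs at least one reference point")
  pooled_sd <- function(v) {
    devs <- unlist(lapply(labs, function(l) {
      x <- v[reference$label == l]
      x - mean(x)
    }))
    denom <- length(v) - length(labs)
    if (denom > 0) sqrt(sum(devs^2) / denom) else 0
  }
  s200 <- pooled_sd(reference$theta_200)
  s222 <- pooled_sd(reference$theta_222)
  if (s200 <= 0 && s222 <= 0 && nrow(reference) > length(labs)) {
    stop("degenerate reference: zero within-cohort variance on both axes")
  }
  # single-point cohorts carry no spread information: fall back to raw scale
  if (s200 <= 0) s200 <- 1
  if (s222 <= 0) s222 <- 1
  d <- vapply(labs, function(l) {
    cx <- mean(reference$theta_200[reference$label == l])
    cy <- mean(reference$theta_222[reference$label == l])
    sqrt(((point$theta_200 - cx) / s200)^2 + ((point$theta_222 - cy) / s222)^2)
  }, numeric(1))
  names(d) <- labs
  dmin <- min(d)
  winners <- names(d)[abs(d - dmin) < 1e-12]
  structure(
    list(
      label = if (length(winners) == 1L) winners else NA_character_,
      tie = length(winners) > 1L,
      distances = d
    ),
    class = "conformation_class"
  )
}

#' @export
print.conformation_class <- function(x, ...) {
  if (x$tie) {
    cat("<conformation_class> tie between cohorts\n")
  } else {
    cat(sprintf("<conformation_class> %s\n", x$label))
  }
  print(round(x$distances, 4))
  invisible(x)
}

#' Read/write classification reference points as CSV
#'
#' Columns `theta_200`, `theta_222`, `label`.
#' @param path CSV file.
#' @export
read_reference_points_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("theta_200", "theta_222", "label") %in% names(tab))) {
    stop("reference CSV needs columns theta_200, theta_222, label")
  }
  tab
}
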