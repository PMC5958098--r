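# Fast-exchange titration thermodynamics: chemical-shift perturbation
# fitting of dissociation constants, free-energy differences, and
# population bookkeeping from peak intensities.

.gas_constant_kcal <- 1.987e-3  # kcal mol-1 K-1

#' Fraction of protein sites occupied by ligand
#'
#' Exact 1:1 per-site binding: the bound-complex concentration is the
#' smaller root of \eqn{X^2 - X(L+P+K_D) + LP = 0}, evaluated in the
#' numerically stable form \eqn{X = 2LP / (b + \sqrt{b^2 - 4LP})} with
#' \eqn{b = L+P+K_D}.  As \eqn{P \to 0} this reduces smoothly to the
#' excess-ligand limit \eqn{L/(L+K_D)}.
#'
#' @param L_tot Total ligand concentration (M), vectorised.
#' @param P_tot Total protein *site* concentration (M); for a trimer with
#'   three independent identical sites this is 3x the trimer concentration.
#' @param K_D Dissociation constant (M).
#' @return Bound fraction in `[0, 1]`.
#' @examples
#' fraction_bound(6e-3, 0, 6e-3)  # half saturation
#' @export
fraction_bound <- function(L_tot, P_tot, K_D) {
  if (any(L_tot < 0) || P_tot < 0 || K_D <= 0) {
    stop("concentrations must be non-negative and K_D positive")
  }
  b <- L_tot + P_tot + K_D
  disc <- sqrt(pmax(b^2 - 4 * L_tot * P_tot, 0))
  2 * L_tot / (b + disc)
}

#' Build a titration series
#'
#' @param L_tot Total ligand concentrations (M), non-negative and strictly
#'   increasing.
#' @param delta_obs Observed chemical shifts (ppm).
#' @param P_tot Protein site concentration (M).
#' @param resonance_id Label of the followed resonance.
#' @return List of class `titration_series`.
#' @export
titration_series <- function(L_tot, delta_obs, P_tot,
                             resonance_id = "resonance") {
  stopifnot(length(L_tot) == length(delta_obs), all(L_tot >= 0), P_tot >= 0)
  if (any(diff(L_tot) <= 0)) stop("L_tot must be strictly increasing")
  structure(list(resonance_id = resonance_id, L_tot = L_tot,
                 delta_obs = delta_obs, P_tot = P_tot),
            class = "titration_series")
}

#' Fit a dissociation constant to a fast-exchange titration
#'
#' Under fast exchange the observed shift is the population-weighted
#' average \eqn{\delta_{obs} = \delta_{free} + (\delta_{bound} -
#' \delta_{free}) f_b(L)}.  For any trial K_D the two shift parameters
#' enter linearly, so the fit profiles the residual sum of squares over
#' log K_D (coarse grid + golden-section refinement) with the shifts
#' solved by linear least squares; this removes any sensitivity to
#' starting values.
#'
#' @param series A [titration_series()] with at least 4 points.
#' @param noise_floor Minimal shift range (ppm) considered identifiable.
#' @return List of class `binding_fit`: `K_D` (M), `delta_free`,
#'   `delta_bound` (ppm), `rss`, `se_KD` (M).
#' @export
fit_kd <- function(series, noise_floor = 1e-4) {
  stopifnot(inherits(series, "titration_series"))
  L <- series$L_tot
  y <- series$delta_obs
  P <- series$P_tot
  if (length(L) < 4) stop("need at least 4 titration points")
  if (diff(range(y)) < noise_floor) {
    stop("unidentifiable: shift range below the noise floor")
  }
  rss_at <- function(logk) {
    f <- fraction_bound(L, P, 10^logk)
    fit <- stats::lm.fit(cbind(1, f), y)
    sum(fit$residuals^2)
  }
  lmax <- log10(max(L[L > 0]))
  grid <- seq(lmax - 5, lmax + 2, length.out = 141)
  r <- vapply(grid, rss_at, numeric(1))
  g0 <- grid[which.min(r)]
  opt <- stats::optimize(rss_at, interval = c(g0 - 0.5, g0 + 0.5),
                         tol = 1e-10)
  kd <- 10^opt$minimum
  f <- fraction_bound(L, P, kd)
  lin <- stats::lm.fit(cbind(1, f), y)
  delta_free <- unname(lin$coefficients[1])
  delta_bound <- delta_free + unname(lin$coefficients[2])
  rss <- sum(lin$residuals^2)
  # standard error from the Jacobian of (delta_free, amplitude, K_D)
  h <- kd * 1e-4
  dfdk <- (fraction_bound(L, P, kd + h) - fraction_bound(L, P, kd - h)) / (2 * h)
  J <- cbind(1, f, unname(lin$coefficients[2]) * dfdk)
  dof <- length(L) - 3L
  se_kd <- NA_real_
  if (dof > 0) {
    jtj <- crossprod(J)
    cv <- tryCatch(solve(jtj) * rss / dof, error = function(e) NULL)
    if (!is.null(cv)) se_kd <- sqrt(pmax(cv[3, 3], 0))
  }
  structure(list(K_D = kd, delta_free = delta_free,
                 delta_bound = delta_bound, rss = rss, se_KD = se_kd,
                 resonance_id = series$resonance_id),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> %s: K_D = %.3g M (se %.2g), shifts %.4g -> %.4g ppm, rss %.3g\n",
              x$resonance_id, x$K_D, x$se_KD, x$delta_free, x$delta_bound,
              x$rss))
  invisible(x)
}

#' Free-energy difference between two dissociation constants
#'
#' \eqn{\Delta\Delta G = R T \ln(K_1/K_2)} with R = 1.987e-3 kcal/mol/K.
#' A ~2000-fold affinity ratio at 298.15 K corresponds to ~4.5 kcal/mol,
#' the cost one or two hydrogen bonds can compensate.
#'
#' @param K1,K2 Dissociation constants (M).
#' @param T_K Temperature (K).
#' @return Free-energy difference (kcal/mol); positive when K1 > K2
#'   (binding 2 stronger).
#' @examples
#' delta_delta_g(5.9e-3, 3e-6)  # ~4.5
#' @export
delta_delta_g <- function(K1, K2, T_K = 298.15) {
  if (any(c(K1, K2, T_K) <= 0)) stop("K1, K2 and T_K must be positive")
  .gas_constant_kcal * T_K * log(K1 / K2)
}

#' Species populations from peak intensities
#'
#' Normalises non-negative peak intensities (optionally per contributing
#' proton count) to fractions summing to one, e.g. anomer populations from
#' methyl-proton peak intensities.
#'
#' @param intensities Non-negative peak intensities.
#' @param protons Optional per-peak proton counts for normalisation.
#' @return Fractions summing to 1.
#' @examples
#' population_from_intensities(c(3, 7))  # 0.30 / 0.70
#' @export
population_from_intensities <- function(intensities, protons = NULL) {
  if (!length(intensities) || any(intensities < 0)) {
    stop("need non-negative intensities")
  }
  if (!is.null(protons)) {
    stopifnot(length(protons) == length(intensities), all(protons > 0))
    intensities <- intensities / protons
  }
  tot <- sum(intensities)
  if (tot <= 0) stop("all intensities are zero")
  intensities / tot
}

#' Saturation-transfer difference spectrum
#'
#' Subtracts the on-resonance (protein-saturated) spectrum from the
#' off-resonance reference; positive difference peaks mark ligand protons
#' in contact with the protein.  Populations of the flagged species are
#' estimated from the difference-peak heights.
#'
#' @param on_resonance,off_resonance Equal-length spectrum vectors on one
#'   axis.
#' @param threshold Minimal height for a difference peak, as a fraction of
#'   the maximal difference.
#' @return List with `difference`, `peaks` (index and height of positive
#'   local maxima) and `populations`.
#' @export
std_difference <- function(on_resonance, off_resonance, threshold = 0.05) {
  if (length(on_resonance) != length(off_resonance)) {
    stop("spectra must share one axis (equal length)")
  }
  d <- off_resonance - on_resonance
  n <- length(d)
  if (n < 3 || max(d) <= 0) {
    return(list(difference = d,
                peaks = data.frame(index = integer(), height = numeric()),
                populations = numeric(0)))
  }
  inner <- 2:(n - 1)
  is_peak <- d[inner] > d[inner - 1] & d[inner] >= d[inner + 1] &
    d[inner] > threshold * max(d)
  idx <- inner[is_peak]
  peaks <- data.frame(index = idx, height = d[idx])
  pops <- if (nrow(peaks)) population_from_intensities(peaks$height) else numeric(0)
  list(difference = d, peaks = peaks, populations = pops)
}
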