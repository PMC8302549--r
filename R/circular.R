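#' Circular feature spaces
#'
#' A circular space describes the report dimension of a continuous-report
#' task: its period (180 degrees for bar orientation, 360 degrees for a colour
#' wheel) and the minimum pairwise separation enforced between item features
#' within a trial (10 degrees for orientation, 20 degrees for colour).
#'
#' All user-facing angles are degrees on the raw feature scale. Analyses of
#' half-circle spaces internally double angles onto a full 360-degree circle
#' (see [to_analysis_scale()]) so the von Mises distribution applies in its
#' standard form.
#'
#' @param period circle period in degrees; must be positive.
#' @param min_separation minimum pairwise wrapped feature distance in degrees;
#'   must satisfy `0 < min_separation < period / 4` so that four items remain
#'   placeable.
#' @return An object of class `circ_space` with elements `period` and
#'   `min_separation`.
#' @examples
#' orientation_space()
#' circ_space(360, 20)
#' @export
circ_space <- function(period, min_separation) {
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) ||
      period <= 0)
    stop("'period' must be a single positive finite number", call. = FALSE)
  if (!is.numeric(min_separation) || length(min_separation) != 1L ||
      !is.finite(min_separation) || min_separation <= 0 ||
      min_separation >= period / 4)
    stop("'min_separation' must lie in (0, period/4)", call. = FALSE)
  structure(list(period = period, min_separation = min_separation),
            class = "circ_space")
}

#' @rdname circ_space
#' @export
orientation_space <- function() circ_space(180, 10)

#' @rdname circ_space
#' @export
colour_space <- function() circ_space(360, 20)

#' @export
print.circ_space <- function(x, ...) {
  cat(sprintf("Circular space: period %g deg, min separation %g deg\n",
              x$period, x$min_separation))
  invisible(x)
}

as_space <- function(space) {
  if (inherits(space, "circ_space")) return(space)
  stop("'space' must be a circ_space object", call. = FALSE)
}

#' Signed wrapped difference between angles
#'
#' Computes `a - b` reduced to the half-open symmetric interval
#' `(-period/2, period/2]`. A difference of exactly half the period maps to
#' `+period/2`, a deterministic tie-break that keeps histogram bins exact.
#'
#' @param a,b angles in degrees (vectors recycle as usual).
#' @param space a [circ_space()], or a single number taken as the period.
#' @return signed differences in degrees, in `(-period/2, period/2]`.
#' @examples
#' wrap_diff(10, 350, circ_space(360, 20))   # 20
#' wrap_diff(170, 10, orientation_space())   # -20
#' @export
wrap_diff <- function(a, b, space) {
  period <- if (is.numeric(space) && length(space) == 1L) space
            else as_space(space)$period
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("angles must be finite", call. = FALSE)
  d <- (a - b) %% period
  # map (period/2, period) to negative; exactly period/2 stays positive
  ifelse(d > period / 2, d - period, d)
}

#' von Mises density in degrees
#'
#' Density of the von Mises distribution with mean `mu` and concentration
#' `kappa`, evaluated at `x`, on a circle of the given period. The density is
#' per radian of the analysis circle, so it integrates to 1 over one full
#' period; `kappa = 0` gives the circular uniform density `1/(2*pi)`.
#' Exponentially scaled Bessel functions keep the computation finite for
#' large `kappa`.
#'
#' @param x angles in degrees.
#' @param mu mean direction in degrees.
#' @param kappa concentration parameter, `>= 0`.
#' @param period circle period in degrees (default 360, the analysis circle).
#' @return densities per radian.
#' @examples
#' vm_pdf(0, 0, 0)          # 1/(2*pi)
#' vm_pdf(90, 90, 5)        # modal density
#' @export
vm_pdf <- function(x, mu, kappa, period = 360) {
  if (!is.numeric(kappa) || any(!is.finite(kappa)) || any(kappa < 0))
    stop("'kappa' must be finite and >= 0", call. = FALSE)
  theta <- (x - mu) * 2 * pi / period
  # exp(kappa*(cos(theta)-1)) / (2*pi*I0(kappa)*exp(-kappa)): overflow-safe
  exp(kappa * (cos(theta) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

# ratio I1(kappa)/I0(kappa), the mean resultant length of a von Mises sample
bessel_ratio <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

#' Invert the Bessel ratio: concentration from mean resultant length
#'
#' Solves `I1(kappa)/I0(kappa) = R` for `kappa`, the maximum-likelihood
#' update for the von Mises concentration given a mean resultant length `R`.
#' The root is bracketed from the Best-Fisher approximation and polished by
#' [stats::uniroot()]. Values of `R` approaching 1 are capped at
#' `kappa_ceiling`, beyond which the inversion is numerically degenerate.
#'
#' @param R mean resultant length(s) in `[0, 1]`.
#' @param kappa_ceiling upper cap on the returned concentration (default 700).
#' @return concentration(s) `kappa >= 0`.
#' @examples
#' kappa_from_resultant(0)      # 0
#' kappa_from_resultant(0.9)    # about 5.3
#' @export
kappa_from_resultant <- function(R, kappa_ceiling = 700) {
  if (any(!is.finite(R)) || any(R < 0) || any(R > 1))
    stop("'R' must lie in [0, 1]", call. = FALSE)
  vapply(R, function(r) {
    if (r == 0) return(0)
    if (bessel_ratio(kappa_ceiling) <= r) return(kappa_ceiling)
    # Best-Fisher seed, then Newton (d/dk of the ratio is 1 - r^2 - r/k)
    k <- if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
         else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
         else 1 / (r^3 - 4 * r^2 + 3 * r)
    k <- min(max(k, 1e-8), kappa_ceiling)
    for (i in 1:50) {
      ratio <- bessel_ratio(k)
      if (abs(ratio - r) < 1e-12) return(min(k, kappa_ceiling))
      step <- (ratio - r) / (1 - ratio^2 - ratio / k)
      k_new <- k - step
      if (!is.finite(k_new) || k_new <= 0 || k_new > kappa_ceiling) break
      k <- k_new
      if (abs(step) < 1e-12 * max(k, 1)) break
    }
    if (is.finite(k) && k > 0 && abs(bessel_ratio(k) - r) < 1e-9)
      return(min(k, kappa_ceiling))
    stats::uniroot(function(kk) bessel_ratio(kk) - r,
                   c(1e-12, kappa_ceiling), tol = 1e-12)$root
  }, numeric(1))
}

#' Circular mean absolute deviation
#'
#' Mean of absolute wrapped deviations, the model-free error measure used
#' throughout the swap-error analyses. For responses unrelated to the
#' reference feature the expectation is `period/4` (45 degrees on the
#' orientation space, 90 on the colour wheel); see [chance_mad()].
#'
#' @param deviations signed wrapped deviations in degrees (as produced by
#'   [wrap_diff()]).
#' @param space a [circ_space()] used only to validate the range.
#' @return mean absolute deviation in degrees, in `[0, period/2]`.
#' @export
circ_mad <- function(deviations, space) {
  space <- as_space(space)
  if (length(deviations) == 0L)
    stop("empty deviation vector", call. = FALSE)
  if (any(!is.finite(deviations)))
    stop("deviations must be finite", call. = FALSE)
  if (any(abs(deviations) > space$period / 2 + 1e-9))
    stop("deviations must be wrapped to (-period/2, period/2]", call. = FALSE)
  mean(abs(deviations))
}

#' @rdname circ_mad
#' @export
chance_mad <- function(space) as_space(space)$period / 4
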