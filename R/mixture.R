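#' Rescale angles between the raw feature scale and the analysis circle
#'
#' Half-circle feature spaces (orientation, period 180) are doubled onto the
#' full 360-degree circle before the mixture model is applied, so the von
#' Mises distribution can be used in its standard formulation; full-circle
#' spaces are unchanged. Fitted concentrations therefore always refer to the
#' analysis circle.
#'
#' @param x angles in degrees.
#' @param space a [circ_space()].
#' @return rescaled angles in degrees.
#' @examples
#' to_analysis_scale(90, orientation_space())   # 180
#' to_analysis_scale(90, colour_space())        # 90
#' @export
to_analysis_scale <- function(x, space) x * 360 / as_space(space)$period

#' @rdname to_analysis_scale
#' @export
from_analysis_scale <- function(x, space) x * as_space(space)$period / 360

# deviations (radians, analysis circle) of each response from each von Mises
# component center: column 1 the target, columns 2..m+1 the non-targets
component_deviations <- function(trials) {
  space <- trial_space(trials)
  scale <- 2 * pi / space$period   # degrees (raw) -> radians on analysis circle
  centers <- cbind(target_features(trials), nontarget_features(trials))
  (trials$response - centers) * scale
}

# mixture density of each response under Eq.-style three-component model
mixture_density <- function(dev_rad, p_t, p_nt, p_u, kappa) {
  m <- ncol(dev_rad) - 1L
  fvm <- exp(kappa * (cos(dev_rad) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
  p_t * fvm[, 1] + (p_nt / m) * rowSums(fvm[, -1, drop = FALSE]) +
    p_u / (2 * pi)
}

#' Log-likelihood of the three-component mixture on a trial set
#'
#' Evaluates, on the analysis circle, the density of each response as a
#' mixture of a von Mises component at the target feature, von Mises
#' components (equal weight) at each non-target feature sharing the same
#' concentration, and a circular uniform component, and sums the logs.
#'
#' @param trials a `trial_set` slice (all trials sharing one feature space).
#' @param params a [mixture_params()].
#' @return log-likelihood in nats.
#' @export
mixture_loglik <- function(trials, params) {
  if (nrow(trials) == 0L) stop("empty trial set", call. = FALSE)
  dev <- component_deviations(trials)
  sum(log(mixture_density(dev, params$p_t, params$p_nt, params$p_u,
                          params$kappa)))
}

em_run <- function(cosdev, start, tol, max_iter, kappa_ceiling = 700) {
  n <- nrow(cosdev); m <- ncol(cosdev) - 1L
  p_t <- start$p_t; p_nt <- start$p_nt; p_u <- start$p_u; kappa <- start$kappa
  ll_old <- -Inf; converged <- FALSE; resp <- NULL
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    fvm <- exp(kappa * (cosdev - 1)) /
      (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
    lik <- cbind(p_t * fvm[, 1], (p_nt / m) * fvm[, -1, drop = FALSE],
                 p_u / (2 * pi))
    s <- rowSums(lik)
    ll <- sum(log(s))
    trace[it] <- ll
    resp <- lik / s
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    p_t <- mean(resp[, 1])
    p_nt <- sum(resp[, 2:(m + 1)]) / n
    p_u <- mean(resp[, m + 2])
    w <- resp[, 1:(m + 1), drop = FALSE]
    W <- sum(w)
    if (W > 0) {
      # component means are fixed at the item features, so the concentration
      # update inverts the weighted cosine moment of the centered deviations
      # (not the free-mean resultant length, which would overestimate kappa)
      R <- sum(w * cosdev) / W
      kappa <- if (R <= 0) 0 else kappa_from_resultant(min(R, 1), kappa_ceiling)
    }
  }
  list(p_t = p_t, p_nt = p_nt, p_u = p_u, kappa = kappa, loglik = ll,
       converged = converged, iterations = it, responsibilities = resp,
       trace = trace)
}

#' Fit the three-component swap mixture model by multistart EM
#'
#' Maximum-likelihood fit of the response distribution of a trial slice
#' (typically one participant in one condition, pooled over ordinal
#' positions) as a mixture of target-centered von Mises, non-target-centered
#' von Mises (one shared concentration, equal weight across non-targets) and
#' uniform-guessing components. Expectation-maximisation with closed-form
#' M-steps: proportions from component responsibilities, concentration by
#' Bessel-ratio inversion of the responsibility-weighted cosine moment of the
#' component-centered deviations (the component means are fixed at the item
#' features, so the mean direction is not re-estimated). The likelihood can
#' be multimodal when the
#' target and swap clusters overlap, so several starting points are used and
#' the best final likelihood wins (ties broken towards lower concentration).
#'
#' @param trials a `trial_set` slice; at least 2 trials (10 or more
#'   recommended — fewer triggers a warning).
#' @param n_starts number of EM starts: one moment-based start (concentration
#'   from the resultant of target deviations) plus up to `n_starts - 1` from
#'   a coarse lattice of proportions crossed with kappa in \{2, 8, 32\}.
#' @param tol EM stops when the log-likelihood improves by less than this
#'   (nats; default 1e-6).
#' @param max_iter iteration cap per start (default 1000).
#' @return an object of class `mixture_fit`: fitted [mixture_params()] in
#'   `params`, `log_likelihood`, `n_trials`, `n_starts_used`, `converged`,
#'   per-trial posterior `responsibilities` over \{target, each non-target,
#'   uniform\}, and the data's `space`.
#' @seealso [mixture_loglik()], [fit_by_condition()]
#' @examples
#' cfg <- generator_config(trials_per_condition = 40, block_size = 40,
#'                         conditions = data.frame(location = "same",
#'                                                 isi = "short"), seed = 7)
#' fit <- fit_mixture(generate_dataset(cfg))
#' coef(fit)
#' @export
fit_mixture <- function(trials, n_starts = 10, tol = 1e-6, max_iter = 1000) {
  if (nrow(trials) < 2L)
    stop("at least 2 trials are required to fit the mixture", call. = FALSE)
  if (nrow(trials) < 10L)
    warning("fewer than 10 trials; mixture estimates will be unstable")
  space <- trial_space(trials)
  dev <- component_deviations(trials)
  cosdev <- cos(dev)
  n <- nrow(dev); m <- ncol(dev) - 1L

  # exact-boundary degenerate case: every response equals its target
  if (all(abs(wrap_diff(trials$response, target_features(trials),
                        space$period)) < 1e-9)) {
    params <- mixture_params(1, 0, 0, 700)
    resp <- cbind(1, matrix(0, n, m + 1L))
    fit <- structure(list(params = params,
                          log_likelihood = mixture_loglik(trials, params),
                          n_trials = n, n_starts_used = 0L, converged = TRUE,
                          boundary = TRUE, responsibilities = resp,
                          space = space, call = match.call()),
                     class = "mixture_fit")
    return(fit)
  }

  # moment start: concentration from the resultant of target deviations
  R_t <- max(mean(cosdev[, 1]), 0.01)
  starts <- list(list(p_t = 0.6, p_nt = 0.3, p_u = 0.1,
                      kappa = kappa_from_resultant(min(R_t, 0.999))))
  lattice_p <- list(c(0.2, 0.6), c(0.5, 0.3), c(0.8, 0.1))
  for (pp in lattice_p)
    for (k in c(2, 8, 32))
      starts[[length(starts) + 1L]] <-
        list(p_t = pp[1], p_nt = pp[2], p_u = 1 - pp[1] - pp[2], kappa = k)
  starts <- starts[seq_len(min(n_starts, length(starts)))]

  best <- NULL
  for (s in starts) {
    run <- em_run(cosdev, s, tol, max_iter)
    if (is.null(best) || run$loglik > best$loglik + 1e-9 ||
        (abs(run$loglik - best$loglik) <= 1e-9 && run$kappa < best$kappa))
      best <- run
  }
  params <- mixture_params(max(best$p_t, 0), max(best$p_nt, 0),
                           max(best$p_u, 0), min(best$kappa, 700))
  structure(list(params = params, log_likelihood = best$loglik,
                 n_trials = n, n_starts_used = length(starts),
                 converged = best$converged, boundary = FALSE,
                 responsibilities = best$responsibilities,
                 em_trace = best$trace, space = space,
                 call = match.call()),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, digits = 3, ...) {
  cat("Three-component swap mixture model\n")
  cat(sprintf("  p_t = %.*f, p_nt = %.*f, p_u = %.*f, kappa = %.*f\n",
              digits, x$params$p_t, digits, x$params$p_nt,
              digits, x$params$p_u, max(digits - 1, 1), x$params$kappa))
  cat(sprintf("  log-likelihood %.3f on %d trials (%s)\n",
              x$log_likelihood, x$n_trials,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
summary.mixture_fit <- function(object, ...) {
  structure(list(params = object$params,
                 log_likelihood = object$log_likelihood,
                 n_trials = object$n_trials,
                 n_starts_used = object$n_starts_used,
                 converged = object$converged,
                 mean_responsibility = colMeans(object$responsibilities)),
            class = "summary.mixture_fit")
}

#' @export
print.summary.mixture_fit <- function(x, ...) {
  cat("Three-component swap mixture model fit\n\n")
  est <- c(p_t = x$params$p_t, p_nt = x$params$p_nt, p_u = x$params$p_u,
           kappa = x$params$kappa)
  print(round(est, 4))
  cat(sprintf("\nlog-likelihood: %.3f   trials: %d   EM starts: %d   converged: %s\n",
              x$log_likelihood, x$n_trials, x$n_starts_used, x$converged))
  mr <- x$mean_responsibility
  cat(sprintf("mean posterior mass: target %.3f, non-targets %.3f, uniform %.3f\n",
              mr[1], sum(mr[-c(1, length(mr))]), mr[length(mr)]))
  invisible(x)
}

#' @export
coef.mixture_fit <- function(object, ...) {
  c(p_t = object$params$p_t, p_nt = object$params$p_nt,
    p_u = object$params$p_u, kappa = object$params$kappa)
}

#' @export
logLik.mixture_fit <- function(object, ...) {
  structure(object$log_likelihood, df = 3L, nobs = object$n_trials,
            class = "logLik")
}

#' @export
residuals.mixture_fit <- function(object, trials, ...) {
  if (missing(trials))
    stop("supply the trial set the model was fitted to", call. = FALSE)
  wrap_diff(trials$response, target_features(trials), object$space$period)
}

#' Predicted mixture density for trials
#'
#' Evaluates the fitted mixture density (per radian of the analysis circle)
#' at each trial's response, or, with `at` supplied, the trial-averaged
#' predictive density of the deviation from the target.
#'
#' @param object a `mixture_fit`.
#' @param trials a `trial_set`.
#' @param at optional deviations from the target (degrees, raw scale) at
#'   which to evaluate the trial-averaged predictive density.
#' @param ... unused.
#' @export
predict.mixture_fit <- function(object, trials, at = NULL, ...) {
  p <- object$params
  if (is.null(at)) {
    dev <- component_deviations(trials)
    return(mixture_density(dev, p$p_t, p$p_nt, p$p_u, p$kappa))
  }
  scale <- 2 * pi / object$space$period
  tf <- target_features(trials)
  nt <- nontarget_features(trials)
  vapply(at, function(d) {
    resp <- tf + d
    dev <- (resp - cbind(tf, nt)) * scale
    mean(mixture_density(dev, p$p_t, p$p_nt, p$p_u, p$kappa))
  }, numeric(1))
}

#' @export
simulate.mixture_fit <- function(object, nsim = 1, seed = NULL, trials, ...) {
  if (missing(trials))
    stop("supply a trial set providing features and targets", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- object$params
  fm <- feature_matrix(trials)
  out <- replicate(nsim, vapply(seq_len(nrow(trials)), function(i)
    generate_response(fm[i, ], trials$target_index[i] + 1L, p, object$space),
    numeric(1)))
  as.data.frame(out)
}

#' @export
plot.mixture_fit <- function(x, trials, bin_width = NULL, ...) {
  if (missing(trials))
    stop("supply the trial set the model was fitted to", call. = FALSE)
  space <- x$space
  if (is.null(bin_width)) bin_width <- space$period / 12
  err <- residuals(x, trials)
  half <- space$period / 2
  br <- seq(-half, half, by = bin_width)
  h <- graphics::hist(err, breaks = br, plot = FALSE)
  grid <- seq(-half, half, length.out = 181)
  dens <- predict(x, trials, at = grid) * 2 * pi / space$period # per degree
  graphics::plot(h, freq = FALSE, xlab = "response error (deg)",
                 main = "Response errors and fitted mixture", ...)
  graphics::lines(grid, dens, lwd = 2)
  invisible(x)
}

#' Fit the mixture model for every participant-by-condition slice
#'
#' Applies [fit_mixture()] separately to each participant in each condition,
#' pooling over ordinal positions, and collects the estimates.
#'
#' @param trials a `trial_set`.
#' @param ... passed on to [fit_mixture()].
#' @return a data frame with one row per participant x condition: the fitted
#'   proportions and concentration, log-likelihood, number of trials and
#'   convergence flag; the individual `mixture_fit` objects are attached as
#'   attribute `fits`.
#' @export
fit_by_condition <- function(trials, ...) {
  combos <- unique(trials[, c("participant", "location_condition",
                              "isi_condition")])
  combos <- combos[order(combos$participant, combos$location_condition,
                         combos$isi_condition), , drop = FALSE]
  fits <- vector("list", nrow(combos))
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sl <- trial_slice(trials, combos$participant[i],
                      combos$location_condition[i], combos$isi_condition[i])
    f <- fit_mixture(sl, ...)
    fits[[i]] <- f
    rows[[i]] <- data.frame(participant = combos$participant[i],
                            location = combos$location_condition[i],
                            isi = combos$isi_condition[i],
                            p_t = f$params$p_t, p_nt = f$params$p_nt,
                            p_u = f$params$p_u, kappa = f$params$kappa,
                            logL = f$log_likelihood, n = f$n_trials,
                            converged = f$converged)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
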