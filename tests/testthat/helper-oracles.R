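# Independent oracles and fixture builders used across the suite.

# modified Bessel function of the first kind, order 0, by its power series
bessel_i0_series <- function(x, terms = 60) {
  k <- 0:terms
  sum((x^2 / 4)^k / factorial(k)^2)
}

# bracketed root-find on the (unscaled) Bessel ratio, independent of the
# package's Newton-based inversion
kappa_oracle <- function(R, upper = 500) {
  ratio <- function(k) besselI(k, 1) / besselI(k, 0)
  uniroot(function(k) ratio(k) - R, c(1e-10, upper), tol = 1e-12)$root
}

# dense-grid maximum of the mixture log-likelihood: proportions on a 0.02
# grid, kappa on a log-spaced grid; direct summation, no EM involved
grid_loglik_best <- function(trials, step = 0.02,
                             kappas = exp(seq(log(0.5), log(200),
                                              length.out = 40))) {
  space <- attr(trials, "space")
  scale <- 2 * pi / space$period
  fm <- as.matrix(trials[, grep("^feature_", names(trials))])
  tf <- fm[cbind(seq_len(nrow(fm)), trials$target_index + 1L)]
  nt <- t(vapply(seq_len(nrow(fm)),
                 function(i) fm[i, -(trials$target_index[i] + 1L)],
                 numeric(ncol(fm) - 1L)))
  dev <- (trials$response - cbind(tf, nt)) * scale
  m <- ncol(nt)
  pg <- expand.grid(p_t = seq(0, 1, step), p_nt = seq(0, 1, step))
  pg <- pg[pg$p_t + pg$p_nt <= 1 + 1e-12, ]
  pg$p_u <- pmax(1 - pg$p_t - pg$p_nt, 0)
  best <- -Inf
  for (k in kappas) {
    fvm <- exp(k * cos(dev)) / (2 * pi * besselI(k, 0, expon.scaled = TRUE) *
                                  exp(k))
    ft <- fvm[, 1]
    fn <- rowMeans(fvm[, -1, drop = FALSE])
    # log-likelihood for every proportion combination at this kappa
    dens <- outer(ft, pg$p_t) + outer(fn, pg$p_nt) +
      matrix(pg$p_u / (2 * pi), nrow(dev), nrow(pg), byrow = TRUE)
    ll <- colSums(log(dens))
    best <- max(best, max(ll[is.finite(ll)]))
  }
  best
}

# JZS Bayes factor by dense trapezoid quadrature on g = u/(1-u)
jzs_trapezoid <- function(t, n, r = sqrt(2) / 2, n_grid = 2e5) {
  nu <- n - 1
  u <- seq(1e-9, 1 - 1e-9, length.out = n_grid)
  g <- u / (1 - u)
  q <- 1 + n * g * r^2
  f <- q^(-1 / 2) * (1 + t^2 / (q * nu))^(-(nu + 1) / 2) *
    (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g)) / (1 - u)^2
  num <- sum((f[-1] + f[-n_grid]) / 2 * diff(u))
  num / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

# build a trial_set by hand from explicit components
make_trials <- function(features, targets, responses, space,
                        location = "same", isi = "short", participant = 1,
                        locations = NULL) {
  n <- nrow(features); m <- ncol(features)
  if (is.null(locations)) locations <- matrix(0, n, m)
  df <- data.frame(participant = participant, location_condition = location,
                   isi_condition = isi, trial_index = seq_len(n),
                   target_index = targets - 1L)
  colnames(features) <- paste0("feature_", seq_len(m) - 1L)
  colnames(locations) <- paste0("location_", seq_len(m) - 1L)
  out <- cbind(df, features, locations, response = responses)
  attr(out, "space") <- space
  class(out) <- c("trial_set", "data.frame")
  out
}

# quick simulated slice from the generator, one condition
sim_slice <- function(n_trials = 120, params = mixture_params(0.7, 0.2, 0.1, 10),
                      seed = 1, space = orientation_space(), ...) {
  cfg <- generator_config(space = space, n_participants = 1,
                          trials_per_condition = n_trials,
                          block_size = n_trials,
                          conditions = data.frame(location = "same",
                                                  isi = "short"),
                          mixture_by_condition = list("same.short" = params),
                          seed = seed, ...)
  generate_dataset(cfg)
}
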