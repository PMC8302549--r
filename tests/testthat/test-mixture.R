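test_that("analysis-scale conversion doubles half-circle spaces only", {
  expect_equal(to_analysis_scale(90, orientation_space()), 180)
  expect_equal(to_analysis_scale(90, colour_space()), 90)
  x <- c(0, 10.5, 179.9)
  expect_equal(from_analysis_scale(to_analysis_scale(x, orientation_space()),
                                   orientation_space()), x)
})

test_that("mixture log-likelihood matches a brute-force evaluation", {
  sp <- orientation_space()
  features <- rbind(c(0, 20, 50, 90), c(10, 30, 70, 120), c(5, 40, 80, 100),
                    c(15, 60, 90, 140), c(0, 12, 130, 160))
  targets <- c(1L, 2L, 3L, 4L, 2L)
  responses <- c(3, 65, 85, 150, 20)
  trials <- make_trials(features, targets, responses, sp)

  params <- mixture_params(0.6, 0.25, 0.15, 6)
  # brute force: enumerate components per trial on the doubled circle
  brute <- 0
  for (i in 1:5) {
    th <- responses[i] * 2
    tgt <- features[i, targets[i]] * 2
    nts <- features[i, -targets[i]] * 2
    vm <- function(x, mu, k) exp(k * cos((x - mu) * pi / 180)) /
      (2 * pi * besselI(k, 0))
    dens <- params$p_t * vm(th, tgt, 6) +
      params$p_nt * mean(sapply(nts, function(m) vm(th, m, 6))) +
      params$p_u / (2 * pi)
    brute <- brute + log(dens)
  }
  expect_equal(mixture_loglik(trials, params), brute, tolerance = 1e-10)

  # uniform-only and kappa = 0 both collapse to N * log(1/(2*pi))
  expect_equal(mixture_loglik(trials, mixture_params(0, 0, 1, 5)),
               5 * log(1 / (2 * pi)))
  expect_equal(mixture_loglik(trials, mixture_params(0.5, 0.3, 0.2, 0)),
               5 * log(1 / (2 * pi)))
  expect_error(mixture_loglik(trials[0, ], params), "empty")
})

test_that("non-target order does not affect likelihood or fit", {
  sp <- orientation_space()
  set.seed(31)
  trials <- sim_slice(60, seed = 31)
  params <- mixture_params(0.5, 0.3, 0.2, 7)
  ll <- mixture_loglik(trials, params)
  # permute the features of the non-target positions within each trial
  fm <- as.matrix(trials[, paste0("feature_", 0:3)])
  for (i in seq_len(nrow(fm))) {
    nt_pos <- setdiff(1:4, trials$target_index[i] + 1L)
    fm[i, nt_pos] <- fm[i, sample(nt_pos)]
  }
  perm <- trials
  perm[, paste0("feature_", 0:3)] <- fm
  attr(perm, "space") <- sp
  expect_equal(mixture_loglik(perm, params), ll, tolerance = 1e-12)
})

test_that("EM recovers generating parameters at large n", {
  truth <- mixture_params(0.7, 0.2, 0.1, 10)
  trials <- sim_slice(2000, params = truth, seed = 37)
  fit <- fit_mixture(trials)
  est <- coef(fit)
  expect_lt(abs(est["p_t"] - 0.7), 0.04)
  expect_lt(abs(est["p_nt"] - 0.2), 0.04)
  expect_lt(abs(est["p_u"] - 0.1), 0.04)
  expect_lt(abs(est["kappa"] - 10) / 10, 0.2)
  expect_true(fit$converged)
  # per-iteration log-likelihood is non-decreasing
  expect_true(all(diff(fit$em_trace) > -1e-8))
  # responsibilities are a proper posterior
  expect_equal(rowSums(fit$responsibilities), rep(1, fit$n_trials),
               tolerance = 1e-9)
  # the reported likelihood is reproducible from the returned parameters
  expect_equal(mixture_loglik(trials, fit$params), fit$log_likelihood,
               tolerance = 1e-6)
})

test_that("uniform data are fit as guessing", {
  # with purely uniform responses the proportions are only weakly identified
  # (a near-zero-concentration von Mises is itself almost flat), so the
  # meaningful check is that the uniform component dominates and the fitted
  # density is indistinguishable from uniform everywhere
  trials <- sim_slice(1000, params = mixture_params(0, 0, 1, 8), seed = 41)
  fit <- fit_mixture(trials)
  expect_gt(coef(fit)[["p_u"]], 0.5)
  expect_gt(coef(fit)[["p_u"]], coef(fit)[["p_t"]] + coef(fit)[["p_nt"]])
  expect_lte(coef(fit)[["p_t"]], 0.05)
  dens <- predict(fit, trials, at = seq(-90, 90, by = 2))
  expect_lt(max(abs(dens - 1 / (2 * pi))) * 2 * pi, 0.05)
  # and the likelihood gain over the flat model is negligible per trial
  expect_lt(fit$log_likelihood - 1000 * log(1 / (2 * pi)), 3)
})

test_that("degenerate inputs are handled explicitly", {
  sp <- orientation_space()
  f <- rbind(c(0, 30, 60, 90), c(10, 40, 80, 120), c(20, 50, 90, 130),
             c(15, 45, 75, 105), c(25, 55, 85, 115),
             c(5, 35, 65, 95), c(12, 42, 72, 102), c(18, 48, 78, 108),
             c(22, 52, 82, 112), c(28, 58, 88, 118))
  tg <- rep(c(1L, 2L), 5)
  # all responses exactly on target: boundary fit
  trials <- make_trials(f, tg, f[cbind(1:10, tg)], sp)
  fit <- fit_mixture(trials)
  expect_true(fit$boundary)
  expect_equal(fit$params$p_t, 1)
  expect_equal(fit$params$kappa, 700)
  # single trial: refused
  expect_error(fit_mixture(trials[1, ]), "at least 2")
  # very small slices still fit, with a warning
  expect_warning(fit_mixture(make_trials(f[1:5, ], tg[1:5],
                                         f[cbind(1:5, tg[1:5])] + c(1, -3, 5, 2, -2),
                                         sp)),
                 "fewer than 10")
})

test_that("EM at least matches a dense grid search on small fixtures", {
  set.seed(43)
  params_pool <- list(mixture_params(0.6, 0.3, 0.1, 5),
                      mixture_params(0.9, 0.05, 0.05, 20),
                      mixture_params(0.3, 0.5, 0.2, 3))
  for (i in 1:5) {
    p <- params_pool[[(i %% 3) + 1]]
    trials <- sim_slice(24, params = p, seed = 100 + i)
    fit <- fit_mixture(trials)
    best_grid <- grid_loglik_best(trials)
    expect_gte(fit$log_likelihood, best_grid - 1e-3)
  }
})

test_that("fit_by_condition fits every participant-condition slice", {
  cfg <- generator_config(n_participants = 2, trials_per_condition = 40,
                          block_size = 40, seed = 47)
  trials <- generate_dataset(cfg)
  fits <- fit_by_condition(trials, n_starts = 4)
  expect_equal(nrow(fits), 8)
  expect_setequal(fits$location, c("same", "different"))
  expect_true(all(abs(fits$p_t + fits$p_nt + fits$p_u - 1) < 1e-9))
  expect_true(all(fits$n == 40))
  expect_length(attr(fits, "fits"), 8)
})

test_that("mixture_fit methods are coherent", {
  trials <- sim_slice(120, seed = 53)
  fit <- fit_mixture(trials)
  expect_output(print(fit), "p_nt")
  expect_output(print(summary(fit)), "log-likelihood")
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$log_likelihood)
  expect_equal(attr(ll, "df"), 3L)
  expect_length(residuals(fit, trials), 120)
  expect_true(all(abs(residuals(fit, trials)) <= 90))
  # predictive density integrates to ~1 over the feature circle (per degree)
  grid <- seq(-89.999, 90, by = 0.5)
  dens_deg <- predict(fit, trials, at = grid) * 2 * pi / 180
  expect_equal(sum(dens_deg) * 0.5, 1, tolerance = 1e-2)
  sims <- simulate(fit, nsim = 2, seed = 1, trials = trials)
  expect_equal(dim(sims), c(120, 2))
  expect_true(all(sims >= 0 & sims < 180))
})
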