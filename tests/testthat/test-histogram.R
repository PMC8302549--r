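test_that("target-error histograms bin wrapped errors correctly", {
  sp <- orientation_space()
  f <- rbind(c(0, 30, 60, 90), c(10, 40, 80, 120), c(20, 50, 90, 130))
  f <- f[rep(1:3, 10), ]
  tg <- rep(1:3, 10)
  # perfect responses: all mass in the two central bins
  trials <- make_trials(f, tg, f[cbind(1:30, tg)], sp)
  h <- target_error_histogram(trials)
  expect_s3_class(h, "deviation_histogram")
  mids <- (head(h$bin_edges, -1) + h$bin_edges[-1]) / 2
  expect_equal(sum(h$observed[abs(mids) < 15]), 30)
  expect_equal(sum(h$observed), 30)
  expect_equal(sum(h$corrected), 0, tolerance = 1e-9)
  expect_error(target_error_histogram(trials, bin_width = 14), "even number")
  # uniform responses: roughly flat
  set.seed(59)
  tru <- make_trials(f[rep(1:3, 40), ], rep(1:3, 40), runif(120, 0, 180), sp)
  hu <- target_error_histogram(tru)
  expect_lt(max(abs(hu$observed - 10)), 3 * sqrt(120 * (1 / 12) * (11 / 12)))
})

test_that("central-bin mass of a concentrated fit matches the von Mises CDF", {
  truth <- mixture_params(0.7, 0, 0.3, 10)
  trials <- sim_slice(4000, params = truth, seed = 61)
  h <- target_error_histogram(trials, bin_width = 15)
  mids <- (head(h$bin_edges, -1) + h$bin_edges[-1]) / 2
  central <- sum(h$observed[abs(mids) < 15]) / sum(h$observed)
  # oracle: mixture CDF mass over +/-15 deg raw = +/-30 deg on the doubled
  # circle, by quadrature of the von Mises density
  vm_mass <- integrate(function(x) exp(10 * cos(x)) / (2 * pi * besselI(10, 0)),
                       -30 * pi / 180, 30 * pi / 180, rel.tol = 1e-10)$value
  predicted <- 0.7 * vm_mass + 0.3 * (30 / 180)
  se <- sqrt(predicted * (1 - predicted) / 4000)
  expect_lt(abs(central - predicted), 4 * se)
})

test_that("non-target deviation histograms pool one deviation per non-target", {
  trials <- sim_slice(100, seed = 67)
  obs <- nontarget_deviation_histogram(trials)
  expect_equal(sum(obs), 300)
  # invariant under trial order
  shuf <- trials[sample(nrow(trials)), ]
  attr(shuf, "space") <- attr(trials, "space")
  class(shuf) <- class(trials)
  expect_equal(as.numeric(nontarget_deviation_histogram(shuf)),
               as.numeric(obs))
})

test_that("shuffled pseudo-non-targets keep the separation structure", {
  sp <- orientation_space()
  trials <- sim_slice(40, seed = 71)
  tf <- swapmix:::target_features(trials)
  nt <- swapmix:::nontarget_features(trials)
  n <- nrow(trials)
  offsets <- wrap_diff(nt, tf, sp$period)
  # explicit pair construction: pseudo-non-targets for B from A's offsets
  for (A in c(1, 7, 23)) for (B in c(2, 19, 40)) {
    if (A == B) next
    pseudo <- (tf[B] + offsets[A, ]) %% sp$period
    d_to_target <- abs(wrap_diff(pseudo, tf[B], sp$period))
    expect_true(all(d_to_target >= sp$min_separation - 1e-9))
    pairw <- abs(wrap_diff(rep(pseudo, each = 3), rep(pseudo, 3), sp$period))
    pairw <- pairw[rep(1:3, each = 3) != rep(1:3, 3)]
    expect_true(all(pairw >= sp$min_separation - 1e-9))
  }
  # ordered-pair count: N(N-1) pairs, 3 deviations each
  dev <- swapmix:::shuffle_deviations(trials, sp)
  expect_length(dev, n * (n - 1) * 3)
  # expected histogram mass is rescaled to the observed mass
  expected <- shuffle_expected_histogram(trials)
  expect_equal(sum(expected), 3 * n, tolerance = 1e-6)
  # order invariance of the expected histogram
  shuf <- trials[sample(n), ]
  attr(shuf, "space") <- sp
  class(shuf) <- class(trials)
  expect_equal(as.numeric(shuffle_expected_histogram(shuf)),
               as.numeric(expected), tolerance = 1e-9)
})

test_that("swap-free data show structure that the correction removes", {
  # no swaps: any apparent central structure is the separation artifact
  cfg <- generator_config(n_participants = 2,
                          mixture_by_condition = mixture_params(0.92, 0, 0.08, 8),
                          seed = 73)
  trials <- generate_dataset(cfg)
  h <- nontarget_histogram(trials)
  N <- sum(h$observed)
  p_hat <- h$expected / N
  se <- sqrt(N * p_hat * (1 - p_hat))
  expect_true(all(abs(h$corrected) <= 3 * se))
  # the uncorrected histogram is clearly non-uniform
  se_flat <- sqrt(N * (1 / 12) * (11 / 12))
  expect_gt(max(abs(h$observed - N / 12)), 3 * se_flat)
  expect_equal(sum(h$corrected), 0, tolerance = 1e-6)
})

test_that("heuristic proportions measure window hits on uncorrected deviations", {
  sp <- orientation_space()
  f <- rbind(c(0, 30, 60, 90), c(10, 40, 80, 120))
  f <- f[rep(1:2, 30), ]
  tg <- rep(c(1L, 3L), 30)
  # exact target responses
  tr <- make_trials(f, tg, f[cbind(1:60, tg)], sp)
  hp <- heuristic_proportions(tr)
  expect_equal(hp[["p_t_tilde"]], 1)
  # uniform responses: expected target rate = 2*window/period = 1/6
  set.seed(79)
  tru <- make_trials(f[rep(1:2, 600), ], rep(c(1L, 3L), 600),
                     runif(2400, 0, 180), sp)
  hpu <- heuristic_proportions(tru)
  expect_equal(hpu[["p_t_tilde"]], 1 / 6,
               tolerance = 4 * sqrt((1 / 6) * (5 / 6) / 2400) / (1 / 6))
  expect_error(heuristic_proportions(tr, window = 50), "period/4")

  # consistency with the two central histogram bins at bin_width = window
  trials <- sim_slice(200, seed = 83)
  h <- target_error_histogram(trials, bin_width = 15)
  mids <- (head(h$bin_edges, -1) + h$bin_edges[-1]) / 2
  expect_equal(heuristic_proportions(trials, window = 15)[["p_t_tilde"]],
               sum(h$observed[abs(mids) < 15]) / sum(h$observed))
})

test_that("swap errors raise the heuristic swap rate above shuffled chance", {
  base <- function(p_nt, seed) {
    trials <- sim_slice(400, params = mixture_params(0.9 - p_nt, p_nt, 0.1, 10),
                        seed = seed)
    exp_rate <- {
      dev <- swapmix:::shuffle_deviations(trials, orientation_space())
      mean(abs(dev) <= 15)
    }
    heuristic_proportions(trials)[["p_nt_tilde"]] - exp_rate
  }
  excess0 <- base(0, 89)
  excess3 <- base(0.3, 89)
  expect_gt(excess3, excess0 + 0.1)
})

test_that("mean absolute error by position tracks a recency gradient", {
  # perfect and uniform baselines
  sp <- orientation_space()
  f <- rbind(c(0, 30, 60, 90), c(10, 40, 80, 120), c(20, 50, 90, 130),
             c(5, 35, 65, 95))
  f <- f[rep(1:4, 10), ]
  tg <- rep(1:4, 10)
  perfect <- make_trials(f, tg, f[cbind(1:40, tg)], sp)
  mae <- mean_abs_error_by_position(perfect)
  expect_equal(nrow(mae), 4)
  expect_true(all(mae$mae == 0))
  # increasing kappa over positions -> decreasing error over positions
  cfg <- generator_config(n_participants = 1, trials_per_condition = 480,
                          block_size = 480,
                          conditions = data.frame(location = "same",
                                                  isi = "short"),
                          mixture_by_condition =
                            list("same.short" = mixture_params(0.95, 0, 0.05, 4)),
                          kappa_by_position = c(1, 3, 9, 27), seed = 97)
  trials <- generate_dataset(cfg)
  mae2 <- mean_abs_error_by_position(trials)
  expect_true(all(diff(mae2$mae) < 0))
})
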