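# Design-level simulation: operating characteristics of the sequential
# stopping rule over simulated cohorts run through the full pipeline
# (generate -> per-condition mixture fits -> difference-of-differences ->
# sequential Bayes factor).

#' Condition-specific mixture parameters mirroring the short-ISI swap effect
#'
#' Convenience constructor for the 2 x 2 design: an elevated swap proportion
#' in the same-location short-ISI condition (`p_nt_elevated`) against a
#' baseline (`p_nt_baseline`) in the other three conditions, with the target
#' proportion absorbing the difference. Defaults follow the effect sizes the
#' analyses are calibrated against: swap proportion 0.25 vs 0.12, uniform
#' proportion 0.08, concentration 8 on the analysis circle.
#'
#' @param p_nt_elevated swap proportion in the same/short condition.
#' @param p_nt_baseline swap proportion in the remaining conditions.
#' @param p_u uniform-guessing proportion (all conditions).
#' @param kappa von Mises concentration (all conditions).
#' @return named list of [mixture_params()] keyed `"<location>.<isi>"`.
#' @export
effect_mixtures <- function(p_nt_elevated = 0.25, p_nt_baseline = 0.12,
                            p_u = 0.08, kappa = 8) {
  base <- mixture_params(1 - p_nt_baseline - p_u, p_nt_baseline, p_u, kappa)
  list("same.short" = mixture_params(1 - p_nt_elevated - p_u, p_nt_elevated,
                                     p_u, kappa),
       "different.short" = base, "same.long" = base, "different.long" = base)
}

simulate_participant <- function(mixtures, seed, trials_per_condition = 120,
                                 space = orientation_space()) {
  cfg <- generator_config(space = space, n_participants = 1,
                          trials_per_condition = trials_per_condition,
                          mixture_by_condition = mixtures, seed = seed)
  generate_dataset(cfg)
}

#' Simulate the sequential design end to end
#'
#' Runs `n_runs` simulated cohorts through the full analysis chain:
#' participants are generated one at a time (120 trials in each of the four
#' conditions), the mixture model is fitted per condition, the
#' difference-of-differences in swap proportion is computed, and the
#' sequential stopping rule is applied after each participant. Used to
#' estimate the design's operating characteristics: the rate of correct
#' stops under a condition effect and the rate of false "H1" stops under the
#' null.
#'
#' @param n_runs number of simulated cohorts.
#' @param mixtures per-condition generative parameters; e.g.
#'   [effect_mixtures()] for the calibrated effect, or a single
#'   [mixture_params()] for a null (no-effect) design.
#' @param seed base seed; each run derives a fixed offset from it.
#' @param threshold,n_max,n_min stopping-rule settings (see
#'   [stopping_rule()]).
#' @param trials_per_condition trials per condition per participant.
#' @param n_starts EM starts per fit; the default 4 (moment start plus three
#'   lattice starts) keeps large simulations tractable.
#' @return data frame with one row per run: `run`, `decision`, `n_final`,
#'   `bf_final`, `mean_delta`.
#' @export
simulate_design <- function(n_runs, mixtures = effect_mixtures(), seed = 1,
                            threshold = 10, n_max = 20, n_min = 2,
                            trials_per_condition = 120, n_starts = 4) {
  if (inherits(mixtures, "mixture_params")) {
    keys <- condition_key(default_conditions()$location,
                          default_conditions()$isi)
    mixtures <- stats::setNames(rep(list(mixtures), length(keys)), keys)
  }
  out <- vector("list", n_runs)
  for (run in seq_len(n_runs)) {
    deltas <- numeric(0)
    decision <- "max-n"; bf_final <- NA_real_
    for (k in seq_len(n_max)) {
      pseed <- (seed + 1000003 * (run - 1) + 97 * k) %% 2147483647
      trials <- simulate_participant(mixtures, pseed, trials_per_condition)
      fits <- fit_by_condition(trials, n_starts = n_starts)
      deltas <- c(deltas, delta_pnt(fits)$delta)
      if (k < n_min) next
      t_k <- tryCatch(one_sample_t(deltas), error = function(e) NA_real_)
      if (!is.finite(t_k)) next
      bf_final <- jzs_bf_one_sample(t_k, k)$bf10
      if (bf_final > threshold) { decision <- "H1"; break }
      if (1 / bf_final > threshold) { decision <- "H0"; break }
    }
    out[[run]] <- data.frame(run = run, decision = decision, n_final = k,
                             bf_final = bf_final, mean_delta = mean(deltas))
  }
  do.call(rbind, out)
}
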