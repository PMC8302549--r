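# Bayesian layer: the difference-of-differences swap statistic, JZS default
# Bayes factors for one-sample and paired t tests, and the sequential
# stopping rule used to set the sample size.

#' Difference-of-differences in swap proportions
#'
#' The interaction proxy used for sequential testing: per participant,
#' `(p_nt(different, short) - p_nt(same, short)) -
#'  (p_nt(different, long) - p_nt(same, long))`.
#'
#' @param fits a data frame as returned by [fit_by_condition()] (columns
#'   `participant`, `location`, `isi`, `p_nt`).
#' @return data frame with columns `participant` and `delta`; participants
#'   missing any of the four condition fits are excluded with a warning.
#' @export
delta_pnt <- function(fits) {
  need <- c("participant", "location", "isi", "p_nt")
  if (!all(need %in% names(fits)))
    stop("'fits' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(fits, fits$participant), function(f) {
    g <- function(loc, i) f$p_nt[f$location == loc & f$isi == i]
    vals <- list(g("different", "short"), g("same", "short"),
                 g("different", "long"), g("same", "long"))
    if (any(lengths(vals) != 1L)) return(NULL)
    data.frame(participant = f$participant[1],
               delta = (vals[[1]] - vals[[2]]) - (vals[[3]] - vals[[4]]))
  })
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " participant(s) excluded: missing condition fits")
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(participant = numeric(0), delta = numeric(0)))
  rownames(out) <- NULL
  out
}

#' JZS Bayes factor for a one-sample t test
#'
#' Default-prior Bayes factor comparing a Cauchy(0, r) prior on the
#' standardized effect size against the point null, evaluated from the t
#' statistic by numerical integration over the normal-on-g representation of
#' the Cauchy prior (g mixed over an inverse-gamma(1/2, 1/2) distribution).
#'
#' @param t t statistic.
#' @param n sample size (`df = n - 1`); must be at least 2.
#' @param r Cauchy prior scale; the default `sqrt(2)/2` is the conventional
#'   "medium" default of standard Bayesian t-test software.
#' @return an object of class `bf_result` with elements `t_value`, `df`,
#'   `prior_scale`, `bf10` and `bf01`.
#' @examples
#' jzs_bf_one_sample(2.6, 8)   # about 2.46
#' @export
jzs_bf_one_sample <- function(t, n, r = sqrt(2) / 2) {
  if (!is.finite(t)) stop("'t' must be finite", call. = FALSE)
  if (n < 2) stop("'n' must be at least 2", call. = FALSE)
  if (r <= 0) stop("'r' must be positive", call. = FALSE)
  nu <- n - 1
  num <- stats::integrate(function(g) {
    q <- 1 + n * g * r^2
    q^(-1 / 2) * (1 + t^2 / (q * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g))
  }, 0, Inf, rel.tol = 1e-10, abs.tol = 0)$value
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  bf10 <- num / den
  structure(list(t_value = t, df = nu, prior_scale = r, bf10 = bf10,
                 bf01 = 1 / bf10),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("JZS Bayes factor: t(%g) = %.3f, r = %.3f\n", x$df, x$t_value,
              x$prior_scale))
  cat(sprintf("  BF10 = %.4g  (BF01 = %.4g)\n", x$bf10, x$bf01))
  invisible(x)
}

# t statistic for a one-sample test of 'x' against mu; all-equal degenerate
# input handled by the callers
one_sample_t <- function(x, mu = 0) {
  s <- stats::sd(x)
  if (s == 0) {
    if (isTRUE(all.equal(mean(x), mu))) return(0)
    stop("t statistic undefined: zero variance with nonzero mean",
         call. = FALSE)
  }
  (mean(x) - mu) / (s / sqrt(length(x)))
}

#' JZS Bayes factor from data
#'
#' @param x numeric sample (length at least 2).
#' @param mu null value (default 0).
#' @inheritParams jzs_bf_one_sample
#' @return a `bf_result`.
#' @rdname jzs_bf_one_sample
#' @export
one_sample_bf <- function(x, mu = 0, r = sqrt(2) / 2) {
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  jzs_bf_one_sample(one_sample_t(x, mu), length(x), r)
}

#' Paired-sample JZS Bayes factor
#'
#' One-sample JZS Bayes factor on the per-subject differences `x - y`.
#'
#' @param x,y paired numeric samples of equal length (at least 2).
#' @inheritParams jzs_bf_one_sample
#' @return a `bf_result`.
#' @export
paired_bf <- function(x, y, r = sqrt(2) / 2) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same length", call. = FALSE)
  one_sample_bf(x - y, 0, r)
}

#' Bayesian sequential stopping rule
#'
#' Emulates the sample-size rule: after each new participant (from `n_min`
#' on) a one-sample JZS Bayes factor tests whether the per-participant
#' statistic differs from zero; data collection stops with decision `"H1"`
#' when `BF10` exceeds the threshold, `"H0"` when `BF01` does, and `"max-n"`
#' when `n_max` participants are reached first. With fewer than `n_max`
#' values supplied and no threshold crossing the decision is `"undecided"`.
#'
#' @param deltas per-participant values in arrival order.
#' @param threshold Bayes-factor threshold for stopping (default 10, "strong
#'   evidence").
#' @param n_max maximum number of participants (default 20).
#' @param n_min first sample size at which the Bayes factor is evaluated
#'   (default 2, the smallest size with a variance estimate).
#' @inheritParams jzs_bf_one_sample
#' @return an object of class `stopping_trace`: the decision, the stopping
#'   sample size `n_final`, and the full trajectory (data frame `trace` with
#'   columns `n`, `t`, `bf10`).
#' @export
stopping_rule <- function(deltas, threshold = 10, n_max = 20, n_min = 2,
                          r = sqrt(2) / 2) {
  stopifnot(n_min >= 2, n_max >= n_min)
  rows <- list(); decision <- "undecided"; n_final <- length(deltas)
  upto <- min(length(deltas), n_max)
  for (k in seq_len(upto)) {
    if (k < n_min) next
    x <- deltas[seq_len(k)]
    t_k <- tryCatch(one_sample_t(x), error = function(e) NA_real_)
    if (!is.finite(t_k)) next
    bf <- jzs_bf_one_sample(t_k, k, r)$bf10
    rows[[length(rows) + 1L]] <- data.frame(n = k, t = t_k, bf10 = bf)
    if (bf > threshold) { decision <- "H1"; n_final <- k; break }
    if (1 / bf > threshold) { decision <- "H0"; n_final <- k; break }
    if (k == n_max) { decision <- "max-n"; n_final <- k }
  }
  structure(list(decision = decision, n_final = n_final,
                 threshold = threshold, n_max = n_max,
                 trace = do.call(rbind, rows)),
            class = "stopping_trace")
}

#' @export
print.stopping_trace <- function(x, ...) {
  cat(sprintf("Sequential stopping rule (BF threshold %g, max n %d)\n",
              x$threshold, x$n_max))
  cat(sprintf("  decision: %s after %d participants\n", x$decision,
              x$n_final))
  if (!is.null(x$trace)) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  final BF10 = %.4g (t(%d) = %.3f)\n", last$bf10,
                last$n - 1L, last$t))
  }
  invisible(x)
}
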