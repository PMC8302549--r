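# Histogram layer: target-error and non-target deviation histograms, the
# trial-shuffling correction for minimum feature separation, heuristic
# target/swap proportions, and mean absolute error by ordinal position.

check_bin_width <- function(bin_width, space) {
  if (is.null(bin_width)) bin_width <- space$period / 12
  k <- space$period / bin_width
  if (abs(k - round(k)) > 1e-9 || round(k) %% 2 != 0)
    stop("'bin_width' must divide the period into an even number of bins",
         call. = FALSE)
  bin_width
}

deviation_bins <- function(space, bin_width) {
  half <- space$period / 2
  seq(-half, half, by = bin_width)
}

# counts over right-closed bins; wrap_diff maps exactly -period/2 to +period/2
# so every deviation lands in (-half, half]
bin_counts <- function(dev, edges) {
  as.numeric(table(cut(dev, breaks = edges, right = TRUE,
                       include.lowest = TRUE)))
}

new_deviation_histogram <- function(edges, observed, expected, kind) {
  structure(list(bin_edges = edges, observed = observed, expected = expected,
                 corrected = observed - expected,
                 normalization = sum(observed), kind = kind),
            class = "deviation_histogram")
}

#' @export
print.deviation_histogram <- function(x, ...) {
  cat(sprintf("Deviation histogram (%s): %d bins, %g observations\n",
              x$kind, length(x$observed), x$normalization))
  df <- data.frame(bin_left = utils::head(x$bin_edges, -1),
                   bin_right = x$bin_edges[-1],
                   observed = x$observed,
                   expected = round(x$expected, 2),
                   corrected = round(x$corrected, 2))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.deviation_histogram <- function(x, ...) {
  mid <- (utils::head(x$bin_edges, -1) + x$bin_edges[-1]) / 2
  graphics::barplot(x$corrected, names.arg = mid,
                    xlab = "deviation (deg)", ylab = "corrected count",
                    main = sprintf("Corrected %s deviation histogram", x$kind),
                    ...)
  invisible(x)
}

#' Histogram of response errors relative to the target
#'
#' Bins the wrapped deviations of each response from the target feature. The
#' `expected` field is the flat histogram of equal total mass (a plotting
#' reference only — for target errors no shuffle correction is needed).
#'
#' @param trials a `trial_set` slice.
#' @param bin_width bin width in degrees; the default, `period/12`, gives 15
#'   degrees on the orientation space and 30 on the colour wheel, making the
#'   two central bins coincide with the heuristic window.
#' @return a `deviation_histogram`.
#' @export
target_error_histogram <- function(trials, bin_width = NULL) {
  if (nrow(trials) == 0L) stop("empty trial set", call. = FALSE)
  space <- trial_space(trials)
  bin_width <- check_bin_width(bin_width, space)
  edges <- deviation_bins(space, bin_width)
  dev <- wrap_diff(trials$response, target_features(trials), space$period)
  observed <- bin_counts(dev, edges)
  expected <- rep(sum(observed) / (length(edges) - 1L), length(edges) - 1L)
  new_deviation_histogram(edges, observed, expected, "target")
}

# split into participant x condition slices (the unit of the shuffle)
slice_indices <- function(trials) {
  split(seq_len(nrow(trials)),
        interaction(trials$participant, trials$location_condition,
                    trials$isi_condition, drop = TRUE))
}

# deviations of responses from pseudo-non-targets over all ordered trial
# pairs (A, B), A != B, within one slice: the shuffling construction
shuffle_deviations <- function(slice_trials, space) {
  n <- nrow(slice_trials)
  if (n < 2L) stop("shuffling needs at least 2 trials per slice", call. = FALSE)
  tf <- target_features(slice_trials)
  nt <- nontarget_features(slice_trials)
  m <- ncol(nt)
  respdev <- wrap_diff(slice_trials$response, tf, space$period)  # length n (B)
  offsets <- wrap_diff(nt, tf, space$period)                     # n x m   (A)
  # dev[B, (A, j)] = wrap(respdev_B - offset_{A,j}); drop A == B
  dev <- outer(respdev, as.vector(offsets), function(a, b)
    wrap_diff(a, b, space$period))
  a_index <- rep(seq_len(n), times = m)
  keep <- outer(seq_len(n), a_index, "!=")
  dev[keep]
}

#' Observed histogram of response deviations from non-target features
#'
#' Each trial contributes one wrapped deviation per non-target item. A
#' central peak signals swap errors, but the minimum feature separation
#' enforced at presentation makes even swap-free data non-uniform here — use
#' [shuffle_expected_histogram()] or [nontarget_histogram()] for the
#' corrected version.
#'
#' @inheritParams target_error_histogram
#' @return numeric vector of bin counts, with the edges as attribute
#'   `bin_edges`.
#' @export
nontarget_deviation_histogram <- function(trials, bin_width = NULL) {
  if (nrow(trials) == 0L) stop("empty trial set", call. = FALSE)
  space <- trial_space(trials)
  bin_width <- check_bin_width(bin_width, space)
  edges <- deviation_bins(space, bin_width)
  nt <- nontarget_features(trials)
  dev <- wrap_diff(as.vector(trials$response), as.vector(nt), space$period)
  structure(bin_counts(dev, edges), bin_edges = edges)
}

#' Shuffle-derived expected non-target histogram
#'
#' Builds the non-target deviation histogram expected in the absence of swap
#' errors: for every ordered pair of trials (A, B) within a participant x
#' condition slice, the offsets of A's non-targets from A's target are added
#' to B's target, producing pseudo-non-targets for B that obey the minimum
#' separation constraints but are unrelated to B's response; the deviations
#' of B's response from these pseudo-non-targets are pooled over all pairs
#' (exhaustively: N(N-1) pairs per slice) and rescaled so each slice carries
#' the same total mass as its observed histogram.
#'
#' @inheritParams target_error_histogram
#' @return numeric vector of expected (real-valued) bin counts, edges as
#'   attribute `bin_edges`.
#' @export
shuffle_expected_histogram <- function(trials, bin_width = NULL) {
  space <- trial_space(trials)
  bin_width <- check_bin_width(bin_width, space)
  edges <- deviation_bins(space, bin_width)
  m <- n_items_of(trials) - 1L
  counts <- rep(0, length(edges) - 1L)
  for (idx in slice_indices(trials)) {
    sl <- trials[idx, , drop = FALSE]
    attr(sl, "space") <- space
    dev <- shuffle_deviations(sl, space)
    # rescale pair counts to the slice's observed mass: n*m deviations
    counts <- counts + bin_counts(dev, edges) * (length(idx) * m) / length(dev)
  }
  structure(counts, bin_edges = edges)
}

#' Corrected non-target deviation histogram
#'
#' Combines [nontarget_deviation_histogram()] (observed) and
#' [shuffle_expected_histogram()] (expected under no swaps); the corrected
#' counts are their difference and sum to zero by construction. A central
#' peak remaining after correction indicates swap errors.
#'
#' @inheritParams target_error_histogram
#' @return a `deviation_histogram`.
#' @export
nontarget_histogram <- function(trials, bin_width = NULL) {
  observed <- nontarget_deviation_histogram(trials, bin_width)
  expected <- shuffle_expected_histogram(trials, bin_width)
  new_deviation_histogram(attr(observed, "bin_edges"), as.numeric(observed),
                          as.numeric(expected), "non-target")
}

#' Heuristic target and swap proportions
#'
#' Model-free measures: the fraction of trials whose response falls within
#' `window` degrees of the target feature, and the fraction within the same
#' window of any non-target feature (a trial can count towards both).
#' Computed on the uncorrected deviations. The default window, `period/12`,
#' is 15 degrees for orientation and 30 for colour, matching the two central
#' histogram bins at the default bin width.
#'
#' @param trials a `trial_set` slice.
#' @param window half-width of the acceptance window in degrees; must be at
#'   most `period/4`.
#' @return named numeric vector `c(p_t_tilde, p_nt_tilde)`.
#' @export
heuristic_proportions <- function(trials, window = NULL) {
  if (nrow(trials) == 0L) stop("empty trial set", call. = FALSE)
  space <- trial_space(trials)
  if (is.null(window)) window <- space$period / 12
  if (window > space$period / 4)
    stop("'window' must be at most period/4", call. = FALSE)
  tdev <- abs(wrap_diff(trials$response, target_features(trials),
                        space$period))
  nt <- nontarget_features(trials)
  ndev <- abs(wrap_diff(trials$response, nt, space$period))
  dim(ndev) <- dim(nt)
  c(p_t_tilde = mean(tdev <= window),
    p_nt_tilde = mean(apply(ndev <= window, 1, any)))
}

#' Mean absolute response error by ordinal position
#'
#' The model-free performance measure: the circular mean absolute deviation
#' of responses from the target feature, grouped by the cued item's ordinal
#' position within each participant x condition slice. A recency benefit
#' appears as decreasing error over positions.
#'
#' @param trials a `trial_set`.
#' @return data frame with columns `participant`, `location`, `isi`,
#'   `position` (1-based ordinal position), `mae` (degrees) and `n`; empty
#'   groups are omitted.
#' @export
mean_abs_error_by_position <- function(trials) {
  if (nrow(trials) == 0L) stop("empty trial set", call. = FALSE)
  space <- trial_space(trials)
  dev <- abs(wrap_diff(trials$response, target_features(trials),
                       space$period))
  key <- data.frame(participant = trials$participant,
                    location = trials$location_condition,
                    isi = trials$isi_condition,
                    position = trials$target_index + 1L)
  agg <- stats::aggregate(dev, by = key, FUN = mean)
  names(agg)[5] <- "mae"
  agg$n <- stats::aggregate(dev, by = key, FUN = length)$x
  agg[order(agg$participant, agg$location, agg$isi, agg$position), ,
      drop = FALSE]
}
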