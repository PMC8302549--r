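# Swap-gradient layer: MAD of responses from non-target features grouped by
# temporal separation (relative ordinal position) or spatial distance on the
# placement circle, against a shuffle-derived chance baseline.

#' Shuffle-derived chance level for non-target MAD
#'
#' The mean absolute deviation expected between a response and the
#' non-target features in the absence of swap errors. Without separation
#' constraints this is `period/4` (45 degrees for orientation); the minimum
#' feature distance shifts it, so the chance level is computed from the same
#' exhaustive trial-pair shuffle as the histogram correction: the MAD of each
#' response from all pseudo-non-target values. Computed separately per
#' participant x condition slice and averaged.
#'
#' @param trials a `trial_set`.
#' @return the averaged chance MAD in degrees, with a per-slice data frame
#'   attached as attribute `per_slice`.
#' @export
expected_mad_shuffled <- function(trials) {
  space <- trial_space(trials)
  idx <- slice_indices(trials)
  per <- vapply(idx, function(i) {
    sl <- trials[i, , drop = FALSE]
    attr(sl, "space") <- space
    mean(abs(shuffle_deviations(sl, space)))
  }, numeric(1))
  structure(mean(per),
            per_slice = data.frame(slice = names(idx), expected_mad = per,
                                   row.names = NULL))
}

new_distance_profile <- function(grouping, labels, mad, n, expected) {
  structure(list(grouping = grouping, group_labels = labels,
                 mad_per_group = mad, n_per_group = n,
                 expected_mad = expected),
            class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("Non-target MAD by %s distance (chance level %.2f deg)\n",
              x$grouping, x$expected_mad))
  print(data.frame(group = x$group_labels,
                   mad = round(x$mad_per_group, 2), n = x$n_per_group),
        row.names = FALSE)
  invisible(x)
}

#' @export
plot.distance_profile <- function(x, ...) {
  graphics::plot(seq_along(x$group_labels), x$mad_per_group, type = "b",
                 xaxt = "n", xlab = x$grouping, ylab = "MAD (deg)",
                 main = sprintf("Swap gradient by %s distance", x$grouping),
                 ...)
  graphics::axis(1, at = seq_along(x$group_labels), labels = x$group_labels)
  graphics::abline(h = x$expected_mad, lty = 3)
  invisible(x)
}

#' Non-target MAD by temporal separation
#'
#' Groups every non-target by its ordinal position relative to the cued item
#' (-3 to +3 for four items, 0 excluded) and computes the mean absolute
#' wrapped deviation of the response from the non-target features in each
#' group. MAD below the shuffled chance level at a separation indicates swap
#' errors specifically at that separation; the separation constraint then
#' pushes other groups above chance.
#'
#' @param trials a `trial_set` (the study computes this per participant x
#'   condition slice; pass a slice for that reading).
#' @return a `distance_profile` with the relative positions as labels; groups
#'   that cannot occur are omitted.
#' @export
mad_by_temporal_separation <- function(trials) {
  if (nrow(trials) == 0L) stop("empty trial set", call. = FALSE)
  space <- trial_space(trials)
  n_items <- n_items_of(trials)
  fm <- feature_matrix(trials)
  target_pos <- trials$target_index + 1L
  rel <- numeric(0); dev <- numeric(0)
  for (j in seq_len(n_items)) {
    keep <- target_pos != j
    if (!any(keep)) next
    rel <- c(rel, j - target_pos[keep])
    dev <- c(dev, wrap_diff(trials$response[keep], fm[keep, j],
                            space$period))
  }
  groups <- sort(unique(rel))
  mad <- vapply(groups, function(g) mean(abs(dev[rel == g])), numeric(1))
  n <- vapply(groups, function(g) sum(rel == g), numeric(1))
  new_distance_profile("temporal", groups, mad, n,
                       as.numeric(expected_mad_shuffled(trials)))
}

#' Spatial distance bins on the placement circle
#'
#' Bin edges for angular target-to-non-target distances: the first bin covers
#' distances up to 67.5 degrees and each further bin spans 37.5 degrees up to
#' 180. Right-closed, so a distance of exactly 67.5 falls in the first bin.
#' @return numeric vector of bin edges.
#' @export
spatial_bin_edges <- function() c(0, 67.5, 105, 142.5, 180)

#' Non-target MAD by spatial distance
#'
#' For different-location trials only: groups non-targets by the angular
#' distance between their location and the target's location on the placement
#' circle (period 360, independent of the feature space), using
#' [spatial_bin_edges()], and computes the MAD of response-to-non-target
#' deviations per bin. Same-location trials in the input are excluded with a
#' message.
#'
#' @inheritParams mad_by_temporal_separation
#' @return a `distance_profile` with bin labels `"(0,67.5]"` etc.
#' @export
mad_by_spatial_bin <- function(trials) {
  space <- trial_space(trials)
  same <- trials$location_condition == "same"
  if (any(same)) {
    message(sum(same), " same-location trials excluded from spatial analysis")
    trials <- trial_slice(trials, location = "different")
  }
  if (nrow(trials) == 0L)
    stop("no different-location trials available", call. = FALSE)
  lm <- location_matrix(trials)
  fm <- feature_matrix(trials)
  n_items <- n_items_of(trials)
  target_pos <- trials$target_index + 1L
  target_loc <- lm[cbind(seq_len(nrow(lm)), target_pos)]
  dist <- numeric(0); dev <- numeric(0)
  for (j in seq_len(n_items)) {
    keep <- target_pos != j
    if (!any(keep)) next
    dist <- c(dist, abs(wrap_diff(lm[keep, j], target_loc[keep], 360)))
    dev <- c(dev, wrap_diff(trials$response[keep], fm[keep, j],
                            space$period))
  }
  edges <- spatial_bin_edges()
  bin <- cut(dist, breaks = edges, right = TRUE, include.lowest = TRUE)
  mad <- as.numeric(tapply(abs(dev), bin, mean))
  n <- as.numeric(table(bin))
  new_distance_profile("spatial", levels(bin), mad, n,
                       as.numeric(expected_mad_shuffled(trials)))
}
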