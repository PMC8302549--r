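#' Mixture parameters
#'
#' Container for the three-component mixture: proportion of target responses
#' `p_t`, of swap (non-target) responses `p_nt`, of uniform guesses `p_u`
#' (summing to 1), and the shared von Mises concentration `kappa` on the
#' analysis circle (the full 360-degree circle after any doubling of a
#' half-circle feature space).
#'
#' @param p_t,p_nt,p_u component proportions in `[0, 1]`, summing to 1.
#' @param kappa concentration, in `[0, 700]`.
#' @return an object of class `mixture_params`.
#' @examples
#' mixture_params(0.67, 0.25, 0.08, 8)
#' @export
mixture_params <- function(p_t, p_nt, p_u, kappa) {
  p <- c(p_t, p_nt, p_u)
  if (any(!is.finite(p)) || any(p < -1e-12) || any(p > 1 + 1e-12))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop("p_t + p_nt + p_u must equal 1", call. = FALSE)
  if (!is.finite(kappa) || kappa < 0 || kappa > 700)
    stop("'kappa' must lie in [0, 700]", call. = FALSE)
  structure(list(p_t = p_t, p_nt = p_nt, p_u = p_u, kappa = kappa),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("Mixture parameters: p_t = %.3f, p_nt = %.3f, p_u = %.3f, kappa = %.2f\n",
              x$p_t, x$p_nt, x$p_u, x$kappa))
  invisible(x)
}

#' von Mises random deviates
#'
#' Best-Fisher wrapped-Cauchy rejection sampler.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration, `>= 0`.
#' @return angles in radians in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("'kappa' must be >= 0", call. = FALSE)
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) break
    }
    out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
  }
  out
}

default_conditions <- function() {
  expand.grid(location = c("same", "different"), isi = c("short", "long"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

condition_key <- function(location, isi) paste(location, isi, sep = ".")

#' Configuration for the synthetic trial generator
#'
#' Describes a simulated cued-recall experiment: the feature space, the
#' factorial condition design (presentation location same/different crossed
#' with short/long inter-stimulus interval), the number of trials per
#' condition (split into blocks within which every ordinal position is cued
#' equally often), the generative mixture parameters per condition, optional
#' adjacency weighting of swap destinations, optional per-position
#' concentration (a recency gradient), and the placement-circle geometry.
#'
#' @param space a [circ_space()]; default the 180-degree orientation space.
#' @param n_participants number of simulated participants.
#' @param trials_per_condition trials per condition per participant; must be
#'   divisible by `n_items` (default 120).
#' @param n_items items per trial (default 4).
#' @param conditions data frame with columns `location` and `isi`; default the
#'   full 2 x 2 design.
#' @param mixture_by_condition a single [mixture_params()] used for every
#'   condition, or a named list keyed `"<location>.<isi>"`.
#' @param swap_weights named nonnegative weights over relative ordinal
#'   positions `"-3" ... "3"` (0 excluded); renormalised per trial over the
#'   positions that exist. Default: uniform over all non-targets, matching the
#'   exchangeable-non-target mixture.
#' @param kappa_by_position optional numeric of length `n_items`: response
#'   concentration as a function of the reported item's ordinal position
#'   (overrides the condition `kappa`; emulates a recency benefit).
#' @param placement_radius radius of the invisible placement circle in degrees
#'   of visual angle (default 6).
#' @param min_center_distance minimum distance between item centers in dva on
#'   different-location trials (default 3).
#' @param block_size trials per block (default 40); each position is cued
#'   `block_size / n_items` times per block.
#' @param seed integer seed; participant substreams use fixed offsets from it.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(space = orientation_space(),
                             n_participants = 1,
                             trials_per_condition = 120,
                             n_items = 4,
                             conditions = default_conditions(),
                             mixture_by_condition = mixture_params(0.67, 0.25, 0.08, 8),
                             swap_weights = NULL,
                             kappa_by_position = NULL,
                             placement_radius = 6,
                             min_center_distance = 3,
                             block_size = 40,
                             seed = 1) {
  space <- as_space(space)
  if (trials_per_condition %% n_items != 0)
    stop("'trials_per_condition' must be divisible by 'n_items'", call. = FALSE)
  if (trials_per_condition %% block_size != 0)
    block_size <- trials_per_condition
  if (block_size %% n_items != 0)
    stop("'block_size' must be divisible by 'n_items'", call. = FALSE)
  if (n_items * space$min_separation >= space$period)
    stop("feature separation constraint infeasible for n_items", call. = FALSE)
  if (inherits(mixture_by_condition, "mixture_params")) {
    keys <- condition_key(conditions$location, conditions$isi)
    mixture_by_condition <- stats::setNames(
      rep(list(mixture_by_condition), length(keys)), keys)
  }
  if (is.null(swap_weights)) {
    d <- setdiff(seq(-(n_items - 1), n_items - 1), 0)
    swap_weights <- stats::setNames(rep(1, length(d)), as.character(d))
  }
  if (any(swap_weights < 0)) stop("'swap_weights' must be nonnegative", call. = FALSE)
  if (!is.null(kappa_by_position) && length(kappa_by_position) != n_items)
    stop("'kappa_by_position' must have length n_items", call. = FALSE)
  structure(list(space = space, n_participants = n_participants,
                 trials_per_condition = trials_per_condition,
                 n_items = n_items, conditions = conditions,
                 mixture_by_condition = mixture_by_condition,
                 swap_weights = swap_weights,
                 kappa_by_position = kappa_by_position,
                 placement_radius = placement_radius,
                 min_center_distance = min_center_distance,
                 block_size = block_size, seed = as.integer(seed)),
            class = "generator_config")
}

#' Sample item features with a minimum-separation constraint
#'
#' Draws `n_items` feature values uniformly on the circle, rejecting whole
#' tuples until every pairwise wrapped distance is at least the space's
#' minimum separation. Whole-tuple rejection keeps the accepted tuples
#' uniform on the constrained set (sequential placement would not).
#'
#' @param space a [circ_space()].
#' @param n_items number of items.
#' @param max_attempts rejection cap (default 1e5).
#' @return feature values in degrees, length `n_items`, in presentation order.
#' @export
sample_features <- function(space, n_items, max_attempts = 1e5) {
  space <- as_space(space)
  if (n_items * space$min_separation >= space$period)
    stop("separation constraint infeasible", call. = FALSE)
  if (n_items == 1L) return(stats::runif(1, 0, space$period))
  pr <- which(upper.tri(diag(n_items)), arr.ind = TRUE)
  for (i in seq_len(max_attempts)) {
    f <- stats::runif(n_items, 0, space$period)
    d <- abs(wrap_diff(f[pr[, 1]], f[pr[, 2]], space$period))
    if (min(d) >= space$min_separation) return(f)
  }
  stop(sprintf("rejection cap (%d) exceeded sampling features", max_attempts),
       call. = FALSE)
}

#' Sample item locations on the placement circle
#'
#' Same-location trials use one uniform angle for all items; the location
#' still varies from trial to trial. Different-location trials reject whole
#' tuples until every pairwise chord distance at the placement radius is at
#' least `min_center_distance`, which corresponds to a minimum angular
#' separation of `2*asin(min_center_distance / (2*placement_radius))`
#' (about 28.7 degrees at the 6 dva / 3 dva defaults).
#'
#' @param condition `"same"` or `"different"`.
#' @param n_items number of items.
#' @param placement_radius circle radius in dva.
#' @param min_center_distance minimum chord distance in dva.
#' @param max_attempts rejection cap.
#' @return location angles in degrees on the placement circle (period 360).
#' @export
sample_locations <- function(condition, n_items, placement_radius = 6,
                             min_center_distance = 3, max_attempts = 1e5) {
  condition <- match.arg(condition, c("same", "different"))
  if (condition == "same")
    return(rep(stats::runif(1, 0, 360), n_items))
  min_angle <- 2 * asin(min_center_distance / (2 * placement_radius)) * 180 / pi
  if (n_items * min_angle >= 360)
    stop("placement geometry infeasible", call. = FALSE)
  for (i in seq_len(max_attempts)) {
    a <- stats::runif(n_items, 0, 360)
    ok <- TRUE
    for (j in seq_len(n_items - 1))
      for (k in seq(j + 1, n_items))
        if (abs(wrap_diff(a[j], a[k], 360)) < min_angle) { ok <- FALSE; break }
    if (ok) return(a)
  }
  stop("rejection cap exceeded sampling locations", call. = FALSE)
}

#' Draw one response from the generative mixture
#'
#' With probability `p_t` the response is a von Mises draw around the target
#' feature; with probability `p_nt` a non-target is chosen by the (trial-
#' renormalised) swap weights and the response is drawn around its feature;
#' with probability `p_u` the response is uniform on the feature circle. On a
#' half-circle space the von Mises noise (concentration `kappa`, defined on
#' the doubled analysis circle) is applied on the doubled circle and halved
#' back, so the generating `kappa` is directly comparable to the fitted one.
#'
#' @param features item features in degrees, presentation order.
#' @param target_index 1-based index of the cued item.
#' @param params a [mixture_params()].
#' @param space a [circ_space()].
#' @param swap_weights named weights over relative positions (see
#'   [generator_config()]); `NULL` for uniform.
#' @param kappa_by_position optional per-position concentration override.
#' @param detail if `TRUE`, return a list with the response, the generating
#'   `component` (`"target"`, `"swap"` or `"uniform"`) and the reported item
#'   index (useful for checking the generator itself).
#' @return a response in degrees on the raw feature scale (or a list, with
#'   `detail = TRUE`).
#' @export
generate_response <- function(features, target_index, params, space,
                              swap_weights = NULL, kappa_by_position = NULL,
                              detail = FALSE) {
  space <- as_space(space)
  n_items <- length(features)
  u <- stats::runif(1)
  if (u < params$p_u) {
    resp <- stats::runif(1, 0, space$period)
    if (detail) return(list(response = resp, component = "uniform",
                            index = NA_integer_))
    return(resp)
  }
  if (u < params$p_u + params$p_nt && n_items > 1L) {
    d <- setdiff(seq_len(n_items), target_index) - target_index
    w <- if (is.null(swap_weights)) rep(1, length(d))
         else {
           w <- swap_weights[as.character(d)]
           w[is.na(w)] <- 0
           w
         }
    if (sum(w) == 0) w <- rep(1, length(d))
    rel <- sample(d, 1, prob = w / sum(w))
    idx <- target_index + rel
  } else {
    idx <- target_index
  }
  kappa <- if (is.null(kappa_by_position)) params$kappa
           else kappa_by_position[idx]
  scale <- 360 / space$period
  noise <- rvonmises(1, 0, kappa) * 180 / pi   # degrees on analysis circle
  resp <- ((features[idx] * scale + noise) %% 360) / scale
  if (detail) return(list(response = resp,
                          component = if (idx == target_index) "target"
                                      else "swap",
                          index = as.integer(idx)))
  resp
}

#' Generate a synthetic trial set
#'
#' Simulates the full factorial experiment described by a
#' [generator_config()]: for every participant and condition,
#' `trials_per_condition` trials in blocks within which each ordinal position
#' is cued equally often (randomly interleaved), features and locations drawn
#' under their separation constraints, and responses drawn from the
#' generative mixture. Deterministic given the config seed; participants use
#' fixed seed offsets so a dataset is reproducible independently of
#' `n_participants`.
#'
#' @param config a [generator_config()].
#' @return a `trial_set`: a data frame with columns `participant`,
#'   `location_condition`, `isi_condition`, `trial_index`, `target_index`
#'   (0-based, as stored on disk), `feature_0 ... feature_<n-1>`,
#'   `location_0 ... location_<n-1>` and `response` (degrees), with the
#'   feature space attached as attribute `space`.
#' @examples
#' cfg <- generator_config(n_participants = 1, trials_per_condition = 8,
#'                         block_size = 8, seed = 42)
#' head(generate_dataset(cfg))
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_items
  rows <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    set.seed((config$seed + 10007L * p) %% 2147483647L)
    cond_rows <- vector("list", nrow(config$conditions))
    for (ci in seq_len(nrow(config$conditions))) {
      loc <- config$conditions$location[ci]
      isi <- config$conditions$isi[ci]
      params <- config$mixture_by_condition[[condition_key(loc, isi)]]
      if (is.null(params))
        stop("no mixture parameters for condition ", condition_key(loc, isi),
             call. = FALSE)
      n_blocks <- config$trials_per_condition %/% config$block_size
      targets <- unlist(lapply(seq_len(n_blocks), function(b)
        sample(rep(seq_len(n), config$block_size %/% n))))
      nt <- config$trials_per_condition
      feat <- matrix(0, nt, n); locs <- matrix(0, nt, n); resp <- numeric(nt)
      for (t in seq_len(nt)) {
        feat[t, ] <- sample_features(config$space, n)
        locs[t, ] <- sample_locations(loc, n, config$placement_radius,
                                      config$min_center_distance)
        resp[t] <- generate_response(feat[t, ], targets[t], params,
                                     config$space, config$swap_weights,
                                     config$kappa_by_position)
      }
      df <- data.frame(participant = p, location_condition = loc,
                       isi_condition = isi, trial_index = seq_len(nt),
                       target_index = targets - 1L)
      colnames(feat) <- paste0("feature_", seq_len(n) - 1L)
      colnames(locs) <- paste0("location_", seq_len(n) - 1L)
      cond_rows[[ci]] <- cbind(df, feat, locs, response = resp)
    }
    rows[[p]] <- do.call(rbind, cond_rows)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "space") <- config$space
  class(out) <- c("trial_set", "data.frame")
  out
}

# --- trial_set accessors used across the analysis modules ------------------

trial_space <- function(trials) {
  sp <- attr(trials, "space")
  if (is.null(sp)) stop("trial set has no 'space' attribute", call. = FALSE)
  as_space(sp)
}

n_items_of <- function(trials) {
  sum(grepl("^feature_[0-9]+$", names(trials)))
}

feature_matrix <- function(trials) {
  as.matrix(trials[, paste0("feature_", seq_len(n_items_of(trials)) - 1L),
                   drop = FALSE])
}

location_matrix <- function(trials) {
  as.matrix(trials[, paste0("location_", seq_len(n_items_of(trials)) - 1L),
                   drop = FALSE])
}

target_features <- function(trials) {
  fm <- feature_matrix(trials)
  fm[cbind(seq_len(nrow(trials)), trials$target_index + 1L)]
}

nontarget_features <- function(trials) {
  fm <- feature_matrix(trials)
  n <- ncol(fm)
  t(vapply(seq_len(nrow(fm)),
           function(i) fm[i, -(trials$target_index[i] + 1L)],
           numeric(n - 1L)))
}

#' Subset a trial set to one participant and/or condition
#'
#' Analyses in this package operate on participant-by-condition slices; this
#' helper filters while preserving the `trial_set` class and space attribute.
#'
#' @param trials a `trial_set`.
#' @param participant,location,isi optional filters.
#' @return a `trial_set`.
#' @export
trial_slice <- function(trials, participant = NULL, location = NULL,
                        isi = NULL) {
  keep <- rep(TRUE, nrow(trials))
  if (!is.null(participant)) keep <- keep & trials$participant %in% participant
  if (!is.null(location)) keep <- keep & trials$location_condition %in% location
  if (!is.null(isi)) keep <- keep & trials$isi_condition %in% isi
  out <- trials[keep, , drop = FALSE]
  attr(out, "space") <- attr(trials, "space")
  class(out) <- c("trial_set", "data.frame")
  out
}
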