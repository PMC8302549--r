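# Readers/writers and the pipeline driver. All angles are stored in degrees
# on the raw feature scale; the feature-space metadata travels in a JSON
# sidecar, never per row.

sidecar_path <- function(path) paste0(path, ".space.json")

#' Write a trial set to CSV
#'
#' Writes the trial table (one row per trial, angles in degrees on the raw
#' feature scale) and a JSON sidecar `<path>.space.json` holding the feature
#' space (period, minimum separation).
#'
#' @param trials a `trial_set`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_trials <- function(trials, path) {
  space <- trial_space(trials)
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  jsonlite::write_json(list(period = space$period,
                            min_separation = space$min_separation),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and validate a trial set from CSV
#'
#' Loads a trial table written by [write_trials()] (or any file matching its
#' schema), attaches the feature space from the sidecar or the `space`
#' argument, period-reduces all angles and validates every row: condition
#' labels, target index range, finiteness, and the minimum pairwise feature
#' separation. Validation failures report the offending rows.
#'
#' @param path CSV path.
#' @param space a [circ_space()]; if `NULL`, read from the JSON sidecar.
#' @return a `trial_set`.
#' @export
read_trials <- function(path, space = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(space)) {
    sc <- sidecar_path(path)
    if (!file.exists(sc))
      stop("no 'space' given and sidecar not found: ", sc, call. = FALSE)
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    space <- circ_space(meta$period, meta$min_separation)
  }
  space <- as_space(space)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fixed <- c("participant", "location_condition", "isi_condition",
             "trial_index", "target_index", "response")
  missing_cols <- setdiff(fixed, names(df))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  n_items <- sum(grepl("^feature_[0-9]+$", names(df)))
  if (n_items < 2 ||
      !all(paste0("feature_", seq_len(n_items) - 1L) %in% names(df)) ||
      !all(paste0("location_", seq_len(n_items) - 1L) %in% names(df)))
    stop("feature_*/location_* columns incomplete", call. = FALSE)
  if (nrow(df) == 0L) {
    warning("empty trial file: ", path)
    attr(df, "space") <- space
    class(df) <- c("trial_set", "data.frame")
    return(df)
  }

  bad_label <- which(!(df$location_condition %in% c("same", "different")) |
                       !(df$isi_condition %in% c("short", "long")))
  if (length(bad_label) > 0)
    stop("invalid condition labels in row(s): ",
         paste(utils::head(bad_label, 10), collapse = ", "), call. = FALSE)
  bad_target <- which(df$target_index < 0 | df$target_index >= n_items |
                        df$target_index != round(df$target_index))
  if (length(bad_target) > 0)
    stop("target_index out of range in row(s): ",
         paste(utils::head(bad_target, 10), collapse = ", "), call. = FALSE)

  ang_cols <- c(paste0("feature_", seq_len(n_items) - 1L),
                paste0("location_", seq_len(n_items) - 1L), "response")
  for (cc in ang_cols) {
    if (!is.numeric(df[[cc]]) || any(!is.finite(df[[cc]])))
      stop("non-finite values in column ", cc, call. = FALSE)
  }
  for (cc in paste0("feature_", seq_len(n_items) - 1L))
    df[[cc]] <- df[[cc]] %% space$period
  df$response <- df$response %% space$period
  for (cc in paste0("location_", seq_len(n_items) - 1L))
    df[[cc]] <- df[[cc]] %% 360

  fm <- as.matrix(df[, paste0("feature_", seq_len(n_items) - 1L)])
  pr <- which(upper.tri(diag(n_items)), arr.ind = TRUE)
  min_pair <- apply(fm, 1, function(f)
    min(abs(wrap_diff(f[pr[, 1]], f[pr[, 2]], space$period))))
  bad_sep <- which(min_pair < space$min_separation - 1e-9)
  if (length(bad_sep) > 0)
    stop("feature separation below ", space$min_separation,
         " deg in trial row(s): ",
         paste(utils::head(bad_sep, 10), collapse = ", "), call. = FALSE)

  lm <- as.matrix(df[, paste0("location_", seq_len(n_items) - 1L)])
  same <- df$location_condition == "same"
  if (any(same)) {
    spread <- apply(lm[same, , drop = FALSE], 1, function(a)
      max(abs(wrap_diff(a, a[1], 360))))
    if (any(spread > 1e-6))
      stop("same-location trials with unequal locations in row(s): ",
           paste(utils::head(which(same)[spread > 1e-6], 10), collapse = ", "),
           call. = FALSE)
  }

  message(sprintf("read %d trials (%d participants, %d condition cells)",
                  nrow(df), length(unique(df$participant)),
                  nrow(unique(df[, c("location_condition", "isi_condition")]))))
  attr(df, "space") <- space
  class(df) <- c("trial_set", "data.frame")
  df
}

histogram_to_df <- function(h) {
  data.frame(bin_left = utils::head(h$bin_edges, -1),
             bin_right = h$bin_edges[-1], observed = h$observed,
             expected = h$expected, corrected = h$corrected)
}

profile_to_df <- function(p) {
  data.frame(grouping = p$grouping, group = as.character(p$group_labels),
             mad = p$mad_per_group, n = p$n_per_group,
             expected_mad = p$expected_mad)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the analysis in study order on a generated or supplied trial
#' set: per participant x condition mixture fits, pooled target and
#' shuffle-corrected non-target histograms per condition, heuristic
#' proportions, mean absolute error by ordinal position, temporal and spatial
#' swap-gradient profiles, the per-participant difference-of-differences in
#' swap proportion, and the sequential stopping trace. All results are
#' written as CSV to `out_dir` together with a machine-readable run manifest.
#'
#' @param input a [generator_config()] (the data are simulated) or a
#'   `trial_set`.
#' @param out_dir output directory, created if needed.
#' @param n_starts EM starts for the mixture fits (see [fit_mixture()]).
#' @return invisibly, a list with the in-memory results (`trials`, `fits`,
#'   `histograms`, `heuristics`, `mae`, `distance`, `deltas`, `stopping`) and
#'   the output file paths.
#' @export
run_pipeline <- function(input, out_dir, n_starts = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  if (inherits(input, "generator_config")) {
    seed <- input$seed
    trials <- generate_dataset(input)
    jsonlite::write_json(input[setdiff(names(input), "mixture_by_condition")],
                         p("config.json"), auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  } else if (inherits(input, "trial_set")) {
    seed <- NA
    trials <- input
  } else stop("'input' must be a generator_config or trial_set", call. = FALSE)
  write_trials(trials, p("trials.csv"))
  message("pipeline: ", nrow(trials), " trials")

  fits <- fit_by_condition(trials, n_starts = n_starts)
  utils::write.csv(fits, p("fits.csv"), row.names = FALSE)
  message("pipeline: ", nrow(fits), " mixture fits")

  conds <- unique(trials[, c("location_condition", "isi_condition")])
  hist_rows <- list()
  for (i in seq_len(nrow(conds))) {
    sl <- trial_slice(trials, location = conds$location_condition[i],
                      isi = conds$isi_condition[i])
    for (kind in c("target", "nontarget")) {
      h <- if (kind == "target") target_error_histogram(sl)
           else nontarget_histogram(sl)
      d <- histogram_to_df(h)
      d$kind <- kind
      d$location <- conds$location_condition[i]
      d$isi <- conds$isi_condition[i]
      hist_rows[[length(hist_rows) + 1L]] <- d
    }
  }
  histograms <- do.call(rbind, hist_rows)
  utils::write.csv(histograms, p("histograms.csv"), row.names = FALSE)

  combos <- unique(trials[, c("participant", "location_condition",
                              "isi_condition")])
  heur <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sl <- trial_slice(trials, combos$participant[i],
                      combos$location_condition[i], combos$isi_condition[i])
    hp <- heuristic_proportions(sl)
    data.frame(participant = combos$participant[i],
               location = combos$location_condition[i],
               isi = combos$isi_condition[i],
               p_t_tilde = hp[["p_t_tilde"]], p_nt_tilde = hp[["p_nt_tilde"]])
  }))
  utils::write.csv(heur, p("heuristics.csv"), row.names = FALSE)

  mae <- mean_abs_error_by_position(trials)
  utils::write.csv(mae, p("mae_by_position.csv"), row.names = FALSE)

  dist_rows <- list()
  for (i in seq_len(nrow(conds))) {
    sl <- trial_slice(trials, location = conds$location_condition[i],
                      isi = conds$isi_condition[i])
    d <- profile_to_df(mad_by_temporal_separation(sl))
    d$location <- conds$location_condition[i]; d$isi <- conds$isi_condition[i]
    dist_rows[[length(dist_rows) + 1L]] <- d
    if (conds$location_condition[i] == "different") {
      d <- profile_to_df(mad_by_spatial_bin(sl))
      d$location <- conds$location_condition[i]
      d$isi <- conds$isi_condition[i]
      dist_rows[[length(dist_rows) + 1L]] <- d
    }
  }
  distance <- do.call(rbind, dist_rows)
  utils::write.csv(distance, p("distance_profiles.csv"), row.names = FALSE)

  deltas <- delta_pnt(fits)
  utils::write.csv(deltas, p("deltas.csv"), row.names = FALSE)
  stopping <- NULL
  if (nrow(deltas) >= 2) {
    stopping <- stopping_rule(deltas$delta)
    tr <- stopping$trace
    tr$decision <- ""
    tr$decision[nrow(tr)] <- stopping$decision
    utils::write.csv(tr, p("stopping.csv"), row.names = FALSE)
  }

  manifest <- list(package = "swapmix",
                   version = as.character(utils::packageVersion("swapmix")),
                   r_version = as.character(getRversion()),
                   seed = seed, n_trials = nrow(trials),
                   n_fits = nrow(fits),
                   trials_md5 = unname(tools::md5sum(p("trials.csv"))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(trials = trials, fits = fits, histograms = histograms,
                 heuristics = heur, mae = mae, distance = distance,
                 deltas = deltas, stopping = stopping, out_dir = out_dir))
}

#' Reproduce the headline mixture and Bayes-factor numbers from deposited data
#'
#' Given a local copy of the study's deposited trial data converted to this
#' package's CSV schema (see [read_trials()]), refits the mixture per
#' participant and condition and recomputes the headline quantities: the
#' participant-mean swap proportion in the same- and different-location
#' short-ISI conditions, the participant-mean target proportion in the
#' same-location short-ISI condition, the paired Bayes factor for the
#' location effect on swap proportion at short ISI, and the one-sample Bayes
#' factor on the difference-of-differences.
#'
#' @param path path to the trial CSV (with space sidecar or `space` given).
#' @param space optional [circ_space()].
#' @return named list of the recomputed quantities.
#' @export
reproduce_headline_numbers <- function(path, space = NULL) {
  trials <- read_trials(path, space)
  fits <- fit_by_condition(trials)
  pick <- function(loc, isi, col)
    fits[[col]][fits$location == loc & fits$isi == isi]
  deltas <- delta_pnt(fits)
  list(mean_p_nt_same_short = mean(pick("same", "short", "p_nt")),
       mean_p_nt_different_short = mean(pick("different", "short", "p_nt")),
       mean_p_t_same_short = mean(pick("same", "short", "p_t")),
       bf_location_short = paired_bf(pick("same", "short", "p_nt"),
                                     pick("different", "short", "p_nt"))$bf10,
       bf_delta_pnt = one_sample_bf(deltas$delta)$bf10,
       n_participants = nrow(deltas))
}
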