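# Dataset file schema and run configuration.
#
# Interchange format: plain CSV with header.  Columns:
#   participant_id, experiment (1|2), trial_index, target_deg,
#   bet1_deg..bet6_deg, undo_bet_index, undo_original_deg
# Angles are degrees in [0, 360), serialized to 3 decimals; undo columns are
# empty unless experiment = 2.

dataset_angle_cols <- function(n_bets = 6L) {
  c("target_deg", paste0("bet", seq_len(n_bets), "_deg"))
}

required_cols <- function(n_bets = 6L) {
  c("participant_id", "experiment", "trial_index",
    dataset_angle_cols(n_bets), "undo_bet_index", "undo_original_deg")
}

#' Write a dataset to CSV
#'
#' Deterministic column order and number formatting (angles to 3 decimals),
#' so identical datasets produce byte-identical files.
#'
#' @param dataset A `bet_dataset` (or data.frame in the dataset schema).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  nb <- ncol(bet_matrix(dataset))
  cols <- required_cols(nb)
  missing <- setdiff(cols, names(dataset))
  if (length(missing) > 0) {
    stop("dataset is missing columns: ", paste(missing, collapse = ", "))
  }
  out <- dataset[, cols, drop = FALSE]
  for (col in dataset_angle_cols(nb)) {
    out[[col]] <- sprintf("%.3f", out[[col]])
  }
  out$undo_original_deg <- ifelse(is.na(dataset$undo_original_deg), "",
                                  sprintf("%.3f", dataset$undo_original_deg))
  out$undo_bet_index <- ifelse(is.na(dataset$undo_bet_index), "",
                               as.character(dataset$undo_bet_index))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a dataset from CSV
#'
#' Validates the schema: required columns present, all angles in
#' `[0, 360)`, trial rows complete.  Malformed rows are reported with their
#' line numbers.
#'
#' @param path CSV file in the dataset schema.
#' @param n_bets Expected number of bet columns (default 6).
#' @return A validated `bet_dataset`.
#' @export
read_dataset <- function(path, n_bets = 6L) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- required_cols(n_bets)
  missing <- setdiff(cols, names(raw))
  if (length(missing) > 0) {
    stop("malformed dataset file: missing columns ",
         paste(missing, collapse = ", "))
  }
  raw <- raw[, cols, drop = FALSE]
  angle_cols <- dataset_angle_cols(n_bets)
  bad <- rep(FALSE, nrow(raw))
  for (col in angle_cols) {
    v <- raw[[col]]
    bad <- bad | !is.finite(v) | v < 0 | v >= 360
  }
  if (any(bad)) {
    # +1 for the header line
    stop("out-of-range or missing angles at line(s): ",
         paste(which(bad) + 1L, collapse = ", "))
  }
  if (!is.numeric(raw$undo_original_deg)) {
    raw$undo_original_deg <- as.numeric(raw$undo_original_deg)
  }
  raw$undo_bet_index <- as.integer(raw$undo_bet_index)
  badu <- !is.na(raw$undo_original_deg) &
    (raw$undo_original_deg < 0 | raw$undo_original_deg >= 360)
  if (any(badu)) {
    stop("out-of-range undo angles at line(s): ",
         paste(which(badu) + 1L, collapse = ", "))
  }
  class(raw) <- c("bet_dataset", "data.frame")
  raw
}

#' Run configuration
#'
#' Bundles every knob of a simulate-score-analyze run.  The defaults
#' reproduce the study setup: component sd 4 degrees, penalty exponent
#' 0.4, 6 bets with the first twice as tall, a 40 x 150 cohort.
#'
#' @param observer,n_participants,n_trials,seed,participant_jitter
#'   Simulation settings; `observer` is a kind accepted by
#'   [observer_params()].
#' @param exponent,gauss_sd,standard_peak,normalization,n_bets,first_bet_multiplier
#'   Scoring settings, see [penalty_params()].
#' @param spread_measure,flip_axis,ks_variant,min_trials_ks Analysis
#'   settings, see [analyze_dataset()].
#' @param ... Observer hyper-parameters passed on to [observer_params()]
#'   (e.g. `encoding_sd`, `skew`, `lapse_rate`, `undo_enabled`).
#' @return An object of class `run_config` (a plain list).
#' @export
run_config <- function(observer = "sampling", n_participants = 40L,
                       n_trials = 150L, seed = 1L,
                       participant_jitter = 0.2,
                       exponent = 0.4, gauss_sd = 4, standard_peak = 0.1,
                       normalization = "fixed", n_bets = 6L,
                       first_bet_multiplier = 2,
                       spread_measure = "adjacent", flip_axis = "target",
                       ks_variant = "pseudo_sample", min_trials_ks = 20,
                       ...) {
  cfg <- list(observer = observer, n_participants = as.integer(n_participants),
              n_trials = as.integer(n_trials), seed = as.integer(seed),
              participant_jitter = participant_jitter,
              exponent = exponent, gauss_sd = gauss_sd,
              standard_peak = standard_peak, normalization = normalization,
              n_bets = as.integer(n_bets),
              first_bet_multiplier = first_bet_multiplier,
              spread_measure = spread_measure, flip_axis = flip_axis,
              ks_variant = ks_variant, min_trials_ks = min_trials_ks,
              observer_args = list(...))
  class(cfg) <- "run_config"
  cfg
}

config_penalty_params <- function(cfg) {
  penalty_params(exponent = cfg$exponent, gauss_sd = cfg$gauss_sd,
                 standard_peak = cfg$standard_peak,
                 normalization = cfg$normalization, n_bets = cfg$n_bets,
                 first_bet_multiplier = cfg$first_bet_multiplier)
}

config_observer_params <- function(cfg) {
  do.call(observer_params,
          c(list(kind = cfg$observer, n_bets = cfg$n_bets),
            cfg$observer_args))
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file with flat `run_config` fields (unknown fields
#'   rejected).
#' @return [read_run_config()]: a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(vals), c(setdiff(known, "..."),
                                  names(formals(observer_params))))
  if (length(extra) > 0) {
    stop("unknown config fields: ", paste(extra, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  flat <- unclass(config)
  flat <- c(flat[names(flat) != "observer_args"], config$observer_args)
  yaml::write_yaml(flat, path)
  invisible(path)
}
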