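trial_cols <- c("predator_stage_id", "replicate_id", "prey_id", "n_offered", "n_surviving")

#' Validate a table of feeding trials
#'
#' Checks the long-format trial table invariants: required columns present,
#' counts non-negative with `n_surviving <= n_offered`, and (when a roster is
#' supplied) every trial covering exactly the roster's prey set. Prey that
#' were never offered in a trial are an error, not imputed: a missing prey
#' row would silently corrupt the selectivity index.
#'
#' @param trials Data frame with columns `predator_stage_id`, `replicate_id`,
#'   `prey_id`, `n_offered`, `n_surviving` (one row per predator individual
#'   and prey type).
#' @param roster Optional prey roster (as [default_prey_roster()]); if given,
#'   each trial must contain each `prey_id` of the roster exactly once.
#' @return The validated table, invisibly as a tibble.
#' @export
validate_trials <- function(trials, roster = NULL) {
  trials <- tibble::as_tibble(trials)
  missing_cols <- setdiff(trial_cols, names(trials))
  if (length(missing_cols) > 0) {
    abort(paste0("trial table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "preysel_schema_error")
  }
  bad <- which(trials$n_surviving > trials$n_offered |
                 trials$n_surviving < 0 | trials$n_offered <= 0)
  if (length(bad) > 0) {
    abort(paste0("invalid counts (need 0 <= n_surviving <= n_offered, n_offered > 0) at row(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "preysel_validation_error")
  }
  if (!is.null(roster)) {
    chk <- trials |>
      dplyr::group_by(.data$predator_stage_id, .data$replicate_id) |>
      dplyr::summarise(
        ok = setequal(.data$prey_id, roster$prey_id) &&
          !anyDuplicated(.data$prey_id),
        .groups = "drop")
    if (any(!chk$ok)) {
      off <- chk[!chk$ok, ]
      abort(paste0("trial(s) not covering the prey roster exactly once: ",
                   paste(paste(off$predator_stage_id, off$replicate_id, sep = "/"),
                         collapse = ", ")),
            class = "preysel_validation_error")
    }
  }
  invisible(trials)
}

#' Read feeding trials from a long-format CSV
#'
#' One row per (predator individual, prey type) with initial and surviving
#' counts. This is the canonical on-disk form; use [trials_from_wide()] to
#' convert spreadsheet-style wide tables.
#'
#' @param path CSV file with columns `predator_stage_id`, `replicate_id`,
#'   `prey_id`, `n_offered`, `n_surviving`.
#' @inheritParams validate_trials
#' @return A validated tibble of trials.
#' @export
read_trials <- function(path, roster = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  trials <- readr::read_csv(path, show_col_types = FALSE)
  validate_trials(trials, roster)
  tibble::as_tibble(trials)
}

#' Write feeding trials to CSV
#'
#' Writes the canonical long format with a fixed column order and row order
#' (predator, replicate, prey), so write-read round trips are byte-stable.
#'
#' @param trials Trial table (see [validate_trials()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  trials <- dplyr::arrange(trials[, trial_cols],
                           .data$predator_stage_id, .data$replicate_id, .data$prey_id)
  readr::write_csv(trials, path)
  invisible(path)
}

#' Convert a wide trial table to the canonical long format
#'
#' Spreadsheet-style inputs often carry one column of surviving counts per
#' prey type. This converter melts such a table given the roster that maps
#' prey columns to initial offers.
#'
#' @param wide Data frame with `predator_stage_id`, `replicate_id` and one
#'   column per prey type holding surviving counts.
#' @param roster Prey roster supplying `prey_id` and `n_offered_default`.
#' @return A long-format tibble of trials.
#' @export
trials_from_wide <- function(wide, roster = default_prey_roster()) {
  wide <- tibble::as_tibble(wide)
  missing_prey <- setdiff(roster$prey_id, names(wide))
  if (length(missing_prey) > 0) {
    abort(paste0("wide table is missing prey column(s): ",
                 paste(missing_prey, collapse = ", ")),
          class = "preysel_schema_error")
  }
  long <- tidyr::pivot_longer(wide, cols = dplyr::all_of(roster$prey_id),
                              names_to = "prey_id", values_to = "n_surviving")
  long$n_offered <- roster$n_offered_default[match(long$prey_id, roster$prey_id)]
  validate_trials(long[, trial_cols])
}

#' Read control-trial mortality
#'
#' Background (predator-free) prey mortality used to correct consumed counts.
#' The file may give either `mean_dead` (mean dead individuals per control
#' trial) or `percent_dead` (percent of the default offer); percents are
#' normalised to mean counts using the roster's `n_offered_default`, since
#' downstream corrections operate on counts.
#'
#' @param path CSV with columns `prey_id`, `n_control_trials` and one of
#'   `mean_dead` or `percent_dead`.
#' @param roster Prey roster (needed to convert percents to counts).
#' @return Tibble with `prey_id`, `mean_dead`, `n_control_trials`.
#' @export
read_controls <- function(path, roster = default_prey_roster()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ctl <- readr::read_csv(path, show_col_types = FALSE)
  if (!"mean_dead" %in% names(ctl)) {
    if (!"percent_dead" %in% names(ctl)) {
      abort("controls need a mean_dead or percent_dead column",
            class = "preysel_schema_error")
    }
    n0 <- roster$n_offered_default[match(ctl$prey_id, roster$prey_id)]
    ctl$mean_dead <- ctl$percent_dead / 100 * n0
  }
  validate_controls(ctl, roster)
}

#' Controls from a roster's mortality proportions
#'
#' Convenience constructor turning the `control_mortality` proportion carried
#' by a prey roster into the mean-dead-count table the correction step needs.
#'
#' @param roster Prey roster with `control_mortality`.
#' @param n_control_trials Number of control trials the means describe.
#' @return Tibble with `prey_id`, `mean_dead`, `n_control_trials`.
#' @export
controls_from_roster <- function(roster = default_prey_roster(), n_control_trials = 4L) {
  validate_controls(
    tibble(prey_id = roster$prey_id,
           mean_dead = roster$control_mortality * roster$n_offered_default,
           n_control_trials = as.integer(n_control_trials)),
    roster)
}

validate_controls <- function(controls, roster = NULL) {
  controls <- tibble::as_tibble(controls)
  need <- c("prey_id", "mean_dead")
  missing_cols <- setdiff(need, names(controls))
  if (length(missing_cols) > 0) {
    abort(paste0("control table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "preysel_schema_error")
  }
  if (any(controls$mean_dead < 0)) {
    abort("mean_dead must be non-negative", class = "preysel_validation_error")
  }
  if (!is.null(roster)) {
    n0 <- roster$n_offered_default[match(controls$prey_id, roster$prey_id)]
    if (any(!is.na(n0) & controls$mean_dead > n0)) {
      abort("mean_dead exceeds the default offer for some prey",
            class = "preysel_validation_error")
    }
  }
  controls
}

#' Read a literature table of published selectivity experiments
#'
#' Long format: one row per (experiment, prey taxon offered), with flags for
#' whether the taxon was among the most preferred in that experiment, the
#' microhabitats of predator and prey, and experiment-level flags. Rows of an
#' experiment reported as unselective simply carry `most_preferred_flag = 0`
#' everywhere.
#'
#' @param path CSV with columns `study_id`, `experiment_id`,
#'   `predator_taxon`, `predator_stage`, `predator_microhabitat`,
#'   `prey_taxon`, `prey_microhabitat`, `most_preferred_flag`,
#'   `habitat_structure`, `multiple_choice`.
#' @return A validated tibble, one row per offered prey taxon.
#' @export
read_literature <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  validate_literature(readr::read_csv(path, show_col_types = FALSE))
}

validate_literature <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("study_id", "experiment_id", "predator_taxon",
            "predator_microhabitat", "prey_taxon", "prey_microhabitat",
            "most_preferred_flag")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("literature table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "preysel_schema_error")
  }
  if (!all(records$most_preferred_flag %in% c(0, 1))) {
    abort("most_preferred_flag must be 0/1", class = "preysel_validation_error")
  }
  n_offered <- table(records$experiment_id)
  if (any(n_offered < 1)) abort("each experiment must offer at least one prey taxon")
  records
}

#' Write a labelled square matrix as TSV
#'
#' @param mat Matrix with row and column names (an overlap or dissimilarity
#'   matrix, or a weight matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- tibble::as_tibble(as.data.frame(mat), rownames = "label")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a labelled matrix written by [write_matrix_tsv()]
#'
#' @param path TSV whose first column (`label`) holds row names.
#' @return A numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  mat <- as.matrix(df[, -1])
  rownames(mat) <- df[[1]]
  mat
}
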