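#' Prey mortality across predator stages
#'
#' Per (prey, predator stage): the mean and standard error across replicates
#' of the proportion consumed (control-corrected consumption over the
#' initial offer). The per-prey grand mean averages the per-predator means
#' with equal weight, i.e. it is the overall observed mortality averaged
#' across all predator-prey combinations, not across raw replicates.
#'
#' @param trials Trial table.
#' @param controls Control summary, or `NULL` to skip the correction.
#' @return Object of class `mortality_table`: list with `cells` (tibble per
#'   prey and predator: `mean_mortality`, `se_mortality`, `n`), and
#'   `grand` (tibble per prey: `grand_mean_mortality`). Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
#' @examples
#' study <- simulate_study(seed = 1)
#' mt <- mortality_table(study$trials, study$controls)
#' glance(mt)
mortality_table <- function(trials, controls = NULL) {
  cons <- if (is.null(controls)) {
    dplyr::mutate(validate_trials(trials),
                  consumed = as.numeric(.data$n_offered - .data$n_surviving))
  } else {
    control_correct(trials, controls)
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  cells <- cons |>
    dplyr::mutate(mortality = .data$consumed / .data$n_offered) |>
    dplyr::group_by(.data$prey_id, .data$predator_stage_id) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_mortality = mean(.data$mortality),
                     se_mortality = se(.data$mortality),
                     .groups = "drop")
  grand <- cells |>
    dplyr::group_by(.data$prey_id) |>
    dplyr::summarise(grand_mean_mortality = mean(.data$mean_mortality),
                     .groups = "drop")
  structure(list(cells = cells, grand = grand), class = "mortality_table")
}

#' @export
print.mortality_table <- function(x, ...) {
  cat("Mortality table:", length(unique(x$cells$prey_id)), "prey x",
      length(unique(x$cells$predator_stage_id)), "predator stages\n")
  print(x$grand)
  invisible(x)
}

#' @describeIn mortality_table Per-cell means, one row per (prey, predator).
#' @param x A `mortality_table`.
#' @param ... Unused.
#' @method tidy mortality_table
#' @export
tidy.mortality_table <- function(x, ...) x$cells

#' @describeIn mortality_table Per-prey grand means.
#' @method glance mortality_table
#' @export
glance.mortality_table <- function(x, ...) x$grand

#' Prey-by-predator matrix of mean mortalities
#'
#' @param x A [mortality_table()].
#' @return Numeric matrix, prey in rows, predator stages in columns.
#' @export
mortality_matrix <- function(x) {
  stopifnot(inherits(x, "mortality_table"))
  wide <- tidyr::pivot_wider(
    x$cells[, c("prey_id", "predator_stage_id", "mean_mortality")],
    names_from = "predator_stage_id", values_from = "mean_mortality",
    values_fill = 0)
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$prey_id
  mat
}

#' Quasi-binomial GLM of prey vulnerability across predators
#'
#' For each prey type, fits a quasi-binomial (logit link, free dispersion)
#' GLM of the replicate-level proportion consumed on the predator-stage
#' factor, each replicate weighted by its binomial denominator (the initial
#' offer). Significance of the predator factor comes from the analysis-of-
#' deviance F test, the appropriate reference under estimated dispersion.
#'
#' @param trials Trial table.
#' @param controls Control summary, or `NULL`.
#' @return Tibble per prey: `F_statistic`, `df1`, `df2`, `p_value`,
#'   `dispersion`.
#' @export
#' @examples
#' study <- simulate_study(seed = 1)
#' vulnerability_glm(study$trials, study$controls)
vulnerability_glm <- function(trials, controls = NULL) {
  cons <- if (is.null(controls)) {
    dplyr::mutate(validate_trials(trials),
                  consumed = as.numeric(.data$n_offered - .data$n_surviving))
  } else {
    control_correct(trials, controls)
  }
  cons <- dplyr::mutate(cons, mortality = .data$consumed / .data$n_offered)
  purrr::map_dfr(split(cons, cons$prey_id), function(d) {
    if (length(unique(d$predator_stage_id)) < 2) {
      abort("vulnerability GLM needs at least 2 predator stages")
    }
    fit <- stats::glm(mortality ~ factor(predator_stage_id),
                      family = stats::quasibinomial(), data = d,
                      weights = d$n_offered)
    av <- stats::anova(fit, test = "F")
    tibble(
      prey_id = d$prey_id[1],
      F_statistic = av$F[2],
      df1 = av$Df[2],
      df2 = av$`Resid. Df`[2],
      p_value = av$`Pr(>F)`[2],
      dispersion = summary(fit)$dispersion)
  })
}
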