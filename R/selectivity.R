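#' Correct consumption for background (control) mortality
#'
#' The number of prey missing at the end of a trial overstates consumption
#' whenever prey also die of natural causes. Following standard practice for
#' short multiple-choice trials, the mean number of dead individuals observed
#' in predator-free control trials is subtracted from the missing count, and
#' the result clamped to `[0, n_offered]`. Corrected consumption is
#' real-valued; no rounding is applied before index estimation.
#'
#' @param trials Validated trial table (see [validate_trials()]).
#' @param controls Control summary with `prey_id` and `mean_dead` (see
#'   [read_controls()] / [controls_from_roster()]).
#' @return The trial table with columns `n_missing` (raw missing count) and
#'   `consumed` (control-corrected consumption `r`).
#' @export
#' @examples
#' study <- simulate_study(seed = 1)
#' control_correct(study$trials, study$controls)
control_correct <- function(trials, controls) {
  trials <- validate_trials(trials)
  controls <- validate_controls(controls)
  uncovered <- setdiff(unique(trials$prey_id), controls$prey_id)
  if (length(uncovered) > 0) {
    abort(paste0("controls missing for prey: ", paste(uncovered, collapse = ", ")),
          class = "preysel_validation_error")
  }
  trials |>
    dplyr::mutate(n_missing = .data$n_offered - .data$n_surviving) |>
    dplyr::left_join(controls[, c("prey_id", "mean_dead")], by = "prey_id") |>
    dplyr::mutate(
      consumed = pmin(pmax(.data$n_missing - .data$mean_dead, 0), .data$n_offered)) |>
    dplyr::select(-"mean_dead")
}

#' Manly-Chesson selectivity index for one trial
#'
#' Estimates the selectivity vector alpha from consumed counts `r` and
#' initial offers `n0`: `alpha_i = (r_i / n_i0) / sum_j (r_j / n_j0)`. The
#' index is the probability that the predator's next capture is prey `i`
#' when all prey are equally available, so it corrects for unequal offers.
#'
#' When the predator consumed a prey completely (`r_i = n_i0`), one
#' individual is added to that prey's initial count before forming the
#' ratios (in the numerator term and in the normalising sum alike). This
#' assumes the hypothetical extra individual would have survived, making the
#' estimate slightly conservative for the depleted prey.
#'
#' @param consumed Numeric vector `r` of consumed counts (may be fractional
#'   after control correction).
#' @param n_offered Integer vector of initial offers `n0`, same length.
#' @param depletion_correction Apply the +1 correction to fully consumed
#'   prey (default `TRUE`).
#' @return Numeric vector alpha summing to 1, or all-`NA` when nothing was
#'   consumed (such individuals are excluded from averaging downstream).
#' @export
#' @examples
#' manly_alpha(c(5, 2, 3), c(10, 10, 30))  # 0.625 0.250 0.125
#' manly_alpha(c(10, 3), c(10, 10))        # depletion-corrected: 10/11 vs 3/10
manly_alpha <- function(consumed, n_offered, depletion_correction = TRUE) {
  stopifnot(length(consumed) == length(n_offered))
  if (any(consumed < 0) || any(consumed > n_offered + 1e-9)) {
    abort("need 0 <= consumed <= n_offered", class = "preysel_validation_error")
  }
  n_eff <- n_offered +
    as.numeric(depletion_correction & consumed >= n_offered - 1e-9)
  ratio <- consumed / n_eff
  total <- sum(ratio)
  if (total <= 0) return(rep(NA_real_, length(consumed)))
  ratio / total
}

#' Chesson electivity index
#'
#' Rescales Manly-Chesson alpha to `[-1, +1]` via
#' `eps = (m * alpha - 1) / ((m - 2) * alpha + 1)`, where `m` is the number
#' of prey types on offer. Values of 0 mean unselective feeding
#' (`alpha = 1/m`), -1 a prey absent from the diet, +1 a prey forming the
#' entire diet. The transform is strictly increasing in alpha for `m >= 3`.
#'
#' @param alpha Numeric vector of selectivity values in `[0, 1]`.
#' @param m Number of prey types in the experiment (>= 3; the rescaling
#'   degenerates below that).
#' @return Numeric vector of electivities in `[-1, 1]`.
#' @export
#' @examples
#' electivity(c(0, 1 / 7, 0.5, 1), m = 7)
electivity <- function(alpha, m) {
  if (m < 3) abort("electivity requires at least 3 prey types")
  if (any(alpha < -1e-9 | alpha > 1 + 1e-9, na.rm = TRUE)) {
    abort("alpha must lie in [0, 1]")
  }
  (m * alpha - 1) / ((m - 2) * alpha + 1)
}

#' Per-individual and species-level selectivity profile
#'
#' Runs the full selectivity workflow: control-mortality correction,
#' per-individual Manly-Chesson alpha with depletion correction, electivity
#' conversion, species-level means with standard errors, and diet breadth
#' (the number of prey types a predator consumed at all, i.e. with mean
#' electivity above -1). Individuals that consumed nothing carry no
#' information about relative preference and are excluded from averaging
#' (they are listed in the returned object).
#'
#' @param trials Trial table.
#' @param controls Control summary; `NULL` for no background-mortality
#'   correction.
#' @param depletion_correction Passed to [manly_alpha()].
#' @return An object of class `selectivity_profile`: a list with
#'   `individual` (per-individual alpha/electivity, long), `summary`
#'   (per predator and prey: `mean_alpha`, `se_alpha`, `mean_electivity`,
#'   `se_electivity`, `n_individuals`), `breadth` (per predator), `m`, and
#'   `excluded` (zero-consumption individuals). Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
#' @examples
#' study <- simulate_study(seed = 1)
#' prof <- selectivity_profile(study$trials, study$controls)
#' tidy(prof)
#' glance(prof)
selectivity_profile <- function(trials, controls = NULL,
                                depletion_correction = TRUE) {
  cons <- if (is.null(controls)) {
    dplyr::mutate(validate_trials(trials),
                  n_missing = .data$n_offered - .data$n_surviving,
                  consumed = as.numeric(.data$n_missing))
  } else {
    control_correct(trials, controls)
  }
  m <- length(unique(cons$prey_id))
  indiv <- cons |>
    dplyr::group_by(.data$predator_stage_id, .data$replicate_id) |>
    dplyr::mutate(alpha = manly_alpha(.data$consumed, .data$n_offered,
                                      depletion_correction)) |>
    dplyr::ungroup() |>
    dplyr::mutate(electivity = electivity(.data$alpha, m))
  excluded <- indiv |>
    dplyr::filter(is.na(.data$alpha)) |>
    dplyr::distinct(.data$predator_stage_id, .data$replicate_id)
  kept <- dplyr::filter(indiv, !is.na(.data$alpha))
  se <- function(x) stats::sd(x) / sqrt(length(x))
  summary <- kept |>
    dplyr::group_by(.data$predator_stage_id, .data$prey_id) |>
    dplyr::summarise(
      n_individuals = dplyr::n(),
      mean_alpha = mean(.data$alpha),
      se_alpha = se(.data$alpha),
      mean_electivity = mean(.data$electivity),
      se_electivity = se(.data$electivity),
      total_consumed = sum(.data$consumed),
      .groups = "drop")
  breadth <- summary |>
    dplyr::group_by(.data$predator_stage_id) |>
    dplyr::summarise(diet_breadth = sum(.data$total_consumed > 0),
                     n_individuals = .data$n_individuals[1],
                     .groups = "drop")
  structure(
    list(individual = kept, summary = summary, breadth = breadth,
         m = m, excluded = excluded),
    class = "selectivity_profile")
}

#' @export
print.selectivity_profile <- function(x, ...) {
  cat("Selectivity profile:",
      length(unique(x$summary$predator_stage_id)), "predator stages x",
      x$m, "prey types;",
      nrow(x$excluded), "zero-consumption individual(s) excluded\n")
  print(x$summary, n = 10)
  invisible(x)
}

#' @describeIn selectivity_profile Species-level summary, one row per
#'   (predator stage, prey type).
#' @param x A `selectivity_profile`.
#' @param ... Unused.
#' @method tidy selectivity_profile
#' @export
tidy.selectivity_profile <- function(x, ...) x$summary

#' @describeIn selectivity_profile One row per predator stage with diet
#'   breadth and replicate count.
#' @method glance selectivity_profile
#' @export
glance.selectivity_profile <- function(x, ...) x$breadth

#' Diet breadth of each predator
#'
#' Number of prey types with species-level electivity above -1, i.e. prey
#' consumed at least once by the predator across its replicates.
#'
#' @param profile A [selectivity_profile()].
#' @return Tibble with `predator_stage_id` and `diet_breadth`.
#' @export
diet_breadth <- function(profile) {
  stopifnot(inherits(profile, "selectivity_profile"))
  profile$breadth[, c("predator_stage_id", "diet_breadth")]
}

safe_one_sample_t <- function(x, mu) {
  if (length(x) < 2) return(list(t = NA_real_, p = NA_real_, degenerate = TRUE))
  if (stats::sd(x) < 1e-12) {
    if (abs(mean(x) - mu) < 1e-9) {
      return(list(t = 0, p = 1, degenerate = TRUE))
    }
    return(list(t = sign(mean(x) - mu) * Inf, p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(x, mu = mu)
  list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
}

#' Test each predator's selectivity against unselective feeding
#'
#' For every predator stage with at least two informative individuals, the
#' per-individual alpha values for each prey are compared with the
#' no-selectivity value `1/m` by a two-sided one-sample t-test, and p-values
#' are Holm-adjusted across the `m` prey within the predator. Zero-variance
#' prey (all individuals identical) are flagged `degenerate`: p = 1 when the
#' common value equals `1/m`, p = 0 otherwise.
#'
#' @param profile A [selectivity_profile()].
#' @param alpha_level Significance level for the `significant` flag.
#' @return Tibble per (predator, prey): `statistic`, `p_value`,
#'   `p_holm`, `significant`, `degenerate`.
#' @export
#' @examples
#' study <- simulate_study(seed = 1)
#' test_no_selectivity(selectivity_profile(study$trials, study$controls))
test_no_selectivity <- function(profile, alpha_level = 0.05) {
  stopifnot(inherits(profile, "selectivity_profile"))
  m <- profile$m
  res <- profile$individual |>
    dplyr::group_by(.data$predator_stage_id, .data$prey_id) |>
    dplyr::summarise(fit = list(safe_one_sample_t(.data$alpha, 1 / m)),
                     .groups = "drop") |>
    tidyr::unnest_wider("fit") |>
    dplyr::rename(statistic = "t", p_value = "p")
  res |>
    dplyr::group_by(.data$predator_stage_id) |>
    dplyr::mutate(p_holm = stats::p.adjust(.data$p_value, method = "holm")) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$p_holm < alpha_level)
}

safe_two_sample_t <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2) {
    return(list(t = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12) {
    if (abs(mean(x) - mean(y)) < 1e-9) return(list(t = 0, p = 1, degenerate = TRUE))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
}

#' Ontogenetic diet-shift contrast between two stages of a predator
#'
#' Per prey type, a two-sample t-test of individual alpha values between a
#' later and an earlier developmental stage. The statistic is oriented so a
#' positive value means the prey is more preferred by the *later* stage.
#' Prey consumed by neither stage yield a missing result (`NA`), not a
#' number. The unequal-variance (Welch) form is the default; set
#' `var_equal = TRUE` for the pooled-variance test.
#'
#' @param profile A [selectivity_profile()] containing both stages.
#' @param later,earlier `predator_stage_id` of the later and earlier stage.
#' @param var_equal Use the pooled-variance t-test.
#' @return Tibble per prey: `statistic`, `p_value`, `consumed_by_either`.
#' @export
#' @examples
#' study <- simulate_study(seed = 1)
#' prof <- selectivity_profile(study$trials, study$controls)
#' compare_stages(prof, later = "Acilius(A)", earlier = "Acilius(L3)")
compare_stages <- function(profile, later, earlier, var_equal = FALSE) {
  stopifnot(inherits(profile, "selectivity_profile"))
  ind <- profile$individual
  for (s in c(later, earlier)) {
    if (!s %in% ind$predator_stage_id) abort(paste0("unknown stage: ", s))
  }
  prey <- sort(unique(ind$prey_id))
  purrr::map_dfr(prey, function(p) {
    a <- dplyr::filter(ind, .data$predator_stage_id == later, .data$prey_id == p)
    b <- dplyr::filter(ind, .data$predator_stage_id == earlier, .data$prey_id == p)
    eaten <- sum(a$consumed) + sum(b$consumed) > 0
    if (!eaten) {
      return(tibble(prey_id = p, statistic = NA_real_, p_value = NA_real_,
                    consumed_by_either = FALSE))
    }
    tt <- safe_two_sample_t(a$alpha, b$alpha, var_equal)
    tibble(prey_id = p, statistic = tt$t, p_value = tt$p,
           consumed_by_either = TRUE)
  })
}
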