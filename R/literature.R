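#' Binary most-preferred scoring of published experiments
#'
#' Pools published multiple-choice experiments and scores each prey taxon in
#' each experiment on a binary scale: 1 if it was (one of) the most
#' preferred prey in that experiment, 0 otherwise. Experiments whose offered
#' prey all belong to a single order carry no information about between-
#' order preference and are excluded. Ties are allowed: every taxon reported
#' as most preferred in an experiment scores 1, which inflates that
#' experiment's total score but keeps the per-taxon denominators honest.
#'
#' @param records Literature table (see [read_literature()]), one row per
#'   (experiment, offered prey taxon). If a `prey_order` column is present
#'   it drives the single-order exclusion; otherwise `prey_taxon` is used.
#' @return Object of class `preference_scores`: list with `scores` (one row
#'   per experiment and taxon: `score`), `taxa` (per taxon: `n_offered`,
#'   `n_preferred`, `proportion`), `n_experiments`, `n_excluded`. Has
#'   [tidy()] and [glance()] methods.
#' @export
score_preferences <- function(records) {
  records <- validate_literature(records)
  order_col <- if ("prey_order" %in% names(records)) "prey_order" else "prey_taxon"
  keep <- records |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::filter(dplyr::n_distinct(.data[[order_col]]) >= 2) |>
    dplyr::ungroup()
  n_excluded <- length(unique(records$experiment_id)) -
    length(unique(keep$experiment_id))
  scores <- keep |>
    dplyr::transmute(experiment_id = .data$experiment_id,
                     prey_taxon = .data$prey_taxon,
                     score = as.integer(.data$most_preferred_flag))
  taxa <- scores |>
    dplyr::group_by(.data$prey_taxon) |>
    dplyr::summarise(n_offered = dplyr::n(),
                     n_preferred = sum(.data$score),
                     proportion = mean(.data$score),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$proportion))
  structure(list(scores = scores, taxa = taxa,
                 n_experiments = length(unique(scores$experiment_id)),
                 n_excluded = n_excluded),
            class = "preference_scores")
}

#' @export
print.preference_scores <- function(x, ...) {
  cat("Preference scores:", x$n_experiments, "experiments (",
      x$n_excluded, "single-order experiment(s) excluded )\n")
  print(x$taxa)
  invisible(x)
}

#' @describeIn score_preferences Per-experiment binary scores.
#' @param x A `preference_scores` object.
#' @param ... Unused.
#' @method tidy preference_scores
#' @export
tidy.preference_scores <- function(x, ...) x$scores

#' @describeIn score_preferences Per-taxon counts and proportions.
#' @method glance preference_scores
#' @export
glance.preference_scores <- function(x, ...) x$taxa

#' Experiment-by-taxon rank matrix and its sparsity
#'
#' Builds the incomplete-ranking matrix underlying formal rank-based
#' meta-analyses: one row per experiment, one column per taxon, holding the
#' within-experiment preference rank (`preference_rank` column if supplied,
#' else rank 1 for the most-preferred taxa and 2 for the rest) and `NA`
#' where a taxon was not offered. The attribute `empty_fraction` reports the
#' proportion of empty cells; rank-based methods need roughly half the cells
#' filled, so a sparse matrix (e.g. >80% empty, typical when most
#' experiments offer 2-3 prey out of dozens of taxa) rules them out and
#' motivates the binary scoring of [score_preferences()].
#'
#' @param records Literature table.
#' @return Numeric matrix with attribute `empty_fraction`.
#' @export
rank_matrix <- function(records) {
  records <- validate_literature(records)
  rk <- if ("preference_rank" %in% names(records)) {
    records$preference_rank
  } else {
    2L - as.integer(records$most_preferred_flag)
  }
  exps <- unique(records$experiment_id)
  taxa <- sort(unique(records$prey_taxon))
  mat <- matrix(NA_real_, length(exps), length(taxa),
                dimnames = list(as.character(exps), taxa))
  mat[cbind(match(records$experiment_id, exps),
            match(records$prey_taxon, taxa))] <- rk
  attr(mat, "empty_fraction") <- mean(is.na(mat))
  mat
}

#' Quasi-binomial GLM of most-preferred probability across taxa
#'
#' Models the binary most-preferred scores as a function of the prey-taxon
#' factor with a quasi-binomial GLM, reports the analysis-of-deviance F test
#' for the factor, and performs post-hoc pairwise comparisons of taxa.
#' The default adjustment is the single-step max-modulus method on the Wald
#' statistics (Tukey-type contrasts for GLMs); `adjust = "holm"` is the
#' step-down fallback.
#'
#' @param scores A [score_preferences()] object.
#' @param min_experiments Keep only taxa offered in at least this many
#'   experiments (default 1 = all taxa).
#' @param adjust `"single-step"` or `"holm"` for the pairwise contrasts.
#' @return Object of class `preference_glm`: list with `fit`, `F_statistic`,
#'   `df1`, `df2`, `p_value`, `dispersion`, `contrasts` (tibble of pairwise
#'   z tests with adjusted p), and `groups` (compact letter display per
#'   taxon). Has [tidy()] and [glance()] methods.
#' @export
preference_glm <- function(scores, min_experiments = 1,
                           adjust = c("single-step", "holm")) {
  stopifnot(inherits(scores, "preference_scores"))
  adjust <- match.arg(adjust)
  keep_taxa <- scores$taxa$prey_taxon[scores$taxa$n_offered >= min_experiments]
  if (length(keep_taxa) < 2) abort("need at least 2 taxa to compare")
  d <- dplyr::filter(scores$scores, .data$prey_taxon %in% keep_taxa)
  d$prey_taxon <- factor(d$prey_taxon)
  fit <- stats::glm(score ~ prey_taxon, family = stats::quasibinomial(),
                    data = d)
  av <- stats::anova(fit, test = "F")
  mc <- multcomp::glht(fit, linfct = multcomp::mcp(prey_taxon = "Tukey"))
  ms <- summary(mc, test = multcomp::adjusted(
    type = if (adjust == "single-step") "single-step" else "holm"))
  contrasts <- tibble(
    contrast = names(ms$test$coefficients),
    estimate = unname(ms$test$coefficients),
    std_error = unname(ms$test$sigma),
    statistic = unname(ms$test$tstat),
    p_adjusted = unname(as.numeric(ms$test$pvalues)))
  letters <- tryCatch(multcomp::cld(ms)$mcletters$Letters,
                      error = function(e) NULL)
  groups <- if (is.null(letters)) {
    tibble(prey_taxon = levels(d$prey_taxon), group = NA_character_)
  } else {
    tibble(prey_taxon = names(letters), group = unname(letters))
  }
  structure(
    list(fit = fit, F_statistic = av$F[2], df1 = av$Df[2],
         df2 = av$`Resid. Df`[2], p_value = av$`Pr(>F)`[2],
         dispersion = summary(fit)$dispersion,
         contrasts = contrasts, groups = groups),
    class = "preference_glm")
}

#' @export
print.preference_glm <- function(x, ...) {
  cat("Taxon preference GLM (quasi-binomial): F(", x$df1, ",", x$df2,
      ") = ", round(x$F_statistic, 2), ", p = ", signif(x$p_value, 3),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn preference_glm Pairwise contrasts with adjusted p-values.
#' @param x A `preference_glm` object.
#' @param ... Unused.
#' @method tidy preference_glm
#' @export
tidy.preference_glm <- function(x, ...) x$contrasts

#' @describeIn preference_glm One-row model summary.
#' @method glance preference_glm
#' @export
glance.preference_glm <- function(x, ...) {
  tibble(F_statistic = x$F_statistic, df1 = x$df1, df2 = x$df2,
         p_value = x$p_value, dispersion = x$dispersion)
}

#' Cross-tabulate predator and preferred-prey microhabitats
#'
#' Counts experiments with a clear microhabitat outcome: all most-preferred
#' prey from one microhabitat and at least one non-preferred prey from the
#' other. Experiments with no preference, mixed-microhabitat preference, or
#' prey from a single microhabitat are uninformative and dropped.
#'
#' @param records Literature table with `predator_microhabitat` and
#'   `prey_microhabitat` columns (values `"benthic"` / `"water_column"`).
#' @return A 2x2 integer matrix, predator microhabitat in rows, preferred-
#'   prey microhabitat in columns.
#' @export
microhabitat_table <- function(records) {
  records <- validate_literature(records)
  habs <- c("benthic", "water_column")
  tab <- matrix(0L, 2, 2, dimnames = list(predator = habs, preferred_prey = habs))
  for (d in split(records, records$experiment_id)) {
    pref <- d[d$most_preferred_flag == 1, ]
    if (nrow(pref) == 0) next
    ph <- unique(pref$prey_microhabitat)
    if (length(ph) != 1 || !ph %in% habs) next
    other <- setdiff(habs, ph)
    nonpref <- d[d$most_preferred_flag == 0, ]
    if (!any(nonpref$prey_microhabitat == other)) next
    pred <- unique(d$predator_microhabitat)[1]
    if (!pred %in% habs) next
    tab[pred, ph] <- tab[pred, ph] + 1L
  }
  tab
}

#' One-tailed Fisher exact test of microhabitat association
#'
#' Tests whether predators preferentially select prey from their own
#' foraging microhabitat: a one-tailed Fisher exact test (hypergeometric
#' tail probability) of the 2x2 table of predator microhabitat against
#' preferred-prey microhabitat, with the alternative of positive
#' same-microhabitat association (diagonal excess).
#'
#' @param x A 2x2 count matrix (as from [microhabitat_table()]) or a
#'   literature table from which one is built.
#' @return Tibble with `p_value`, `odds_ratio` and the four cell counts.
#' @export
#' @examples
#' microhabitat_fisher(matrix(c(10, 1, 4, 3), 2, 2))
microhabitat_fisher <- function(x) {
  tab <- if (is.matrix(x)) x else microhabitat_table(x)
  if (!all(dim(tab) == c(2, 2))) abort("need a 2x2 table")
  if (any(tab < 0)) abort("cell counts must be non-negative")
  ft <- stats::fisher.test(tab, alternative = "greater")
  tibble(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
         n11 = tab[1, 1], n12 = tab[1, 2], n21 = tab[2, 1], n22 = tab[2, 2])
}
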