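#' Run the full selectivity analysis on a study
#'
#' Orchestrates the whole pipeline in the natural order: selectivity
#' profiles and no-selectivity tests, diet overlaps, predator dissimilarity
#' clustering and ordination, prey mortality, predation-pressure overlaps
#' with their clustering and ordination, food-web module detection under
#' both interaction-strength measures, and (when a literature table is
#' supplied) the meta-analytic scoring, taxon GLM and microhabitat Fisher
#' test.
#'
#' @param trials Trial table.
#' @param controls Control summary (or `NULL`).
#' @param literature Optional literature table; when `NULL` the literature
#'   stage is skipped with a notice.
#' @param seed Integer seed driving NMDS restarts and module detection.
#' @param restarts Restarts for module detection and NMDS.
#' @param predator_groups,prey_groups Numbers of groups cut from the two
#'   cluster trees.
#' @return A named list (`study_analysis`) with components `profile`,
#'   `selectivity_tests`, `diet_overlap`, `predator_tree`,
#'   `predator_groups`, `predator_nmds`, `mortality`, `vulnerability_glm`,
#'   `predation_overlap`, `prey_tree`, `prey_groups`, `prey_nmds`,
#'   `modules_alpha`, `modules_mortality`, and (optionally) `literature`
#'   (list with `scores`, `glm`, `fisher`).
#' @export
#' @examples
#' study <- simulate_study(seed = 7)
#' res <- run_study_analysis(study$trials, study$controls,
#'                           seed = 7, restarts = 10)
#' glance(res$modules_alpha)
run_study_analysis <- function(trials, controls = NULL, literature = NULL,
                               seed = 1, restarts = 50,
                               predator_groups = 4, prey_groups = 3) {
  profile <- selectivity_profile(trials, controls)
  tests <- test_no_selectivity(profile)
  O <- diet_overlap(profile)
  ptree <- ward_cluster(dissimilarity(O))
  pgroups <- cut_groups(ptree, predator_groups)
  pnmds <- nmds_ordination(dissimilarity(O), restarts = max(restarts, 10),
                           seed = seed)
  mort <- mortality_table(trials, controls)
  vglm <- vulnerability_glm(trials, controls)
  P <- predation_pressure_overlap(mort)
  ytree <- ward_cluster(dissimilarity(P))
  ygroups <- cut_groups(ytree, prey_groups)
  ynmds <- nmds_ordination(dissimilarity(P), restarts = max(restarts, 10),
                           seed = seed + 1)
  alpha_web <- scale_weights(alpha_matrix(profile), measure = "manly_alpha")
  mort_web <- scale_weights(t(mortality_matrix(mort)), measure = "mortality")
  mod_a <- find_modules(alpha_web, restarts = restarts, seed = seed + 2)
  mod_m <- find_modules(mort_web, restarts = restarts, seed = seed + 3)
  out <- list(profile = profile, selectivity_tests = tests,
              diet_overlap = O, predator_tree = ptree,
              predator_groups = pgroups, predator_nmds = pnmds,
              mortality = mort, vulnerability_glm = vglm,
              predation_overlap = P, prey_tree = ytree,
              prey_groups = ygroups, prey_nmds = ynmds,
              modules_alpha = mod_a, modules_mortality = mod_m)
  if (is.null(literature)) {
    inform("no literature table supplied; literature synthesis skipped")
  } else {
    scores <- score_preferences(literature)
    out$literature <- list(
      scores = scores,
      glm = preference_glm(scores),
      fisher = microhabitat_fisher(literature))
  }
  structure(out, class = "study_analysis")
}

#' @export
print.study_analysis <- function(x, ...) {
  cat("Study analysis bundle\n")
  cat(" -", length(unique(x$profile$summary$predator_stage_id)),
      "predator stages,", x$profile$m, "prey types\n")
  cat(" - modules (alpha weights):", x$modules_alpha$n_modules,
      "| Q =", round(x$modules_alpha$Q, 3), "\n")
  cat(" - NMDS stress (predators):", round(x$predator_nmds$stress, 2), "\n")
  if (!is.null(x$literature)) {
    cat(" - literature: F =", round(x$literature$glm$F_statistic, 2),
        ", Fisher p =", round(x$literature$fisher$p_value, 3), "\n")
  }
  invisible(x)
}

#' Predator-by-prey matrix of mean selectivity
#'
#' @param profile A [selectivity_profile()].
#' @return Numeric matrix of species-mean alpha, predators in rows.
#' @export
alpha_matrix <- function(profile) {
  stopifnot(inherits(profile, "selectivity_profile"))
  wide <- tidyr::pivot_wider(
    profile$summary[, c("predator_stage_id", "prey_id", "mean_alpha")],
    names_from = "prey_id", values_from = "mean_alpha")
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$predator_stage_id
  mat
}

#' Write a study-analysis bundle to disk
#'
#' Writes TSV matrices (overlaps, dissimilarities, selectivity summary,
#' mortality), Newick dendrograms, ordination coordinates, and a JSON
#' results bundle (module partitions, GLM results, stress values, seeds).
#'
#' @param res A `study_analysis` from [run_study_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(res, dir) {
  stopifnot(inherits(res, "study_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  readr::write_tsv(tidy(res$profile), p("selectivity.tsv"))
  readr::write_tsv(res$selectivity_tests, p("selectivity_tests.tsv"))
  readr::write_tsv(glance(res$profile), p("breadth.tsv"))
  write_matrix_tsv(unclass(res$diet_overlap), p("overlap_diet.tsv"))
  write_matrix_tsv(unclass(res$predation_overlap), p("overlap_pressure.tsv"))
  readr::write_tsv(tidy(res$mortality), p("mortality.tsv"))
  readr::write_tsv(res$vulnerability_glm, p("vulnerability_glm.tsv"))
  cluster_newick(res$predator_tree, p("predator_dendrogram.nwk"))
  cluster_newick(res$prey_tree, p("prey_dendrogram.nwk"))
  readr::write_tsv(tidy(res$predator_nmds), p("predator_nmds.tsv"))
  readr::write_tsv(tidy(res$prey_nmds), p("prey_nmds.tsv"))
  readr::write_tsv(tidy(res$modules_alpha), p("modules_alpha.tsv"))
  readr::write_tsv(tidy(res$modules_mortality), p("modules_mortality.tsv"))
  bundle <- list(
    modules_alpha = list(Q = res$modules_alpha$Q,
                         n_modules = res$modules_alpha$n_modules,
                         seed = res$modules_alpha$seed),
    modules_mortality = list(Q = res$modules_mortality$Q,
                             n_modules = res$modules_mortality$n_modules,
                             seed = res$modules_mortality$seed),
    nmds = list(predator_stress = res$predator_nmds$stress,
                prey_stress = res$prey_nmds$stress))
  if (!is.null(res$literature)) {
    bundle$literature <- list(
      F_statistic = res$literature$glm$F_statistic,
      p_value = res$literature$glm$p_value,
      fisher_p = res$literature$fisher$p_value)
    readr::write_tsv(glance(res$literature$scores), p("preference_scores.tsv"))
  }
  jsonlite::write_json(bundle, p("results.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
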