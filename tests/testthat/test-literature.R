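lit_row <- function(exp_id, taxon, order, hab, pref, pred_hab = "benthic") {
  tibble::tibble(
    study_id = "s1", experiment_id = exp_id, predator_taxon = "Dytiscus",
    predator_stage = "A", predator_microhabitat = pred_hab,
    prey_taxon = taxon, prey_order = order, prey_microhabitat = hab,
    most_preferred_flag = pref, habitat_structure = FALSE,
    multiple_choice = TRUE)
}

test_that("single-order experiments are excluded from preference scoring", {
  recs <- dplyr::bind_rows(
    lit_row("e1", "Daphnia", "Cladocera", "water_column", 1),
    lit_row("e1", "Bosmina", "Cladocera", "water_column", 0),   # single order
    lit_row("e2", "Daphnia", "Cladocera", "water_column", 1),
    lit_row("e2", "Chironomidae", "Diptera", "benthic", 0))
  sc <- score_preferences(recs)
  expect_equal(sc$n_excluded, 1)
  expect_equal(sc$n_experiments, 1)
  expect_equal(sc$taxa$n_offered[sc$taxa$prey_taxon == "Daphnia"], 1)
})

test_that("ties and unselective experiments are scored faithfully", {
  recs <- dplyr::bind_rows(
    lit_row("e1", "Daphnia", "Cladocera", "water_column", 1),
    lit_row("e1", "Culicidae", "Diptera", "water_column", 1),  # tie
    lit_row("e1", "Ephemeroptera", "Ephemeroptera", "benthic", 0),
    lit_row("e2", "Daphnia", "Cladocera", "water_column", 0),  # no selectivity
    lit_row("e2", "Culicidae", "Diptera", "water_column", 0))
  sc <- score_preferences(recs)
  per_exp <- dplyr::count(tidy(sc), experiment_id, wt = score)
  expect_equal(per_exp$n[per_exp$experiment_id == "e1"], 2)
  expect_equal(per_exp$n[per_exp$experiment_id == "e2"], 0)
  # scoring is order-independent and idempotent
  sc2 <- score_preferences(recs[sample(nrow(recs)), ])
  expect_equal(dplyr::arrange(sc$taxa, prey_taxon),
               dplyr::arrange(sc2$taxa, prey_taxon))
})

test_that("rank matrix mirrors offerings and reports sparsity", {
  sim <- simulate_literature(n_experiments = 40, seed = 6)
  rm <- rank_matrix(sim$records)
  expect_equal(nrow(rm), 40)
  expect_equal(sum(!is.na(rm)), nrow(sim$records))
  expect_equal(attr(rm, "empty_fraction"), mean(is.na(rm)))
  # mostly 2-6 prey offered out of 10 taxa -> well over half the cells empty
  expect_gt(attr(rm, "empty_fraction"), 0.5)
})

test_that("taxa with identical preference proportions are not separated", {
  recs <- purrr::map_dfr(1:12, function(i) dplyr::bind_rows(
    lit_row(paste0("e", i), "A_tax", "OrdA", "benthic", as.integer(i %% 2 == 0)),
    lit_row(paste0("e", i), "B_tax", "OrdB", "water_column",
            as.integer(i %% 2 == 1))))
  fit <- preference_glm(score_preferences(recs))
  expect_gt(fit$contrasts$p_adjusted[1], 0.9)
  expect_lt(fit$F_statistic, 1e-6)
})

test_that("preference GLM recovers a planted taxon ordering", {
  set.seed(14)
  hits <- 0
  for (run in 1:10) {
    eff <- tibble::tibble(
      prey_taxon = c("strong", "weak1", "weak2"),
      prey_order = c("O1", "O2", "O3"),
      prey_microhabitat = c("benthic", "benthic", "water_column"),
      effect = c(2.5, -0.5, -0.5))
    sim <- simulate_literature(60, effects = eff, prey_range = 3,
                               seed = run * 100 + 7)
    sc <- score_preferences(sim$records)
    top <- sc$taxa$prey_taxon[which.max(sc$taxa$proportion)]
    fit <- preference_glm(sc)
    sig <- fit$contrasts$p_adjusted[grepl("strong", fit$contrasts$contrast)]
    if (top == "strong" && all(sig < 0.05)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("one-tailed Fisher p equals exhaustive hypergeometric enumeration", {
  tab <- matrix(c(10, 1, 4, 3), 2, 2)
  res <- microhabitat_fisher(tab)
  expect_equal(res$p_value, enumerate_fisher_greater(tab))
  expect_equal(res$p_value, 420 / 3060)
  # random tables against the enumeration oracle
  set.seed(9)
  for (i in 1:25) {
    t2 <- matrix(rpois(4, 4), 2, 2)
    expect_equal(microhabitat_fisher(t2)$p_value,
                 enumerate_fisher_greater(t2), tolerance = 1e-12)
  }
  # perfectly diagonal table: minimal tail 1 / choose(a+d, a)
  for (ad in list(c(3, 2), c(5, 5), c(1, 4))) {
    t3 <- diag(ad)
    expect_equal(microhabitat_fisher(t3)$p_value,
                 1 / choose(sum(ad), ad[1]))
  }
  # association in the opposite direction -> p of 1 (or nearly so)
  expect_equal(microhabitat_fisher(matrix(c(0, 5, 5, 0), 2, 2))$p_value, 1)
  expect_error(microhabitat_fisher(matrix(c(-1, 1, 1, 1), 2, 2)))
})

test_that("microhabitat table keeps only experiments with a clear outcome", {
  recs <- dplyr::bind_rows(
    # clear: benthic predator prefers benthic prey, water-column alternative
    lit_row("e1", "Chironomidae", "Diptera", "benthic", 1, "benthic"),
    lit_row("e1", "Daphnia", "Cladocera", "water_column", 0, "benthic"),
    # no preference -> dropped
    lit_row("e2", "Chironomidae", "Diptera", "benthic", 0, "benthic"),
    lit_row("e2", "Daphnia", "Cladocera", "water_column", 0, "benthic"),
    # single microhabitat on offer -> dropped
    lit_row("e3", "Chironomidae", "Diptera", "benthic", 1, "benthic"),
    lit_row("e3", "Ephemeroptera", "Ephemeroptera", "benthic", 0, "benthic"),
    # mixed-microhabitat preference -> dropped
    lit_row("e4", "Chironomidae", "Diptera", "benthic", 1, "water_column"),
    lit_row("e4", "Daphnia", "Cladocera", "water_column", 1, "water_column"),
    # clear: water-column predator prefers water-column prey
    lit_row("e5", "Daphnia", "Cladocera", "water_column", 1, "water_column"),
    lit_row("e5", "Chironomidae", "Diptera", "benthic", 0, "water_column"))
  tab <- microhabitat_table(recs)
  expect_equal(sum(tab), 2)
  expect_equal(tab["benthic", "benthic"], 1L)
  expect_equal(tab["water_column", "water_column"], 1L)
})
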