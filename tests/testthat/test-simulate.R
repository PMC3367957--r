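test_that("study simulation is deterministic under a fixed seed", {
  s1 <- simulate_study(seed = 123)
  s2 <- simulate_study(seed = 123)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$controls, s2$controls)
  s3 <- simulate_study(seed = 124)
  expect_false(identical(s1$trials, s3$trials))
})

test_that("the default study has the reference shape", {
  study <- simulate_study(seed = 1)
  counts <- dplyr::count(dplyr::distinct(study$trials, predator_stage_id,
                                         replicate_id), predator_stage_id)
  roster <- default_predator_roster()
  expect_equal(counts$n[match(roster$predator_stage_id, counts$predator_stage_id)],
               roster$n_replicates)
  expect_true(all(dplyr::count(study$trials, predator_stage_id,
                               replicate_id)$n == 7))
  expect_equal(sort(unique(study$trials$prey_id)),
               sort(default_prey_roster()$prey_id))
  # offers follow the fixed unequal design
  offers <- dplyr::distinct(study$trials, prey_id, n_offered)
  expect_equal(offers$n_offered[match(c("Rana", "Lymnaea", "Daphnia"), offers$prey_id)],
               c(6L, 6L, 30L))
})

test_that("sequential capture is marginally Manly-Chesson: uniform weights", {
  # equal attack weights: estimated alpha should sit at 1/m for every prey
  prey <- default_prey_roster()
  prey$control_mortality <- 0
  preds <- default_predator_roster()[1, ]
  preds$n_replicates <- 400L
  w <- matrix(1, 1, 7, dimnames = list(preds$predator_stage_id, prey$prey_id))
  cfg <- generator_config(prey = prey, predators = preds, attack_weights = w,
                          budget_mean = setNames(6, preds$predator_stage_id),
                          budget_distribution = "fixed")
  study <- simulate_study(cfg, seed = 77)
  prof <- selectivity_profile(study$trials)
  s <- prof$summary
  expect_true(all(abs(s$mean_alpha - 1 / 7) <= 3 * s$se_alpha))
})

test_that("a zero budget yields no consumption and exclusion downstream", {
  cfg <- generator_config(budget_mean = setNames(
    rep(0, 13), default_predator_roster()$predator_stage_id),
    budget_distribution = "fixed")
  prey0 <- default_prey_roster(); prey0$control_mortality <- 0
  cfg <- generator_config(prey = prey0,
                          budget_mean = cfg$budget_mean,
                          budget_distribution = "fixed")
  set.seed(1)
  tr <- simulate_trial(cfg, "Anax(F-0)")
  expect_equal(tr$n_surviving, tr$n_offered)
  study <- simulate_study(cfg, seed = 2)
  prof <- selectivity_profile(study$trials)
  expect_equal(nrow(prof$summary), 0)
  expect_gt(nrow(prof$excluded), 0)
})

test_that("a concentrated weight with a large budget exercises depletion", {
  prey <- default_prey_roster(); prey$control_mortality <- 0
  preds <- default_predator_roster()[1, ]; preds$n_replicates <- 10L
  w <- matrix(c(0.01, 50, 0.01, 0.01, 0.01, 0.01, 0.01), 1, 7,
              dimnames = list(preds$predator_stage_id, prey$prey_id))
  cfg <- generator_config(prey = prey, predators = preds, attack_weights = w,
                          budget_mean = setNames(15, preds$predator_stage_id),
                          budget_distribution = "fixed")
  study <- simulate_study(cfg, seed = 5)
  chir <- dplyr::filter(study$trials, prey_id == "Chironomus")
  expect_true(all(chir$n_surviving == 0))  # depleted every replicate
  prof <- selectivity_profile(study$trials)
  a <- prof$summary
  expect_true(all(abs(1 - vapply(
    split(prof$individual$alpha,
          paste(prof$individual$predator_stage_id, prof$individual$replicate_id)),
    sum, numeric(1))) < 1e-9))
  # the +1 correction keeps the depleted prey's alpha strictly below 1
  expect_lt(max(prof$individual$alpha), 1)
})

test_that("budgets beyond the total offer are truncated and flagged", {
  prey <- default_prey_roster()[1:3, ]; prey$control_mortality <- 0
  preds <- default_predator_roster()[1, ]
  w <- matrix(1, 1, 3, dimnames = list(preds$predator_stage_id, prey$prey_id))
  cfg <- generator_config(prey = prey, predators = preds, attack_weights = w,
                          budget_mean = setNames(1000, preds$predator_stage_id),
                          budget_distribution = "fixed")
  set.seed(3)
  tr <- simulate_trial(cfg, preds$predator_stage_id)
  expect_true(attr(tr, "truncated"))
  expect_equal(sum(tr$n_surviving), 0)
})

test_that("simulated literature honours its contracts", {
  sim <- simulate_literature(30, seed = 9)
  expect_equal(length(unique(sim$records$experiment_id)), 30)
  per_exp <- dplyr::count(sim$records, experiment_id, wt = most_preferred_flag)
  expect_true(all(per_exp$n == 1))  # exactly one winner per experiment
  expect_identical(sim$records,
                   simulate_literature(30, seed = 9)$records)
  expect_error(simulate_literature(0), "at least 1")
})

test_that("null taxon effects produce near-nominal type-I error", {
  set.seed(25)
  eff <- default_taxon_effects()
  eff$effect <- 0
  rejections <- 0
  for (run in 1:15) {
    sim <- simulate_literature(60, effects = eff, seed = 5000 + run)
    fit <- suppressWarnings(preference_glm(score_preferences(sim$records)))
    if (!is.na(fit$p_value) && fit$p_value < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections, 3)  # ~0.75 expected at the nominal level
})

test_that("a strongly preferred taxon dominates the simulated literature", {
  eff <- default_taxon_effects()
  eff$effect <- ifelse(eff$prey_taxon == "Cladocera", 3, -1)
  sim <- simulate_literature(80, effects = eff, seed = 44)
  sc <- score_preferences(sim$records)
  expect_equal(sc$taxa$prey_taxon[which.max(sc$taxa$proportion)], "Cladocera")
  expect_gt(sc$taxa$proportion[sc$taxa$prey_taxon == "Cladocera"], 0.5)
})
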