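test_that("Manly-Chesson alpha matches hand-computed ratios", {
  # (5/10, 2/10, 3/30) / 0.8
  expect_equal(manly_alpha(c(5, 2, 3), c(10, 10, 30)),
               c(0.625, 0.25, 0.125))
  # equal proportional consumption -> 1/m
  expect_equal(manly_alpha(c(2, 2, 6), c(10, 10, 30)), rep(1 / 3, 3))
  # single prey consumed
  expect_equal(manly_alpha(c(0, 4, 0), c(10, 10, 30)), c(0, 1, 0))
  # nothing consumed -> undefined
  expect_true(all(is.na(manly_alpha(c(0, 0), c(10, 10)))))
  expect_error(manly_alpha(c(11, 0), c(10, 10)), class = "preysel_validation_error")
})

test_that("depletion correction inflates fully consumed prey by one", {
  # ratios (10/11, 3/10)
  a <- manly_alpha(c(10, 3), c(10, 10))
  expect_equal(a, c(10 / 11, 3 / 10) / (10 / 11 + 3 / 10))
  # both depleted: both inflated, still sums to 1
  b <- manly_alpha(c(10, 10), c(10, 10))
  expect_equal(b, c(0.5, 0.5))
  expect_equal(sum(b), 1)
  # no depleted prey: identity with uncorrected form
  expect_equal(manly_alpha(c(5, 2), c(10, 10)),
               manly_alpha(c(5, 2), c(10, 10), depletion_correction = FALSE))
  # conservative: corrected alpha for the depleted prey is below the
  # uncorrected limit whenever another prey was eaten
  expect_lt(manly_alpha(c(10, 3), c(10, 10))[1],
            manly_alpha(c(10, 3), c(10, 10), depletion_correction = FALSE)[1])
})

test_that("alpha vectors always normalise to one", {
  set.seed(42)
  for (i in 1:50) {
    n0 <- sample(c(6L, 10L, 30L), 5, replace = TRUE)
    r <- vapply(n0, function(n) sample(0:n, 1), integer(1))
    if (sum(r) == 0) r[1] <- 1L
    expect_equal(sum(manly_alpha(r, n0)), 1, tolerance = 1e-9)
  }
})

test_that("electivity hits its anchors and is monotone in alpha", {
  m <- 7
  expect_equal(electivity(1 / m, m), 0)
  expect_equal(electivity(0, m), -1)
  expect_equal(electivity(1, m), 1)
  expect_equal(electivity(0.5, m), 2.5 / 3.5)
  a <- seq(0, 1, by = 0.01)
  expect_true(all(diff(electivity(a, m)) > 0))
  expect_true(all(electivity(a, 3) >= -1 & electivity(a, 3) <= 1))
  expect_error(electivity(0.5, 2))
})

test_that("control correction subtracts mean control deaths and clamps at zero", {
  trials <- tibble::tibble(
    predator_stage_id = "p", replicate_id = 1L,
    prey_id = c("Chironomus", "Cloeon", "Asellus"),
    n_offered = c(10L, 10L, 10L),
    n_surviving = c(5L, 10L, 4L))
  controls <- tibble::tibble(
    prey_id = c("Chironomus", "Cloeon", "Asellus"),
    mean_dead = c(1.17, 0.33, 0), n_control_trials = 4L)
  out <- control_correct(trials, controls)
  expect_equal(out$consumed[out$prey_id == "Chironomus"], 5 - 1.17)
  expect_equal(out$consumed[out$prey_id == "Cloeon"], 0)   # clamped
  expect_equal(out$consumed[out$prey_id == "Asellus"], 6)  # untouched
  expect_error(control_correct(trials, controls[-1, ]),
               class = "preysel_validation_error")
})

test_that("diet breadth counts prey consumed at all", {
  trials <- tidyr::crossing(
    predator_stage_id = "p", replicate_id = 1:3,
    tibble::tibble(prey_id = letters[1:7], n_offered = 10L))
  trials$n_surviving <- 10L
  trials$n_surviving[trials$prey_id %in% c("a", "b", "c", "d")] <- 6L
  prof <- selectivity_profile(trials)
  expect_equal(diet_breadth(prof)$diet_breadth, 4)
  # every prey eaten -> m; none eaten -> profile has no informative individuals
  trials$n_surviving <- 5L
  expect_equal(diet_breadth(selectivity_profile(trials))$diet_breadth, 7)
})

test_that("zero-consumption individuals are excluded, not propagated", {
  trials <- tidyr::crossing(
    predator_stage_id = "p", replicate_id = 1:3,
    tibble::tibble(prey_id = c("a", "b", "c"), n_offered = 10L))
  trials$n_surviving <- ifelse(trials$replicate_id == 2L, 10L, 5L)
  prof <- selectivity_profile(trials)
  expect_equal(nrow(prof$excluded), 1)
  expect_equal(unique(prof$summary$n_individuals), 2L)
  expect_false(any(is.na(prof$summary$mean_alpha)))
})

test_that("no-selectivity t-tests follow the Holm step-down within predator", {
  set.seed(7)
  trials <- tidyr::crossing(
    predator_stage_id = "p", replicate_id = 1:8,
    tibble::tibble(prey_id = sprintf("prey%d", 1:7),
                   n_offered = c(10L, 10L, 10L, 10L, 30L, 6L, 6L)))
  trials$n_surviving <- vapply(seq_len(nrow(trials)), function(i) {
    n <- trials$n_offered[i]
    pref <- if (trials$prey_id[i] == "prey1") 0.7 else 0.15
    n - rbinom(1, n, pref)
  }, integer(1))
  prof <- selectivity_profile(trials)
  res <- test_no_selectivity(prof)
  expect_equal(nrow(res), 7)
  # Holm never lowers a p-value and is monotone in the raw ordering
  expect_true(all(res$p_holm >= res$p_value - 1e-15))
  ord <- order(res$p_value)
  expect_true(all(diff(res$p_holm[ord]) >= -1e-15))
  # hand-checked Holm mapping on the raw p-values
  expect_equal(res$p_holm, p.adjust(res$p_value, "holm"))
})

test_that("uniform alpha across individuals is never called selective", {
  trials <- tidyr::crossing(
    predator_stage_id = "p", replicate_id = 1:5,
    tibble::tibble(prey_id = c("a", "b", "c"), n_offered = 10L))
  trials$n_surviving <- 8L  # identical proportional consumption -> alpha = 1/3
  res <- test_no_selectivity(selectivity_profile(trials))
  expect_true(all(res$p_holm == 1))
  expect_true(all(res$degenerate))
  expect_false(any(res$significant))
})

test_that("stage contrasts are oriented later-minus-earlier and flag missing prey", {
  base <- tidyr::crossing(
    replicate_id = 1:6,
    tibble::tibble(prey_id = c("a", "b", "c"), n_offered = 10L))
  set.seed(11)
  early <- dplyr::mutate(base, predator_stage_id = "early",
                         n_surviving = ifelse(prey_id == "a", 3L, 9L) -
                           sample(0:1, dplyr::n(), TRUE))
  late <- dplyr::mutate(base, predator_stage_id = "late",
                        n_surviving = ifelse(prey_id == "b", 3L, 9L) -
                          sample(0:1, dplyr::n(), TRUE))
  prof <- selectivity_profile(dplyr::bind_rows(early, late))
  res <- compare_stages(prof, later = "late", earlier = "early")
  expect_gt(res$statistic[res$prey_id == "b"], 0)  # later stage prefers b
  expect_lt(res$statistic[res$prey_id == "a"], 0)  # earlier stage preferred a
  # identical samples -> t = 0, p = 1
  both <- dplyr::bind_rows(
    dplyr::mutate(early, predator_stage_id = "s1"),
    dplyr::mutate(early, predator_stage_id = "s2"))
  res2 <- compare_stages(selectivity_profile(both), "s2", "s1")
  expect_true(all(abs(res2$statistic) < 1e-9))
  expect_true(all(res2$p_value == 1))
  # prey eaten by neither stage -> missing marker
  neither <- dplyr::bind_rows(early, late)
  neither$n_surviving[neither$prey_id == "c"] <- 10L
  res3 <- compare_stages(selectivity_profile(neither), "late", "early")
  expect_true(is.na(res3$statistic[res3$prey_id == "c"]))
  expect_false(res3$consumed_by_either[res3$prey_id == "c"])
})
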