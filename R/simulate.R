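#' Target per-trial mortality pattern behind the default attack weights
#'
#' A 13 x 7 matrix of expected proportions consumed per 24-h trial (rows:
#' predator stages, columns: prey types), encoding the selectivity
#' structure documented for pool food webs of this composition: medium
#' benthic predators concentrated on *Chironomus*; nektonic predators
#' (backswimmers, *Acilius* larvae, damselfly larvae) on *Culex*,
#' *Daphnia* and *Cloeon*; large benthic predators (*Dytiscus*,
#' *Ilyocoris*, *Anax*) heavily exploiting *Asellus*, *Chironomus* and
#' *Rana* tadpoles (*Dytiscus* larvae nearly depleting all three); and the
#' shelled *Lymnaea* nearly invulnerable, taken only by the two largest
#' predators at ~10%.
#'
#' @return Numeric matrix of proportions in `[0, 1)`.
#' @export
default_target_mortality <- function() {
  prey <- default_prey_roster()$prey_id
  m <- rbind(
    #                Asellus Chiron. Cloeon Culex Daphnia Lymnaea  Rana
    "Hydaticus(A)"    = c(.03, .65, .05, .15, .020, 0,   0),
    "Acilius(L2)"     = c(0,   .10, .10, .70, .083, 0,   0),
    "Acilius(L3)"     = c(0,   .15, .73, .70, .100, 0,   0),
    "Acilius(A)"      = c(.05, .75, .05, .15, .020, 0,   .13),
    "Dytiscus(L3)"    = c(.92, .85, .05, .05, .017, 0,   .995),
    "Dytiscus(A)"     = c(.50, .70, .05, .15, .033, .10, .10),
    "Ilyocoris(A)"    = c(.68, .60, .10, .30, 0,    0,   0),
    "Notonecta(A)"    = c(0,   .10, .10, .80, .050, 0,   0),
    "Coenagrion(F-0)" = c(0,   .10, .10, .60, .300, 0,   0),
    "Libellula(F-2)"  = c(.05, .65, .05, .30, .050, 0,   0),
    "Libellula(F-0)"  = c(.15, .65, .05, .60, .033, 0,   .05),
    "Sympetrum(F-0)"  = c(.10, .60, .05, .60, .050, 0,   .033),
    "Anax(F-0)"       = c(.25, .60, .20, .70, .100, .10, .54))
  colnames(m) <- prey
  m
}

#' Default ground-truth attack weights for the synthetic study
#'
#' Relative attack weights `w` derived from the target mortality pattern as
#' exponential depletion rates, `w = -log(1 - m)`: under a continuous-time
#' capture process at rate `w_i` per prey individual, a prey experiencing
#' rate `w_i` for one trial ends with expected mortality `m_i`. Each row is
#' scale-free (only ratios matter) and the row normalised to sum 1 is the
#' ground-truth Manly-Chesson selectivity the estimation pipeline should
#' recover in the absence of heavy depletion.
#'
#' @return Numeric matrix with dimnames matching [default_predator_roster()]
#'   and [default_prey_roster()].
#' @export
default_attack_weights <- function() {
  -log(1 - default_target_mortality())
}

#' Default per-stage feeding budgets (mean prey items per 24 h)
#'
#' Mean total consumption per trial for each predator stage: the row sums
#' of the target mortality pattern times the offers, rounded. Budgets scale
#' with predator body size; the large *Dytiscus* and *Anax* larvae consume
#' in the twenties, small adults and early instars around ten.
#'
#' @return Named integer vector over predator stages.
#' @export
default_budget_means <- function() {
  m <- default_target_mortality()
  n0 <- default_prey_roster()$n_offered_default
  round(drop(m %*% n0))
}

#' Configuration for the synthetic study generator
#'
#' Bundles the prey roster (offers, background mortality), predator roster
#' (replicate counts), ground-truth attack weights, and the feeding-budget
#' distribution. Defaults describe a 13-predator-stage x 7-prey study with
#' 5-9 replicates per stage, fixed unequal offers
#' (6/6/10/10/10/10/30), low background mortality, and over-dispersed
#' appetites (negative-binomial budgets).
#'
#' @param prey Prey roster (see [default_prey_roster()]).
#' @param predators Predator roster (see [default_predator_roster()]).
#' @param attack_weights Non-negative matrix of relative attack weights,
#'   predators x prey.
#' @param budget_mean Named vector of mean items consumed per trial.
#' @param budget_distribution `"nbinom"` (default), `"poisson"` or
#'   `"fixed"`.
#' @param budget_size Negative-binomial size (inverse over-dispersion).
#' @param n_control_trials Number of predator-free control trials.
#' @return A `generator_config` list.
#' @export
generator_config <- function(prey = default_prey_roster(),
                             predators = default_predator_roster(),
                             attack_weights = default_attack_weights(),
                             budget_mean = default_budget_means(),
                             budget_distribution = c("nbinom", "poisson", "fixed"),
                             budget_size = 8,
                             n_control_trials = 4L) {
  budget_distribution <- match.arg(budget_distribution)
  attack_weights <- as.matrix(attack_weights)
  stopifnot(
    all(predators$predator_stage_id %in% rownames(attack_weights)),
    all(prey$prey_id %in% colnames(attack_weights)),
    all(predators$predator_stage_id %in% names(budget_mean)))
  if (any(attack_weights < 0)) abort("attack weights must be non-negative")
  if (any(rowSums(attack_weights) <= 0)) {
    abort("each predator needs at least one positive attack weight")
  }
  if (any(prey$control_mortality < 0 | prey$control_mortality > 1)) {
    abort("control mortality rates must lie in [0, 1]")
  }
  structure(
    list(prey = prey, predators = predators,
         attack_weights = attack_weights[predators$predator_stage_id,
                                         prey$prey_id, drop = FALSE],
         budget_mean = budget_mean, budget_distribution = budget_distribution,
         budget_size = budget_size,
         n_control_trials = as.integer(n_control_trials)),
    class = "generator_config")
}

draw_budget <- function(config, stage) {
  mu <- config$budget_mean[[stage]]
  switch(config$budget_distribution,
         nbinom = stats::rnbinom(1, mu = mu, size = config$budget_size),
         poisson = stats::rpois(1, mu),
         fixed = round(mu))
}

#' Simulate one multiple-choice feeding trial
#'
#' Draws a total feeding budget `K` for the predator, then consumes `K` prey
#' sequentially without replacement: each capture picks prey type `i` with
#' probability proportional to `w_i * n_i(t)`, where `n_i(t)` is the number
#' of that prey still alive (a depletion-aware Manly-Chesson process, so the
#' selectivity index is the natural estimator of the normalised `w`).
#' Background mortality is then applied to the survivors as independent
#' binomial thinning with the prey-specific control rates. A budget
#' exceeding the prey still available is truncated (attribute `truncated`).
#'
#' @param config A [generator_config()].
#' @param predator_stage_id Stage to simulate.
#' @param replicate_id Replicate label for the output rows.
#' @return A long-format trial tibble (one row per prey type).
#' @export
#' @examples
#' set.seed(1)
#' simulate_trial(generator_config(), "Anax(F-0)")
simulate_trial <- function(config, predator_stage_id, replicate_id = 1L) {
  stopifnot(inherits(config, "generator_config"))
  if (!predator_stage_id %in% rownames(config$attack_weights)) {
    abort(paste0("unknown predator stage: ", predator_stage_id))
  }
  w <- config$attack_weights[predator_stage_id, ]
  n0 <- config$prey$n_offered_default
  names(n0) <- config$prey$prey_id
  alive <- n0
  k_drawn <- draw_budget(config, predator_stage_id)
  truncated <- FALSE
  eaten <- 0L
  while (eaten < k_drawn) {
    rate <- w * alive
    if (sum(rate) <= 0) { truncated <- TRUE; break }
    pick <- sample(names(alive), 1, prob = rate)
    alive[pick] <- alive[pick] - 1L
    eaten <- eaten + 1L
  }
  q <- config$prey$control_mortality
  background_dead <- stats::rbinom(length(alive), alive, q)
  out <- tibble(
    predator_stage_id = predator_stage_id,
    replicate_id = as.integer(replicate_id),
    prey_id = config$prey$prey_id,
    n_offered = as.integer(n0),
    n_surviving = as.integer(alive - background_dead))
  attr(out, "truncated") <- truncated
  out
}

#' Simulate a complete multiple-choice predation study
#'
#' Generates a full fixture with known ground truth: every predator stage
#' with its configured number of replicate trials, predator-free control
#' trials driven by the same background mortality rates, and the normalised
#' attack weights the selectivity pipeline should recover.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; the whole study is reproducible given the seed.
#' @return List with `trials` (long trial table), `controls` (per prey:
#'   `mean_dead`, `n_control_trials`, estimated from the simulated control
#'   trials), `control_trials` (the raw control counts), `truth` (tibble of
#'   normalised attack weights per predator and prey) and `config`.
#' @export
#' @examples
#' study <- simulate_study(seed = 42)
#' dplyr::count(study$trials, predator_stage_id)
simulate_study <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  trials <- purrr::map_dfr(seq_len(nrow(config$predators)), function(i) {
    stage <- config$predators$predator_stage_id[i]
    purrr::map_dfr(seq_len(config$predators$n_replicates[i]), function(r) {
      simulate_trial(config, stage, replicate_id = r)
    })
  })
  n0 <- config$prey$n_offered_default
  control_trials <- purrr::map_dfr(seq_len(config$n_control_trials), function(r) {
    tibble(control_id = r, prey_id = config$prey$prey_id,
           n_offered = as.integer(n0),
           n_dead = stats::rbinom(length(n0), n0, config$prey$control_mortality))
  })
  controls <- control_trials |>
    dplyr::group_by(.data$prey_id) |>
    dplyr::summarise(mean_dead = mean(.data$n_dead),
                     n_control_trials = dplyr::n(), .groups = "drop")
  truth <- tibble(
    predator_stage_id = rep(rownames(config$attack_weights),
                            each = ncol(config$attack_weights)),
    prey_id = rep(colnames(config$attack_weights),
                  times = nrow(config$attack_weights)),
    alpha_true = as.vector(t(config$attack_weights /
                               rowSums(config$attack_weights))))
  list(trials = trials, controls = controls, control_trials = control_trials,
       truth = truth, config = config)
}

#' Default latent preference effects for the literature simulator
#'
#' A pool of prey taxa with microhabitat labels and latent log-scale
#' preference scores: cladocerans and dipteran larvae strongly preferred,
#' mayflies and copepods weak, heavily defended or unprofitable taxa never
#' preferred.
#'
#' @return Tibble with `prey_taxon`, `prey_order`, `prey_microhabitat`,
#'   `effect`.
#' @export
default_taxon_effects <- function() {
  tibble::tribble(
    ~prey_taxon,     ~prey_order,     ~prey_microhabitat, ~effect,
    "Cladocera",     "Cladocera",     "water_column",      2.0,
    "Culicidae",     "Diptera",       "water_column",      1.2,
    "Chironomidae",  "Diptera",       "benthic",           1.5,
    "Ephemeroptera", "Ephemeroptera", "benthic",          -0.5,
    "Copepoda",      "Copepoda",      "water_column",     -0.7,
    "Trichoptera",   "Trichoptera",   "benthic",           1.0,
    "Isopoda",       "Isopoda",       "benthic",           0.0,
    "Heteroptera",   "Heteroptera",   "water_column",     -2.0,
    "Ostracoda",     "Ostracoda",     "benthic",          -2.0,
    "Oligochaeta",   "Oligochaeta",   "benthic",           0.2)
}

#' Simulate a literature table of published selectivity experiments
#'
#' Each simulated experiment offers a random subset of taxa (mostly 2-6, as
#' in real compilations) to a predator from a random microhabitat; the most
#' preferred taxon is the one maximising latent score + Gumbel noise
#' (optionally boosted for prey sharing the predator's microhabitat), the
#' standard discrete-choice formulation.
#'
#' @param n_experiments Number of experiments to draw (>= 1).
#' @param effects Taxon pool with latent effects (see
#'   [default_taxon_effects()]); at least 2 taxa.
#' @param microhabitat_affinity Log-scale boost for prey in the predator's
#'   microhabitat (0 = none).
#' @param prey_range Candidate numbers of prey taxa per experiment.
#' @param seed Integer seed.
#' @return List with `records` (a literature table as [read_literature()]
#'   would return) and `truth` (the effects used).
#' @export
simulate_literature <- function(n_experiments, effects = default_taxon_effects(),
                                microhabitat_affinity = 0,
                                prey_range = 2:6, seed = NULL) {
  if (n_experiments < 1) abort("n_experiments must be at least 1")
  if (nrow(effects) < 2) abort("need at least 2 taxa")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  records <- purrr::map_dfr(seq_len(n_experiments), function(e) {
    k <- min(prey_range[sample.int(length(prey_range), 1)], nrow(effects))
    offered <- effects[sample.int(nrow(effects), k), ]
    pred_hab <- sample(c("benthic", "water_column"), 1)
    util <- offered$effect +
      microhabitat_affinity * (offered$prey_microhabitat == pred_hab) +
      -log(-log(stats::runif(nrow(offered))))   # Gumbel noise
    winner <- which.max(util)
    tibble(
      study_id = paste0("study", sprintf("%02d", (e - 1) %/% 2 + 1)),
      experiment_id = paste0("exp", sprintf("%03d", e)),
      predator_taxon = sample(c("Dytiscus", "Notonecta", "Anax", "Acilius"), 1),
      predator_stage = sample(c("A", "L"), 1),
      predator_microhabitat = pred_hab,
      prey_taxon = offered$prey_taxon,
      prey_order = offered$prey_order,
      prey_microhabitat = offered$prey_microhabitat,
      most_preferred_flag = as.integer(seq_len(nrow(offered)) == winner),
      habitat_structure = FALSE,
      multiple_choice = TRUE)
  })
  list(records = validate_literature(records), truth = effects)
}
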