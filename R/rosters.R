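#' Prey roster of the reference pool community
#'
#' The seven-prey roster used throughout the package examples and by the
#' synthetic study generator: common prey of predatory aquatic insects in
#' small fishless pools of temperate Europe, with the per-trial number
#' offered, foraging microhabitat, mean body length and the background
#' (predator-free) mortality observed in control trials.
#'
#' Offers are deliberately unequal (6 *Rana* tadpoles, 6 *Lymnaea*,
#' 10 *Chironomus*, 10 *Cloeon*, 10 *Culex*, 10 *Asellus*, 30 *Daphnia*),
#' mirroring natural density differences; the Manly-Chesson index corrects
#' for availability so unequal offers are unproblematic.
#'
#' @return A tibble with one row per prey type and columns `prey_id`,
#'   `taxon_order`, `microhabitat` (`"bottom"` or `"water_column"`),
#'   `n_offered_default`, `body_length_mean`, `body_length_sd` (mm) and
#'   `control_mortality` (proportion dying in 24 h without a predator).
#' @export
#' @examples
#' default_prey_roster()
default_prey_roster <- function() {
  tibble::tribble(
    ~prey_id,     ~taxon_order,    ~microhabitat,  ~n_offered_default, ~body_length_mean, ~body_length_sd, ~control_mortality,
    "Asellus",    "Isopoda",       "bottom",       10L,                 7.63,             1.03,            0.000,
    "Chironomus", "Diptera",       "bottom",       10L,                 9.38,             0.64,            0.117,
    "Cloeon",     "Ephemeroptera", "bottom",       10L,                 6.51,             0.73,            0.033,
    "Culex",      "Diptera",       "water_column", 10L,                 9.16,             0.34,            0.033,
    "Daphnia",    "Cladocera",     "water_column", 30L,                 2.34,             0.22,            0.061,
    "Lymnaea",    "Pulmonata",     "water_column",  6L,                13.19,             1.87,            0.000,
    "Rana",       "Anura",         "bottom",        6L,                 6.33,             0.30,            0.000
  )
}

#' Predator roster of the reference pool community
#'
#' The thirteen predator stages (nine species of diving beetles, water bugs
#' and odonate larvae) used by the synthetic study generator, with replicate
#' counts, body sizes and foraging microhabitat. Stage codes: `A` adult,
#' `L2`/`L3` second/third beetle larval instar, `F-0`/`F-2` final and
#' antepenultimate odonate instar.
#'
#' @return A tibble with columns `predator_stage_id`, `species`, `stage`,
#'   `order`, `microhabitat`, `n_replicates`, `body_length_mean`,
#'   `body_length_sd`.
#' @export
#' @examples
#' default_predator_roster()
default_predator_roster <- function() {
  tibble::tribble(
    ~predator_stage_id, ~species,                  ~stage, ~order,       ~microhabitat,  ~n_replicates, ~body_length_mean, ~body_length_sd,
    "Hydaticus(A)",     "Hydaticus seminiger",     "A",    "Coleoptera", "bottom",       8L,            14.8,              0.29,
    "Acilius(L2)",      "Acilius canaliculatus",   "L2",   "Coleoptera", "water_column", 7L,            12.9,              0.54,
    "Acilius(L3)",      "Acilius canaliculatus",   "L3",   "Coleoptera", "water_column", 8L,            21.7,              1.90,
    "Acilius(A)",       "Acilius canaliculatus",   "A",    "Coleoptera", "bottom",       8L,            15.4,              0.70,
    "Dytiscus(L3)",     "Dytiscus marginalis",     "L3",   "Coleoptera", "bottom",       5L,            47.8,              2.95,
    "Dytiscus(A)",      "Dytiscus marginalis",     "A",    "Coleoptera", "bottom",       9L,            32.9,              0.81,
    "Ilyocoris(A)",     "Ilyocoris cimicoides",    "A",    "Heteroptera","bottom",       8L,            14.1,              0.54,
    "Notonecta(A)",     "Notonecta glauca",        "A",    "Heteroptera","water_column", 8L,            15.1,              0.42,
    "Coenagrion(F-0)",  "Coenagrion puella",       "F-0",  "Odonata",    "water_column", 9L,            12.5,              0.90,
    "Libellula(F-2)",   "Libellula depressa",      "F-2",  "Odonata",    "bottom",       7L,            15.3,              0.63,
    "Libellula(F-0)",   "Libellula depressa",      "F-0",  "Odonata",    "bottom",       6L,            21.9,              1.18,
    "Sympetrum(F-0)",   "Sympetrum sanguineum",    "F-0",  "Odonata",    "bottom",       8L,            15.7,              0.80,
    "Anax(F-0)",        "Anax imperator",          "F-0",  "Odonata",    "bottom",       9L,            48.1,              2.54
  )
}
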