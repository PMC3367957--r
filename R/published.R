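#' Published overlap matrices from a pool food-web experiment
#'
#' Pairwise overlap matrices reported (to two decimals) by a published
#' multiple-choice predation experiment with the thirteen predator stages
#' and seven prey types of [default_predator_roster()] and
#' [default_prey_roster()]: Pianka diet overlaps between predator stages
#' (`kind = "diet"`) and predation-pressure overlaps between prey
#' (`kind = "predation_pressure"`). Useful as real-data inputs for the
#' clustering and ordination stages.
#'
#' @param kind Which matrix to load.
#' @return An `overlap_matrix` (see [as_overlap_matrix()]).
#' @export
#' @examples
#' O <- published_overlap("diet")
#' cut_groups(ward_cluster(dissimilarity(O)), k = 4)
published_overlap <- function(kind = c("diet", "predation_pressure")) {
  kind <- match.arg(kind)
  file <- switch(kind,
                 diet = "diet_overlap_published.tsv",
                 predation_pressure = "predation_overlap_published.tsv")
  path <- system.file("extdata", file, package = "preysel", mustWork = TRUE)
  as_overlap_matrix(read_matrix_tsv(path), kind)
}
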