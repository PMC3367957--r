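#' Pianka's niche-overlap index for two resource-use vectors
#'
#' The cosine-form overlap
#' `O = sum(x * y) / sqrt(sum(x^2) * sum(y^2))`, equal to 1 when the two
#' vectors are proportional (identical resource use) and 0 when their
#' supports are disjoint. Scale-invariant in either argument.
#'
#' @param x,y Non-negative numeric vectors of equal length (e.g. two
#'   predators' mean selectivity vectors, or two prey's mortality-by-predator
#'   vectors).
#' @return Overlap in `[0, 1]`.
#' @export
#' @examples
#' pianka_index(c(1, 0, 1), c(2, 0, 2))  # proportional -> 1
#' pianka_index(c(1, 0), c(0, 1))        # disjoint -> 0
pianka_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) abort("overlap inputs must be non-negative")
  sx <- sum(x^2); sy <- sum(y^2)
  if (sx == 0 || sy == 0) abort("overlap undefined for an all-zero vector")
  sum(x * y) / sqrt(sx * sy)
}

new_overlap_matrix <- function(mat, kind) {
  structure(mat, kind = kind, class = c("overlap_matrix", "matrix", "array"))
}

overlap_from_rows <- function(mat, kind) {
  n <- nrow(mat)
  O <- diag(1, n)
  dimnames(O) <- list(rownames(mat), rownames(mat))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        O[i, j] <- O[j, i] <- pianka_index(mat[i, ], mat[j, ])
      }
    }
  }
  new_overlap_matrix(O, kind)
}

#' Pairwise diet overlaps between predators
#'
#' Pianka's index applied to the species-mean Manly-Chesson alpha vectors of
#' every pair of predator stages. An overlap of 1 means two predators'
#' diets are identical in composition; 0 means they share no prey.
#'
#' @param profile A [selectivity_profile()].
#' @return An `overlap_matrix` (symmetric, unit diagonal) with attribute
#'   `kind = "diet"`. Has [tidy()] and [autoplot()] methods.
#' @export
#' @examples
#' study <- simulate_study(seed = 1)
#' O <- diet_overlap(selectivity_profile(study$trials, study$controls))
#' round(O[1:4, 1:4], 2)
diet_overlap <- function(profile) {
  stopifnot(inherits(profile, "selectivity_profile"))
  wide <- tidyr::pivot_wider(
    profile$summary[, c("predator_stage_id", "prey_id", "mean_alpha")],
    names_from = "prey_id", values_from = "mean_alpha")
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$predator_stage_id
  overlap_from_rows(mat, "diet")
}

#' Pairwise predation-pressure overlaps between prey
#'
#' The same cosine-form index applied to each prey's vector of mean
#' mortalities across predator stages: high overlap means two prey share
#' their predator assemblage.
#'
#' @param mortality A [mortality_table()] or a numeric prey-by-predator
#'   matrix of mean mortalities.
#' @return An `overlap_matrix` with `kind = "predation_pressure"`.
#' @export
predation_pressure_overlap <- function(mortality) {
  mat <- if (inherits(mortality, "mortality_table")) {
    mortality_matrix(mortality)
  } else {
    as.matrix(mortality)
  }
  overlap_from_rows(mat, "predation_pressure")
}

#' Construct an overlap matrix from a plain symmetric matrix
#'
#' Validates symmetry, unit diagonal and the `[0, 1]` range; useful for
#' matrices read back from disk.
#'
#' @param mat Symmetric numeric matrix with dimnames.
#' @param kind `"diet"` or `"predation_pressure"`.
#' @return An `overlap_matrix`.
#' @export
as_overlap_matrix <- function(mat, kind = c("diet", "predation_pressure")) {
  kind <- match.arg(kind)
  mat <- as.matrix(mat)
  if (!isSymmetric(unname(mat), tol = 1e-8)) abort("overlap matrix must be symmetric")
  if (any(abs(diag(mat) - 1) > 1e-8)) abort("overlap diagonal must be 1")
  if (any(mat < -1e-8 | mat > 1 + 1e-8)) abort("overlaps must lie in [0, 1]")
  new_overlap_matrix(mat, kind)
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("Overlap matrix (", attr(x, "kind"), "), ", nrow(x), " labels\n", sep = "")
  print(round(unclass(x), 2))
  invisible(x)
}

#' @describeIn diet_overlap Long tibble of the unique (i < j) pairs.
#' @param x An `overlap_matrix`.
#' @param ... Unused.
#' @method tidy overlap_matrix
#' @export
tidy.overlap_matrix <- function(x, ...) {
  labs <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(label_i = labs[idx[, 1]], label_j = labs[idx[, 2]],
         overlap = x[idx])
}

#' Dissimilarity from an overlap matrix
#'
#' `D = 1 - O`, the input for Ward clustering and NMDS.
#'
#' @param overlap An `overlap_matrix`.
#' @return A [stats::dist] object.
#' @export
dissimilarity <- function(overlap) {
  stopifnot(inherits(overlap, "overlap_matrix"))
  stats::as.dist(1 - unclass(overlap))
}
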