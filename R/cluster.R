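#' Ward hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering under Ward's minimum-variance criterion. The
#' default is the classic algorithm applied to the raw (unsquared)
#' dissimilarities (`stats::hclust` method `"ward.D"`, the behaviour of the
#' historical `"ward"` method); set `squared = TRUE` for the variant that
#' squares the input internally (`"ward.D2"`). The merge sequence is
#' deterministic for a given input.
#'
#' @param d A [stats::dist] or a symmetric dissimilarity matrix (zero
#'   diagonal).
#' @param squared Use the squared-dissimilarity Ward variant.
#' @return A [stats::hclust] tree.
#' @export
#' @examples
#' study <- simulate_study(seed = 1)
#' O <- diet_overlap(selectivity_profile(study$trials, study$controls))
#' tree <- ward_cluster(dissimilarity(O))
#' cut_groups(tree, k = 4)
ward_cluster <- function(d, squared = FALSE) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-8)) abort("dissimilarity matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = if (squared) "ward.D2" else "ward.D")
}

#' Cut a cluster tree into k groups
#'
#' @param tree A [stats::hclust] tree.
#' @param k Number of groups.
#' @return Tibble with `label` and `group` (integer id; ids follow the order
#'   of appearance in the tree's labels).
#' @export
cut_groups <- function(tree, k) {
  ct <- stats::cutree(tree, k = k)
  tibble(label = names(ct), group = unname(ct))
}

#' Export a cluster tree as a Newick string
#'
#' Branch lengths are derived from the merge heights of the tree, so the
#' depth of each internal node equals the value of the clustering criterion
#' at that merge.
#'
#' @param tree A [stats::hclust] tree.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if `path` is given.
#' @export
cluster_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal's NMDS (stress-1, monotone regression) via `vegan::monoMDS`,
#' taking the best of several random starts. The returned stress is on the
#' percent scale (stress 0.04 is reported as 4.0), a common presentation
#' convention for small ordinations.
#'
#' @param d A [stats::dist] or symmetric dissimilarity matrix with at least
#'   3 labels.
#' @param k Target dimensionality (default 2).
#' @param restarts Number of random starts; the configuration with the
#'   lowest final stress wins.
#' @param seed Integer seed making the ordination reproducible.
#' @return An object of class `nmds_ordination`: list with `points`
#'   (tibble: `label`, `axis1`, `axis2`, ...), `stress` (percent),
#'   `stress_all` (final stress of every start, percent), `restarts`,
#'   `seed`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
#' @examples
#' study <- simulate_study(seed = 1)
#' O <- diet_overlap(selectivity_profile(study$trials, study$controls))
#' ord <- nmds_ordination(dissimilarity(O), seed = 1)
#' glance(ord)
nmds_ordination <- function(d, k = 2, restarts = 20, seed = NULL) {
  if (is.matrix(d)) d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < 3) abort("NMDS needs at least 3 labels")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  runs <- lapply(seq_len(restarts), function(i) {
    init <- matrix(stats::rnorm(n * k), n, k)
    fit <- vegan::monoMDS(d, y = init, k = k, model = "global")
    fit
  })
  stress_all <- vapply(runs, function(f) f$stress, numeric(1))
  best <- runs[[which.min(stress_all)]]
  pts <- best$points
  points <- tibble(label = labels(d))
  for (j in seq_len(k)) points[[paste0("axis", j)]] <- pts[, j]
  structure(
    list(points = points, stress = 100 * min(stress_all),
         stress_all = 100 * stress_all, restarts = restarts, seed = seed),
    class = "nmds_ordination")
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat("NMDS ordination:", nrow(x$points), "labels, stress =",
      round(x$stress, 2), "(percent scale), best of", x$restarts, "starts\n")
  invisible(x)
}

#' @describeIn nmds_ordination Coordinates, one row per label.
#' @param x An `nmds_ordination`.
#' @param ... Unused.
#' @method tidy nmds_ordination
#' @export
tidy.nmds_ordination <- function(x, ...) x$points

#' @describeIn nmds_ordination One-row summary with the final stress.
#' @method glance nmds_ordination
#' @export
glance.nmds_ordination <- function(x, ...) {
  tibble(stress = x$stress, restarts = x$restarts,
         n = nrow(x$points))
}
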