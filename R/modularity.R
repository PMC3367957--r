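#' Build a weighted bipartite predator-prey web
#'
#' @param mat Non-negative weight matrix, predators in rows, prey in
#'   columns, with dimnames.
#' @param measure Which interaction-strength measure the weights carry
#'   (`"manly_alpha"` or `"mortality"`); metadata only.
#' @return A `bipartite_web` (matrix with a `measure` attribute). All-zero
#'   rows or columns trigger a warning naming the label: such nodes carry no
#'   information for module detection.
#' @export
bipartite_web <- function(mat, measure = c("manly_alpha", "mortality")) {
  measure <- match.arg(measure)
  mat <- as.matrix(mat)
  if (any(mat < 0)) abort("web weights must be non-negative")
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    abort("web needs row and column names")
  }
  zr <- rownames(mat)[rowSums(mat) == 0]
  zc <- colnames(mat)[colSums(mat) == 0]
  if (length(zr) > 0) warn(paste0("all-zero row(s): ", paste(zr, collapse = ", ")))
  if (length(zc) > 0) warn(paste0("all-zero column(s): ", paste(zc, collapse = ", ")))
  structure(mat, measure = measure, class = c("bipartite_web", "matrix", "array"))
}

#' Scale interaction strengths in [0, 1] to integer weights
#'
#' Module detection on weighted webs conventionally works with integer
#' weights; interaction strengths on the unit scale (selectivity indices or
#' mortalities) are multiplied by `factor` and rounded to the nearest
#' integer.
#'
#' @param mat Numeric matrix with entries in `[0, 1]` (predators x prey).
#' @param factor Scale factor (default 100).
#' @inheritParams bipartite_web
#' @return A `bipartite_web` of integer weights.
#' @export
#' @examples
#' scale_weights(matrix(c(0.515, 0.004, 0.2, 0.3), 2, 2,
#'                      dimnames = list(c("p1", "p2"), c("a", "b"))))
scale_weights <- function(mat, factor = 100, measure = c("manly_alpha", "mortality")) {
  mat <- as.matrix(mat)
  if (any(mat < -1e-9 | mat > 1 + 1e-9)) {
    abort("weights must lie in [0, 1] before scaling")
  }
  bipartite_web(round(mat * factor), measure = match.arg(measure))
}

#' Barber modularity of a partitioned bipartite web
#'
#' The weighted bipartite modularity
#' `Q = (1/F) * sum_ij (A_ij - k_i * d_j / F) * [g(i) == g(j)]`,
#' where `F` is the total weight, `k_i` and `d_j` the row and column weight
#' sums, and the indicator restricts the sum to predator-prey pairs assigned
#' to the same module. `Q = 0` for the single-module partition by
#' construction of the null model.
#'
#' @param web A [bipartite_web()].
#' @param row_modules,col_modules Integer module ids for each row and column
#'   node (in row/column order, or named).
#' @return The modularity score (scalar in `[-1, 1]`).
#' @export
bipartite_modularity <- function(web, row_modules, col_modules) {
  A <- unclass(web)
  p <- nrow(A); q <- ncol(A)
  if (!is.null(names(row_modules))) row_modules <- row_modules[rownames(A)]
  if (!is.null(names(col_modules))) col_modules <- col_modules[colnames(A)]
  stopifnot(length(row_modules) == p, length(col_modules) == q)
  FF <- sum(A)
  if (FF <= 0) abort("web has no interactions")
  B <- A - outer(rowSums(A), colSums(A)) / FF
  same <- outer(row_modules, col_modules, `==`)
  sum(B[same]) / FF
}

modularity_greedy_pass <- function(B, rowmod, colmod) {
  # one full sweep of best-improvement single-node moves; a move to a fresh
  # (empty) module has gain 0 and is always among the candidates
  improved <- FALSE
  p <- nrow(B); q <- ncol(B)
  for (i in seq_len(p)) {
    gains <- rowsum(B[i, ], colmod)           # per-module score for row i
    free_id <- max(rowmod, colmod) + 1L
    cand <- c(as.integer(rownames(gains)), free_id)
    gains <- c(gains[, 1], 0)
    cur <- rowmod[i]
    cur_gain <- if (cur %in% cand) gains[match(cur, cand)] else 0
    best <- which.max(gains)
    if (gains[best] > cur_gain + 1e-12) {
      rowmod[i] <- cand[best]; improved <- TRUE
    }
  }
  for (j in seq_len(q)) {
    gains <- rowsum(B[, j], rowmod)
    free_id <- max(rowmod, colmod) + 1L
    cand <- c(as.integer(rownames(gains)), free_id)
    gains <- c(gains[, 1], 0)
    cur <- colmod[j]
    cur_gain <- if (cur %in% cand) gains[match(cur, cand)] else 0
    best <- which.max(gains)
    if (gains[best] > cur_gain + 1e-12) {
      colmod[j] <- cand[best]; improved <- TRUE
    }
  }
  list(rowmod = rowmod, colmod = colmod, improved = improved)
}

modularity_merge_pass <- function(B, rowmod, colmod) {
  # try merging every pair of occupied modules; apply the best improving merge
  ids <- unique(c(rowmod, colmod))
  if (length(ids) < 2) return(list(rowmod = rowmod, colmod = colmod, improved = FALSE))
  best_gain <- 1e-12; best_pair <- NULL
  for (a in seq_along(ids)[-length(ids)]) {
    for (b in seq(a + 1, length(ids))) {
      g <- ids[a]; h <- ids[b]
      gain <- sum(B[rowmod == g, colmod == h, drop = FALSE]) +
        sum(B[rowmod == h, colmod == g, drop = FALSE])
      if (gain > best_gain) { best_gain <- gain; best_pair <- c(g, h) }
    }
  }
  if (is.null(best_pair)) {
    return(list(rowmod = rowmod, colmod = colmod, improved = FALSE))
  }
  rowmod[rowmod == best_pair[2]] <- best_pair[1]
  colmod[colmod == best_pair[2]] <- best_pair[1]
  list(rowmod = rowmod, colmod = colmod, improved = TRUE)
}

canonical_modules <- function(rowmod, colmod) {
  ids <- unique(c(rowmod, colmod))
  map <- setNames(seq_along(ids), ids)
  list(rows = unname(map[as.character(rowmod)]),
       cols = unname(map[as.character(colmod)]))
}

#' Detect modules in a weighted bipartite web
#'
#' Maximizes Barber modularity over joint partitions of predators and prey
#' by simulated annealing (single-node reassignment moves, geometric
#' cooling) followed by greedy refinement with single-node and
#' module-merge moves to a local optimum, taking the
#' best of `restarts` random restarts. The result is deterministic for a
#' fixed seed. On degenerate webs (a single row or column) the trivial
#' one-module partition is returned.
#'
#' @param web A [bipartite_web()].
#' @param restarts Random restarts (default 50).
#' @param seed Integer seed.
#' @param sa_sweeps Annealing sweeps per restart (each sweep proposes one
#'   move per node).
#' @param t0,t_min Initial and final annealing temperatures.
#' @return An object of class `module_partition`: list with `rows` and
#'   `cols` (named integer module ids), `Q`, `n_modules`, `measure`,
#'   `restarts`, `seed`, `Q_restarts`. Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' w <- rbind(a = c(5, 5, 0, 0), b = c(4, 6, 0, 0),
#'            c = c(0, 0, 5, 5), d = c(0, 0, 6, 4))
#' colnames(w) <- paste0("prey", 1:4)
#' find_modules(bipartite_web(w), restarts = 10, seed = 1)
find_modules <- function(web, restarts = 50, seed = NULL,
                         sa_sweeps = 25, t0 = 0.02, t_min = 1e-4) {
  A <- unclass(web)
  p <- nrow(A); q <- ncol(A)
  FF <- sum(A)
  if (FF <= 0) abort("web has no interactions")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  B <- (A - outer(rowSums(A), colSums(A)) / FF) / FF
  score <- function(rowmod, colmod) sum(B[outer(rowmod, colmod, `==`)])

  if (p < 2 || q < 2) {
    part <- canonical_modules(rep(1L, p), rep(1L, q))
    return(structure(
      list(rows = setNames(part$rows, rownames(A)),
           cols = setNames(part$cols, colnames(A)),
           Q = score(part$rows, part$cols), n_modules = 1L,
           measure = attr(web, "measure"), restarts = 0L, seed = seed,
           Q_restarts = numeric(0)),
      class = "module_partition"))
  }

  n_nodes <- p + q
  best <- NULL; best_q <- -Inf; q_restarts <- numeric(restarts)
  cool <- if (sa_sweeps > 1) (t_min / t0)^(1 / (sa_sweeps - 1)) else 1
  for (r in seq_len(restarts)) {
    k_init <- sample(2:min(n_nodes, 6), 1)
    rowmod <- sample.int(k_init, p, replace = TRUE)
    colmod <- sample.int(k_init, q, replace = TRUE)
    temp <- t0
    for (sweep in seq_len(sa_sweeps)) {
      for (step in seq_len(n_nodes)) {
        node <- sample.int(n_nodes, 1)
        target <- sample.int(max(rowmod, colmod) + 1L, 1)
        if (node <= p) {
          cur <- rowmod[node]
          if (target == cur) next
          delta <- sum(B[node, colmod == target]) - sum(B[node, colmod == cur])
          if (delta > 0 || stats::runif(1) < exp(delta / temp)) rowmod[node] <- target
        } else {
          jj <- node - p
          cur <- colmod[jj]
          if (target == cur) next
          delta <- sum(B[rowmod == target, jj]) - sum(B[rowmod == cur, jj])
          if (delta > 0 || stats::runif(1) < exp(delta / temp)) colmod[jj] <- target
        }
      }
      temp <- temp * cool
    }
    repeat {
      st <- modularity_greedy_pass(B, rowmod, colmod)
      rowmod <- st$rowmod; colmod <- st$colmod
      if (st$improved) next
      st <- modularity_merge_pass(B, rowmod, colmod)
      rowmod <- st$rowmod; colmod <- st$colmod
      if (!st$improved) break
    }
    qq <- score(rowmod, colmod)
    q_restarts[r] <- qq
    if (qq > best_q + 1e-12) {
      best_q <- qq
      best <- list(rowmod = rowmod, colmod = colmod)
    }
  }
  part <- canonical_modules(best$rowmod, best$colmod)
  structure(
    list(rows = setNames(part$rows, rownames(A)),
         cols = setNames(part$cols, colnames(A)),
         Q = best_q, n_modules = length(unique(c(part$rows, part$cols))),
         measure = attr(web, "measure"), restarts = restarts, seed = seed,
         Q_restarts = q_restarts),
    class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("Module partition:", x$n_modules, "modules, Q =", round(x$Q, 4),
    "(measure:", paste0(x$measure, ")"), "\n")
  for (g in sort(unique(c(x$rows, x$cols)))) {
    cat("  module ", g, ": ",
        paste(names(x$rows)[x$rows == g], collapse = ", "), " | ",
        paste(names(x$cols)[x$cols == g], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @describeIn find_modules Long tibble: `label`, `role`
#'   (`"predator"`/`"prey"`), `module`.
#' @param x A `module_partition`.
#' @param ... Unused.
#' @method tidy module_partition
#' @export
tidy.module_partition <- function(x, ...) {
  dplyr::bind_rows(
    tibble(label = names(x$rows), role = "predator", module = unname(x$rows)),
    tibble(label = names(x$cols), role = "prey", module = unname(x$cols)))
}

#' @describeIn find_modules One-row summary (`Q`, `n_modules`, `restarts`).
#' @method glance module_partition
#' @export
glance.module_partition <- function(x, ...) {
  tibble(Q = x$Q, n_modules = x$n_modules, restarts = x$restarts,
         measure = x$measure)
}
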