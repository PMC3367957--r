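# Independent oracles used across the suite. These deliberately use naive
# formulations (double loops, exhaustive enumeration, textbook IRLS) so they
# share no code path with the package implementation.

# Barber modularity by naive double loop over every (row, col) pair
naive_bipartite_Q <- function(A, rowmod, colmod) {
  FF <- sum(A)
  k <- rowSums(A); d <- colSums(A)
  q <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      if (rowmod[i] == colmod[j]) {
        q <- q + (A[i, j] - k[i] * d[j] / FF)
      }
    }
  }
  unname(q / FF)
}

# All set partitions of n elements as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxid) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1]] <<- prefix; return(invisible()) }
    for (g in seq_len(maxid + 1)) rec(c(prefix, g), max(maxid, g))
  }
  rec(integer(0), 0L)
  out
}

# Global maximum of Barber Q by exhaustive enumeration (webs with <= 9 nodes)
brute_force_modules <- function(A) {
  n <- nrow(A) + ncol(A)
  stopifnot(n <= 9)
  best_q <- -Inf; best <- NULL
  for (part in all_partitions(n)) {
    rowmod <- part[seq_len(nrow(A))]
    colmod <- part[nrow(A) + seq_len(ncol(A))]
    q <- naive_bipartite_Q(A, rowmod, colmod)
    if (q > best_q) { best_q <- q; best <- list(rows = rowmod, cols = colmod) }
  }
  list(Q = best_q, partition = best)
}

# One-tailed Fisher p by exhaustive enumeration of tables with fixed margins
enumerate_fisher_greater <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  prob <- function(a) {
    # hypergeometric mass for top-left cell = a
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  }
  a_obs <- tab[1, 1]
  a_max <- min(r1, c1)
  sum(vapply(a_obs:a_max, prob, numeric(1)))
}

# Textbook IRLS for a binomial-logit GLM with prior weights; returns
# coefficients (Newton scoring on the design matrix X)
irls_logit <- function(X, y, w, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- w * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    beta_new <- solve(crossprod(X, W * X), crossprod(X, W * z))
    if (max(abs(beta_new - beta)) < tol) return(drop(beta_new))
    beta <- drop(beta_new)
  }
  drop(beta)
}

# Membership checks for the reference food-web structure
nektonic_predators <- c("Acilius(L2)", "Acilius(L3)", "Coenagrion(F-0)",
                        "Notonecta(A)")
nektonic_prey <- c("Cloeon", "Culex", "Daphnia")

has_exact_nektonic_module <- function(m) {
  g <- m$rows[["Notonecta(A)"]]
  identical(sort(names(m$rows)[m$rows == g]), sort(nektonic_predators)) &&
    identical(sort(names(m$cols)[m$cols == g]), sort(nektonic_prey))
}

group_sets <- function(groups) {
  unname(lapply(split(groups$label, groups$group), sort))
}

same_grouping <- function(groups, expected_sets) {
  setequal(lapply(group_sets(groups), paste, collapse = "|"),
           lapply(lapply(expected_sets, sort), paste, collapse = "|"))
}

# tiny deterministic two-predator fixture used by io tests
tiny_trials <- function() {
  tibble::tibble(
    predator_stage_id = rep(c("predA", "predB"), each = 3),
    replicate_id = 1L,
    prey_id = rep(c("x", "y", "z"), 2),
    n_offered = rep(c(10L, 10L, 30L), 2),
    n_surviving = c(5L, 8L, 27L, 10L, 2L, 30L))
}
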