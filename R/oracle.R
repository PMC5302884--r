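#' Exact outcome distribution of the linkage process on a small instance
#'
#' Brute-force oracle for [run_linkage()]: recurses over every possible
#' cysteine-pair choice at every step with its exact selection probability,
#' memoizing on the process state (free-capacity vector plus the set of edges
#' already carrying a link), and returns the exact probability of every final
#' component-size histogram.  Only the presence of a link on an edge affects
#' the final components, and the selection weight of an edge depends only on
#' the free capacities of its endpoints, so this state is sufficient.
#'
#' Refuses instances with more than 8 cells or more than 12 eligible edges;
#' beyond that the recursion is not worth waiting for.
#'
#' @param graph A [link_graph()] or small `bak_lattice`.
#' @param capacities Per-cell capacities (default all 2).
#' @param eligible Eligible edge ids (default all).
#' @param pair_sampling As in [run_linkage()].
#' @return A tibble with columns `outcome` (canonical histogram key,
#'   e.g. `"1+1+2"` for two singletons and one 2-dimer oligomer), `sizes`
#'   (list column of integer size vectors) and `probability`; probabilities
#'   sum to 1.
#' @examples
#' g <- link_graph(2, 1, 2)
#' enumerate_exact(g)  # a single forced outcome: one 2-dimer component
#' @export
enumerate_exact <- function(graph, capacities = NULL, eligible = NULL,
                            pair_sampling = c("cysteine_pairs", "edges")) {
  pair_sampling <- match.arg(pair_sampling)
  g <- as_link_graph(graph)
  n <- g$n_cells
  if (is.null(capacities)) capacities <- rep(2L, n)
  capacities <- as.integer(capacities)
  stopifnot(length(capacities) == n, all(capacities >= 0L & capacities <= 2L))
  if (is.null(eligible)) eligible <- g$edges$edge
  ea <- g$edges$from[eligible]
  eb <- g$edges$to[eligible]
  m <- length(ea)
  if (n > 8L || m > 12L) {
    stopf(paste0(
      "instance too large for exhaustive enumeration (", n, " cells, ", m,
      " eligible edges); the guard is <= 8 cells and <= 12 eligible edges"
    ))
  }
  pairs_mode <- pair_sampling == "cysteine_pairs"

  memo <- new.env(hash = TRUE, parent = emptyenv())
  recurse <- function(free, linked) {
    fa <- free[ea]
    fb <- free[eb]
    w <- if (pairs_mode) fa * fb else as.integer(fa > 0L & fb > 0L)
    live <- which(w > 0L)
    if (length(live) == 0L) {
      sizes <- component_labels(n, ea[linked], eb[linked])$sizes
      out <- 1
      names(out) <- hist_key(sizes)
      return(out)
    }
    key <- paste(c(free, as.integer(linked)), collapse = "")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    total <- sum(w[live])
    acc <- NULL
    for (e in live) {
      free2 <- free
      free2[ea[e]] <- free2[ea[e]] - 1L
      free2[eb[e]] <- free2[eb[e]] - 1L
      linked2 <- linked
      linked2[e] <- TRUE
      sub <- recurse(free2, linked2) * (w[e] / total)
      if (is.null(acc)) {
        acc <- sub
      } else {
        common <- intersect(names(acc), names(sub))
        acc[common] <- acc[common] + sub[common]
        fresh <- setdiff(names(sub), common)
        if (length(fresh)) acc <- c(acc, sub[fresh])
      }
    }
    memo[[key]] <- acc
    acc
  }

  dist <- recurse(capacities, rep(FALSE, m))
  dist <- dist[order(names(dist))]
  tibble::tibble(
    outcome = names(dist),
    sizes = lapply(strsplit(names(dist), "+", fixed = TRUE), as.integer),
    probability = unname(dist)
  )
}

#' Monte-Carlo outcome distribution on a small instance
#'
#' Empirical counterpart of [enumerate_exact()]: repeated [run_linkage()]
#' runs tabulated by final component-size histogram.  Used to validate the
#' simulator against the oracle via total-variation distance.
#'
#' @inheritParams enumerate_exact
#' @param n_runs Number of Monte-Carlo runs.
#' @param seed Master seed; run `r` uses a deterministic sub-seed.
#' @return A tibble with columns `outcome` and `probability`.
#' @export
mc_outcome_distribution <- function(graph, capacities = NULL, eligible = NULL,
                                    n_runs = 1e5, seed = 1L,
                                    pair_sampling = c("cysteine_pairs", "edges")) {
  pair_sampling <- match.arg(pair_sampling)
  g <- as_link_graph(graph)
  n <- g$n_cells
  if (is.null(capacities)) capacities <- rep(2L, n)
  capacities <- as.integer(capacities)
  if (is.null(eligible)) eligible <- g$edges$edge
  ea <- g$edges$from[eligible]
  eb <- g$edges$to[eligible]
  pairs_mode <- pair_sampling == "cysteine_pairs"

  keys <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_runs), function(r) {
      core <- linkage_core(ea, eb, capacities, pairs_mode = pairs_mode)
      hist_key(component_labels(n, ea[core$picked], eb[core$picked])$sizes)
    }, character(1))
  })
  tab <- table(keys)
  tibble::tibble(
    outcome = names(tab),
    probability = as.numeric(tab) / n_runs
  )
}

#' Total-variation distance between two outcome distributions
#'
#' @param a,b Tibbles with columns `outcome` and `probability` (from
#'   [enumerate_exact()] or [mc_outcome_distribution()]).
#' @return Half the L1 distance between the two probability vectors over the
#'   union of outcomes.
#' @export
total_variation <- function(a, b) {
  keys <- union(a$outcome, b$outcome)
  pa <- setNames(rep(0, length(keys)), keys)
  pb <- pa
  pa[a$outcome] <- a$probability
  pb[b$outcome] <- b$probability
  sum(abs(pa - pb)) / 2
}
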