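#' Cysteine-capacity distribution of a dimer population
#'
#' Each lattice cell is a Bak dimer carrying 0, 1 or 2 cysteines competent for
#' inter-dimer disulphide linkage.  The homogeneous V61C population has all
#' mass on 2; co-expression mixtures put mass on 0 and 1 as well.
#'
#' @param p0,p1,p2 Probabilities of a dimer carrying 0, 1 or 2 linkable
#'   cysteines; must be non-negative and sum to 1.
#' @return A `bak_population` object (named numeric vector of length 3).
#' @seealso [mendelian_population()] for mixtures of competent and
#'   cysteine-null monomers.
#' @export
population_spec <- function(p0 = 0, p1 = 0, p2 = 1) {
  p <- c(p0, p1, p2)
  if (anyNA(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stopf("capacity probabilities must be non-negative and sum to 1")
  }
  structure(setNames(as.numeric(p), c("0", "1", "2")),
            class = "bak_population")
}

#' Dimer capacity mixture from random pairing of monomers
#'
#' When a fraction `f` of Bak monomers carry a linkable cysteine and monomers
#' pair at random into BH3:groove dimers, dimer capacities follow Mendelian
#' proportions: `(1-f)^2` of dimers carry 0 cysteines, `2 f (1-f)` carry 1 and
#' `f^2` carry 2.  At `f = 0.5` (equal co-expression of V61C and Cys-null)
#' this is the 25% / 50% / 25% mixture.
#'
#' @param frac_competent Fraction of monomers carrying a linkable cysteine.
#' @return A `bak_population`.
#' @export
mendelian_population <- function(frac_competent = 0.5) {
  f <- frac_competent
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1) {
    stopf("frac_competent must be a single value in [0, 1]")
  }
  population_spec((1 - f)^2, 2 * f * (1 - f), f^2)
}

#' Simulate random pairing of monomers into dimers
#'
#' Draws `n_pairs` dimers by pairing independent monomers, each competent with
#' probability `frac_competent`, and tabulates the per-dimer cysteine
#' capacities.  The empirical proportions converge on
#' [mendelian_population()]'s analytic values.
#'
#' @param n_pairs Number of dimers to form.
#' @param frac_competent Monomer competence probability.
#' @param seed Optional integer seed.
#' @return A tibble with columns `capacity` (0, 1, 2), `n` and `prop`.
#' @export
pair_monomers <- function(n_pairs, frac_competent = 0.5, seed = NULL) {
  stopifnot(n_pairs >= 1)
  caps <- with_optional_seed(seed, {
    m1 <- runif(n_pairs) < frac_competent
    m2 <- runif(n_pairs) < frac_competent
    as.integer(m1) + as.integer(m2)
  })
  counts <- tabulate(caps + 1L, nbins = 3L)
  tibble::tibble(
    capacity = 0:2,
    n = counts,
    prop = counts / n_pairs
  )
}

#' Assign per-dimer cysteine capacities
#'
#' Independent draws from the population's capacity distribution, one per
#' lattice cell.
#'
#' @param lattice A [build_lattice()] object.
#' @param pop A [population_spec()]; default puts all mass on capacity 2.
#' @param seed Optional integer seed; with a fixed seed the assignment is
#'   reproducible.
#' @return Integer vector of capacities (0, 1 or 2), length `n_cells`.
#' @export
assign_capacities <- function(lattice, pop = population_spec(), seed = NULL) {
  stopifnot(inherits(lattice, "bak_lattice"))
  if (!inherits(pop, "bak_population")) pop <- do.call(population_spec, as.list(pop))
  with_optional_seed(seed, {
    sample(0:2, lattice$n_cells, replace = TRUE, prob = unclass(pop))
  })
}

#' Block lattice edges for the duration of a run
#'
#' Each edge is independently prohibited from ever carrying a link with
#' probability `p`, fixed for the whole run.  This models the steric
#' constraint experienced by cysteines positioned close to the rigid dimer
#' core, which reduces linkage efficiency; `p = 0` is the unconstrained
#' baseline.
#'
#' @param lattice A `bak_lattice`.
#' @param p Blocking probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Integer vector of surviving (eligible) edge ids.
#' @export
block_edges <- function(lattice, p, seed = NULL) {
  stopifnot(inherits(lattice, "bak_lattice"))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stopf("edge blocking probability p must be a single value in [0, 1]")
  }
  n_edges <- nrow(lattice$edges)
  keep <- with_optional_seed(seed, runif(n_edges) >= p)
  which(keep)
}

#' Run the random-greedy disulphide linkage process to jamming
#'
#' Repeatedly (a) selects an available pair of cysteines on neighbouring
#' dimers uniformly at random, (b) declares them linked and (c) removes both
#' from the available pool, until no eligible edge joins two dimers that both
#' retain a free cysteine (the jammed state, reflecting complete linkage).
#' An eligible edge joining cells with `f_a` and `f_b` free cysteines
#' contributes `f_a * f_b` candidate pairs; a second link across the same edge
#' (a reciprocal double linkage) is permitted while both cells retain free
#' cysteines.
#'
#' @param lattice A `bak_lattice`, or a [link_graph()] for small ad-hoc
#'   instances.
#' @param capacities Integer vector of per-cell capacities (0-2); default all
#'   2, the homogeneous V61C population.
#' @param eligible Integer vector of eligible edge ids, e.g. from
#'   [block_edges()]; default all edges.
#' @param seed Optional integer seed.
#' @param pair_sampling `"cysteine_pairs"` (default; steps are uniform over
#'   available cysteine pairs) or `"edges"` (uniform over live edges,
#'   provided for sensitivity checks).
#' @param equalize_geometry Experimental: thin acceptances that create obtuse
#'   or acute double linkages by 1/2, flattening the natural 1:2:2:1
#'   opposite:obtuse:acute:reciprocal direction-pair multiplicity towards
#'   1:1:1:1.  Off by default; the default process is the plain
#'   uniform-pair rule.
#' @return A `bak_linkage` object: list with `links` (tibble: `from`, `to`,
#'   `edge`, `dir_from`, `dir_to`), `used` and `free` (per-cell link counts
#'   and remaining capacities), `capacities`, `eligible`, `component`
#'   (per-cell component label) and `component_sizes` (sizes in dimer units,
#'   one entry per oligomer).
#' @examples
#' lat <- build_lattice("hexagonal", 10, 10)
#' res <- run_linkage(lat, seed = 1)
#' sum(res$component_sizes) == lat$n_cells
#' @export
run_linkage <- function(lattice, capacities = NULL, eligible = NULL,
                        seed = NULL,
                        pair_sampling = c("cysteine_pairs", "edges"),
                        equalize_geometry = FALSE) {
  pair_sampling <- match.arg(pair_sampling)
  g <- as_link_graph(lattice)
  n <- g$n_cells
  if (is.null(capacities)) capacities <- rep(2L, n)
  capacities <- as.integer(capacities)
  if (length(capacities) != n || anyNA(capacities) ||
      any(capacities < 0L | capacities > 2L)) {
    stopf("capacities must be an integer vector of length %d with values 0-2", n)
  }
  if (is.null(eligible)) eligible <- g$edges$edge
  eligible <- as.integer(eligible)

  ea <- g$edges$from[eligible]
  eb <- g$edges$to[eligible]

  run1 <- function() {
    linkage_core(
      ea, eb, capacities,
      pairs_mode = pair_sampling == "cysteine_pairs",
      equalize = equalize_geometry,
      dir_from = if (equalize_geometry) g$edges$dir[eligible] else NULL,
      degree = g$degree
    )
  }
  core <- with_optional_seed(seed, run1())

  links_from <- ea[core$picked]
  links_to <- eb[core$picked]
  dir_from <- g$edges$dir[eligible][core$picked]
  dir_to <- if (!is.null(dir_from)) inverse_direction(dir_from, g$degree) else NULL
  comp <- component_labels(n, links_from, links_to)

  structure(
    list(
      geometry = g$geometry,
      n_cells = n,
      links = tibble::tibble(
        from = links_from,
        to = links_to,
        edge = eligible[core$picked],
        dir_from = dir_from,
        dir_to = dir_to
      ),
      used = capacities - core$free,
      free = core$free,
      capacities = capacities,
      eligible = eligible,
      component = comp$label,
      component_sizes = comp$sizes
    ),
    class = "bak_linkage"
  )
}

# The sampling core.  Lazy-deletion rejection sampler: draw uniformly from an
# active list of candidate edge slots, drop dead entries on contact, and (in
# cysteine-pair mode) accept with probability f_a*f_b / 4 so the accepted edge
# is distributed proportionally to its number of free cysteine pairs.
linkage_core <- function(ea, eb, capacities, pairs_mode = TRUE,
                         equalize = FALSE, dir_from = NULL, degree = NULL) {
  free <- capacities
  active <- which(free[ea] > 0L & free[eb] > 0L)
  n_act <- length(active)
  max_links <- sum(free) %/% 2L
  picked <- integer(max_links)
  n_picked <- 0L
  # per-cell stored direction of the first link, for geometry thinning
  first_dir <- if (equalize) rep(NA_integer_, length(free))

  while (n_act > 0L) {
    j <- sample.int(n_act, 1L)
    e <- active[j]
    a <- ea[e]
    b <- eb[e]
    fa <- free[a]
    fb <- free[b]
    w <- fa * fb
    if (w == 0L) {
      active[j] <- active[n_act]
      n_act <- n_act - 1L
      next
    }
    if (pairs_mode && w < 4L && runif(1L) * 4 >= w) next
    if (equalize) {
      thin <- 1
      da <- dir_from[e]
      db <- inverse_direction(da, degree)
      if (!is.na(first_dir[a])) {
        cls <- classify_pair_sep(first_dir[a], da, degree)
        if (cls == 1L || cls == 2L) thin <- thin / 2 # acute or obtuse
      }
      if (!is.na(first_dir[b])) {
        cls <- classify_pair_sep(first_dir[b], db, degree)
        if (cls == 1L || cls == 2L) thin <- thin / 2
      }
      if (thin < 1 && runif(1L) >= thin) next
      if (is.na(first_dir[a])) first_dir[a] <- da
      if (is.na(first_dir[b])) first_dir[b] <- db
    }
    free[a] <- fa - 1L
    free[b] <- fb - 1L
    n_picked <- n_picked + 1L
    picked[n_picked] <- e
  }
  list(picked = picked[seq_len(n_picked)], free = free)
}

# Angular separation in direction steps (0 = reciprocal).
classify_pair_sep <- function(d1, d2, degree) {
  s <- (d1 - d2) %% degree
  min(s, degree - s)
}

#' Ad-hoc linkage graph for small instances
#'
#' Wraps an explicit edge list as the substrate for [run_linkage()] and
#' [enumerate_exact()], for configurations (paths, rings, ...) that are not
#' toroidal lattices.
#'
#' @param n_cells Number of cells.
#' @param from,to Integer endpoint vectors (1-based cell ids).
#' @return A `bak_link_graph`.
#' @examples
#' ring3 <- link_graph(3, c(1, 2, 3), c(2, 3, 1))
#' @export
link_graph <- function(n_cells, from, to) {
  n_cells <- as.integer(n_cells)
  from <- as.integer(from)
  to <- as.integer(to)
  stopifnot(length(from) == length(to), n_cells >= 1L)
  if (any(from < 1L | from > n_cells | to < 1L | to > n_cells | from == to)) {
    stopf("edge endpoints must be distinct cell ids in 1..n_cells")
  }
  key <- paste(pmin(from, to), pmax(from, to))
  if (anyDuplicated(key)) stopf("duplicate edges are not allowed")
  structure(
    list(
      geometry = "graph",
      n_cells = n_cells,
      degree = NA_integer_,
      edges = tibble::tibble(
        edge = seq_along(from), from = from, to = to, dir = NA_integer_
      )
    ),
    class = "bak_link_graph"
  )
}

as_link_graph <- function(x) {
  if (inherits(x, "bak_lattice") || inherits(x, "bak_link_graph")) return(x)
  stopf("expected a bak_lattice or bak_link_graph")
}

#' Is a linkage result jammed?
#'
#' Exhaustive post-hoc scan: a result is jammed when no eligible edge joins
#' two cells that both retain a free cysteine, i.e. the termination condition
#' of the linkage process holds.
#'
#' @param result A `bak_linkage`.
#' @param lattice The lattice (or link graph) the result was produced on.
#' @return `TRUE`/`FALSE`.
#' @export
is_jammed <- function(result, lattice) {
  g <- as_link_graph(lattice)
  ea <- g$edges$from[result$eligible]
  eb <- g$edges$to[result$eligible]
  !any(result$free[ea] > 0L & result$free[eb] > 0L)
}

#' Oligomer size distribution of a linkage result
#'
#' Counts connected components of the link multigraph by size, in dimer
#' units: size `k = 1` is an unlinked dimer (the "2x" band on blue-native
#' PAGE), `k = 2` a pair of linked dimers ("4x"), and so on.  Sizes are
#' conserved: `sum(size * count)` equals the number of cells.
#'
#' @param x A `bak_linkage`, or an integer vector of component sizes.
#' @return A `bak_sizedist` tibble with columns `size` and `count` and
#'   attribute `n_cells`.
#' @export
size_distribution <- function(x) {
  sizes <- if (inherits(x, "bak_linkage")) x$component_sizes else as.integer(x)
  if (length(sizes) == 0L) stopf("no components: empty input")
  counts <- tabulate(sizes)
  out <- tibble::tibble(size = which(counts > 0L), count = counts[counts > 0L])
  new_sizedist(out, n_cells = sum(sizes))
}

new_sizedist <- function(tbl, n_cells) {
  structure(tbl, n_cells = n_cells,
            class = c("bak_sizedist", class(tibble::tibble())))
}

as_sizedist <- function(x) {
  if (inherits(x, "bak_sizedist")) return(x)
  if (inherits(x, "bak_linkage")) return(size_distribution(x))
  if (is.data.frame(x) && all(c("size", "count") %in% names(x))) {
    return(new_sizedist(
      tibble::tibble(size = as.integer(x$size), count = as.numeric(x$count)),
      n_cells = sum(x$size * x$count)
    ))
  }
  stopf("cannot interpret input as a size distribution")
}

#' Replicated linkage runs
#'
#' Runs the full stochastic pipeline (capacity assignment, edge blocking,
#' linkage to jamming) `replicates` times.  Each replicate re-draws
#' capacities and blocked edges under a deterministic per-replicate sub-seed
#' derived from `seed`, so any single replicate can be reproduced in
#' isolation and the whole set is bit-reproducible.
#'
#' @param lattice A `bak_lattice`.
#' @param pop A [population_spec()].
#' @param p Edge blocking probability.
#' @param replicates Number of independent runs.
#' @param seed Master seed (integer).
#' @inheritParams run_linkage
#' @return A tibble with columns `replicate`, `size`, `count` (class
#'   `bak_replicates`), one row per occupied oligomer size per replicate;
#'   attributes record the parameters and per-replicate seeds.
#' @examples
#' lat <- build_lattice("hexagonal", 12, 12)
#' reps <- run_replicates(lat, replicates = 3, seed = 7)
#' dplyr::count(reps, replicate, wt = size * count)  # conservation: 144 each
#' @export
run_replicates <- function(lattice, pop = population_spec(), p = 0,
                           replicates = 30L, seed = 1L,
                           pair_sampling = c("cysteine_pairs", "edges"),
                           equalize_geometry = FALSE) {
  stopifnot(replicates >= 1L)
  pair_sampling <- match.arg(pair_sampling)
  seeds <- vapply(seq_len(replicates), function(r) sub_seed(seed, r), 1L)
  out <- purrr::map_dfr(seq_len(replicates), function(r) {
    d <- replicate_run(lattice, pop, p, seeds[r], pair_sampling,
                       equalize_geometry)
    dplyr::mutate(tibble::as_tibble(d), replicate = r, .before = 1L)
  })
  structure(
    out,
    params = list(
      pop = unclass(pop), p = p, replicates = replicates, seed = seed,
      sub_seeds = seeds, pair_sampling = pair_sampling,
      equalize_geometry = equalize_geometry
    ),
    n_cells = lattice$n_cells,
    class = c("bak_replicates", class(out))
  )
}

replicate_run <- function(lattice, pop, p, seed, pair_sampling,
                          equalize_geometry) {
  withr::with_seed(seed, {
    caps <- assign_capacities(lattice, pop)
    elig <- block_edges(lattice, p)
    res <- run_linkage(lattice, caps, elig,
                       pair_sampling = pair_sampling,
                       equalize_geometry = equalize_geometry)
    size_distribution(res)
  })
}

#' Split replicated runs into per-replicate size distributions
#' @param reps A `bak_replicates` tibble.
#' @return A list of `bak_sizedist` objects.
#' @export
replicate_distributions <- function(reps) {
  lapply(split(tibble::as_tibble(reps)[c("size", "count")], reps$replicate),
         as_sizedist)
}

#' Pool replicated runs into one size distribution
#'
#' Sums complex counts over replicates; the pooled distribution drives the
#' averaged densitometry prediction and the bin-fraction summaries.
#'
#' @param reps A `bak_replicates` tibble.
#' @return A `bak_sizedist`.
#' @export
pooled_distribution <- function(reps) {
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(reps), .data$size),
    count = sum(.data$count), .groups = "drop"
  )
  as_sizedist(agg)
}

#' Mean oligomer size of a distribution
#'
#' Mean component size in dimer units: total dimers divided by the number of
#' complexes.
#'
#' @param dist Anything coercible to a size distribution.
#' @return A single number.
#' @export
mean_complex_size <- function(dist) {
  d <- as_sizedist(dist)
  sum(d$size * d$count) / sum(d$count)
}

#' Census of double-linkage geometries
#'
#' Tabulates, over all cells that formed exactly two links, the geometry
#' class of their link pair (see [classify_double_linkage()]).
#'
#' @param result A `bak_linkage` produced on a lattice (not an ad-hoc graph).
#' @param lattice The lattice used for the run.
#' @return A tibble with columns `class` and `n`, one row per class (zero
#'   counts included), ordered opposite / obtuse / acute / reciprocal
#'   (hexagonal) or opposite / perpendicular / reciprocal (square).
#' @export
geometry_census <- function(result, lattice) {
  stopifnot(inherits(result, "bak_linkage"), inherits(lattice, "bak_lattice"))
  classes <- linkage_classes(lattice$geometry)
  empty <- tibble::tibble(class = classes, n = 0L)
  if (nrow(result$links) == 0L) return(empty)

  cell <- c(result$links$from, result$links$to)
  dir <- c(result$links$dir_from, result$links$dir_to)
  keep <- result$used[cell] == 2L
  cell <- cell[keep]
  dir <- dir[keep]
  if (length(cell) == 0L) return(empty)

  o <- order(cell, dir)
  cell <- cell[o]
  dir <- dir[o]
  # doubly-linked cells appear exactly twice in the endpoint expansion
  first <- seq(1L, length(cell), by = 2L)
  stopifnot(all(cell[first] == cell[first + 1L]))
  cls <- classify_double_linkage(dir[first], dir[first + 1L], lattice$geometry)
  counts <- table(factor(cls, levels = classes))
  tibble::tibble(class = classes, n = as.integer(counts))
}

#' @export
print.bak_linkage <- function(x, ...) {
  cat(sprintf(
    "<bak_linkage> %d cells, %d links, %d components (mean size %.2f dimers)\n",
    x$n_cells, nrow(x$links), length(x$component_sizes),
    mean(x$component_sizes)
  ))
  invisible(x)
}
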