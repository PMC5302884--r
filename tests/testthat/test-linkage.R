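test_that("population specs validate and Mendelian pairing is 25/50/25 at f = 0.5", {
  expect_error(population_spec(0.5, 0.6, 0.2), "sum to 1")
  expect_error(population_spec(-0.1, 0.6, 0.5), "non-negative")
  pop <- mendelian_population(0.5)
  expect_equal(unclass(pop), c("0" = 0.25, "1" = 0.5, "2" = 0.25))
  # degenerate competence
  expect_equal(unclass(mendelian_population(1))[["2"]], 1)
  expect_equal(unclass(mendelian_population(0))[["0"]], 1)
})

test_that("simulated monomer pairing matches Mendelian proportions within 3 SD", {
  n <- 1e5
  tab <- pair_monomers(n, 0.5, seed = 101)
  expected <- c(0.25, 0.5, 0.25)
  tol <- 3 * sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(tab$prop - expected) <= tol))
  expect_equal(sum(tab$n), n)
})

test_that("capacity assignment is i.i.d., seed-reproducible, and respects the mixture", {
  lat <- build_lattice("hexagonal", 10, 10)
  expect_true(all(assign_capacities(lat) == 2L))
  a <- assign_capacities(lat, mendelian_population(0.5), seed = 7)
  b <- assign_capacities(lat, mendelian_population(0.5), seed = 7)
  expect_identical(a, b)
  big <- build_lattice("hexagonal", 100, 100)
  caps <- assign_capacities(big, mendelian_population(0.5), seed = 3)
  prop <- tabulate(caps + 1L, 3L) / big$n_cells
  tol <- 3 * sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / big$n_cells)
  expect_true(all(abs(prop - c(0.25, 0.5, 0.25)) <= tol))
})

test_that("edge blocking keeps all edges at p=0, none at p=1, and is binomial between", {
  lat <- build_lattice("hexagonal", 100, 100)
  expect_equal(length(block_edges(lat, 0, seed = 1)), 30000L)
  expect_equal(length(block_edges(lat, 1, seed = 1)), 0L)
  n_elig <- length(block_edges(lat, 0.5, seed = 5))
  expect_within(n_elig, 15000, 3 * sqrt(30000 * 0.25))
  expect_error(block_edges(lat, 1.2), "\\[0, 1\\]")
})

test_that("a lone eligible edge between two capacity-2 dimers always double-links", {
  g <- link_graph(2, 1, 2)
  for (seed in 1:5) {
    res <- run_linkage(g, seed = seed)
    expect_equal(nrow(res$links), 2L)
    expect_equal(sort(res$component_sizes), 2L)
    expect_equal(res$used, c(2L, 2L))
  }
})

test_that("degenerate inputs give all singletons", {
  lat <- build_lattice("hexagonal", 6, 6)
  res <- run_linkage(lat, eligible = integer(0), seed = 1)
  expect_equal(res$component_sizes, rep(1L, 36))
  res0 <- run_linkage(lat, capacities = rep(0L, 36), seed = 1)
  expect_equal(nrow(res0$links), 0L)
  expect_equal(size_distribution(res0)$count, 36)
})

test_that("conservation, capacity bound and jamming hold across parameter settings", {
  lat <- build_lattice("hexagonal", 12, 12)
  sq <- build_lattice("square", 12, 12)
  cases <- list(
    list(lat = lat, pop = population_spec(), p = 0),
    list(lat = lat, pop = mendelian_population(0.5), p = 0),
    list(lat = lat, pop = population_spec(), p = 0.5),
    list(lat = sq, pop = mendelian_population(0.5), p = 0.25)
  )
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    withr::with_seed(100 + i, {
      caps <- assign_capacities(cs$lat, cs$pop)
      elig <- block_edges(cs$lat, cs$p)
      res <- run_linkage(cs$lat, caps, elig)
    })
    expect_equal(sum(res$component_sizes), cs$lat$n_cells)
    d <- size_distribution(res)
    expect_equal(sum(d$size * d$count), cs$lat$n_cells)
    expect_true(all(res$used <= caps))
    expect_true(is_jammed(res, cs$lat))
  }
})

test_that("runs are reproducible under a fixed seed", {
  lat <- build_lattice("hexagonal", 8, 8)
  r1 <- run_linkage(lat, seed = 42)
  r2 <- run_linkage(lat, seed = 42)
  expect_identical(r1$links, r2$links)
  expect_identical(r1$component_sizes, r2$component_sizes)
})

test_that("replicate sets are bit-reproducible and single replicates match their sub-seed", {
  lat <- build_lattice("hexagonal", 8, 8)
  reps1 <- run_replicates(lat, p = 0.25, replicates = 3, seed = 9)
  reps2 <- run_replicates(lat, p = 0.25, replicates = 3, seed = 9)
  expect_identical(tibble::as_tibble(reps1), tibble::as_tibble(reps2))
  expect_equal(length(unique(reps1$replicate)), 3L)
  # conservation per replicate
  per <- dplyr::count(tibble::as_tibble(reps1), replicate,
                      wt = size * count)
  expect_true(all(per$n == lat$n_cells))
  # one replicate equals a direct run under the derived sub-seed
  one <- run_replicates(lat, p = 0.25, replicates = 1, seed = 9)
  sub <- attr(one, "params")$sub_seeds[1]
  direct <- withr::with_seed(sub, {
    caps <- assign_capacities(lat)
    elig <- block_edges(lat, 0.25)
    size_distribution(run_linkage(lat, caps, elig))
  })
  expect_equal(one$size, direct$size)
  expect_equal(one$count, direct$count)
})

test_that("size distributions count components and singletons correctly", {
  expect_equal(size_distribution(rep(1L, 9))$count, 9)
  d <- size_distribution(c(1L, 2L))
  expect_equal(d$size, c(1L, 2L))
  expect_equal(d$count, c(1, 1))
  expect_error(size_distribution(integer(0)), "empty")
})

test_that("geometry census is empty for singletons and counts a forced reciprocal pair", {
  lat <- build_lattice("hexagonal", 5, 5)
  res0 <- run_linkage(lat, capacities = rep(0L, 25), seed = 1)
  cen0 <- geometry_census(res0, lat)
  expect_equal(cen0$n, rep(0L, 4))
  # restrict to one edge: both cells double-link reciprocally
  res <- run_linkage(lat, capacities = ifelse(seq_len(25) %in% c(1L, 2L), 2L, 0L),
                     eligible = lat$edges$edge[lat$edges$from == 1L & lat$edges$to == 2L],
                     seed = 2)
  cen <- geometry_census(res, lat)
  expect_equal(cen$n[cen$class == "reciprocal"], 2L)
  expect_equal(sum(cen$n), 2L)
})

test_that("double-link geometry frequencies on a hex star match exact selection probabilities", {
  # Centre with capacity 2 and six capacity-2 neighbours, spokes only.
  # First link: uniform over the 6 spokes.  Second: the used spoke now offers
  # 1x1 = 1 cysteine pair, the other five 1x2 = 2 each, so P(reciprocal) =
  # 1/11 and each distinct second direction has probability 2/11.  Of the 5
  # distinct directions 1 is opposite, 2 obtuse, 2 acute:
  # P = (2/11, 4/11, 4/11, 1/11) for opposite/obtuse/acute/reciprocal.
  st <- hex_star()
  n_runs <- 2000
  counts <- c(opposite = 0, obtuse = 0, acute = 0, reciprocal = 0)
  withr::with_seed(11, {
    for (r in seq_len(n_runs)) {
      res <- run_linkage(st$lattice, st$caps, st$spokes)
      cen <- geometry_census(res, st$lattice)
      got <- cen$class[cen$n > 0]
      # the centre cell is always doubly linked; reciprocal doubles the count
      cls <- if (any(cen$n[cen$class == "reciprocal"] == 2L)) "reciprocal" else got[1]
      counts[cls] <- counts[cls] + 1
    }
  })
  freq <- counts / n_runs
  expected <- c(opposite = 2, obtuse = 4, acute = 4, reciprocal = 1) / 11
  tol <- 3 * sqrt(expected * (1 - expected) / n_runs)
  expect_true(all(abs(freq - expected) <= tol))
})

test_that("mean complex size and pooling behave", {
  d <- size_distribution(c(1L, 1L, 2L, 4L))
  expect_equal(mean_complex_size(d), 2)
  lat <- build_lattice("hexagonal", 6, 6)
  reps <- run_replicates(lat, replicates = 2, seed = 4)
  pooled <- pooled_distribution(reps)
  expect_equal(sum(pooled$size * pooled$count), 2 * lat$n_cells)
})

test_that("tidiers summarise linkage objects", {
  lat <- build_lattice("hexagonal", 6, 6)
  res <- run_linkage(lat, seed = 8)
  td <- tidy(res)
  expect_equal(sum(td$size), 36L)
  gl <- glance(res)
  expect_equal(gl$n_cells, 36L)
  expect_equal(gl$n_components, nrow(td))
  reps <- run_replicates(lat, replicates = 2, seed = 5)
  expect_equal(glance(reps)$replicates, 2L)
})
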