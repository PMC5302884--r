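small_config <- function(...) {
  utils::modifyList(
    list(
      lattice = list(geometry = "hexagonal", rows = 8, cols = 8),
      blocking_p = 0, replicates = 3, seed = 5
    ),
    list(...)
  )
}

test_that("config validation reports the offending field path", {
  expect_error(read_run_config(small_config(blocking_p = 1.5)), "blocking_p")
  expect_error(read_run_config(small_config(lattice = list(geometry = "triangular"))),
               "lattice.geometry")
  expect_error(
    read_run_config(small_config(population = list(p0 = 0.5, p1 = 0.1, p2 = 0.1))),
    "population"
  )
  cfg <- read_run_config(small_config())
  expect_equal(cfg$replicates, 3)
  expect_equal(cfg$population$p2, 1) # default fills in
})

test_that("configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(small_config(blocking_p = 0.25), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$blocking_p, 0.25)
  expect_error(read_run_config("/nonexistent/config.yaml"), "not found")
})

test_that("a simulation study writes per-replicate CSVs, a pooled CSV and a manifest", {
  dir <- withr::local_tempdir()
  reps <- simulate_linkage_study(small_config(), out_dir = dir)
  expect_length(list.files(dir, pattern = "^sizedist_rep"), 3L)
  expect_true(file.exists(file.path(dir, "sizedist_pooled.csv")))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$config$replicates, 3)
  expect_equal(manifest$lattice$n_cells, 64L)
  expect_length(manifest$sub_seeds, 3L)
  # written distribution matches the returned object
  d1 <- read.csv(file.path(dir, "sizedist_rep01.csv"))
  r1 <- dplyr::filter(tibble::as_tibble(reps), replicate == 1)
  expect_equal(d1$size_dimer_units, r1$size)
  expect_equal(d1$count, r1$count)
  # rerunning the same config reproduces the distributions exactly
  reps2 <- simulate_linkage_study(small_config())
  expect_identical(tibble::as_tibble(reps), tibble::as_tibble(reps2))
})

test_that("densitometry prediction yields one aligned trace per replicate plus a mean", {
  reps <- simulate_linkage_study(small_config())
  pred <- predict_study_densitometry(reps)
  expect_length(pred$traces, 3L)
  expect_true(all(vapply(pred$traces, function(t) isTRUE(attr(t, "aligned")), TRUE)))
  expect_s3_class(pred$mean, "bnp_trace")
  single <- predict_study_densitometry(replicate_distributions(reps)[1])
  expect_length(single$traces, 1L)
  expect_error(predict_study_densitometry(list()), "no size distributions")
})

test_that("trace processing reports per-lane alignment failures and continues", {
  m <- lane_model()
  good <- synth_replicate_set(m, 3, seed = 21)
  # a lane with no 4x peak: strictly increasing through the 4x window
  grid <- seq(-0.6, 2.4, length.out = 700)
  bad <- new_trace(grid, 0.05 * (grid - min(grid)) + dnorm(grid, 1.9, 0.2))
  out <- process_trace_set(c(good, list(bad)))
  expect_equal(length(out$traces), 3L)
  expect_equal(nrow(out$failures), 1L)
  expect_match(out$failures$error, "4x peak")
  expect_equal(nrow(out$landmarks), 3L)
  # duplicated identical lane averages to itself
  one <- align_trace(normalize_trace(good[[1]]))
  dup <- process_trace_set(list(good[[1]], good[[1]]))
  ref <- approx(one$position, one$intensity, dup$mean$position)$y
  expect_equal(dup$mean$intensity, ref, tolerance = 1e-9)
})

test_that("comparison returns zero self-distance and a bin-fraction table", {
  reps <- simulate_linkage_study(small_config())
  pred <- predict_study_densitometry(reps)
  cmp <- compare_densitometry(pred$mean, pred$mean,
                              pooled_distribution(reps),
                              pooled_distribution(reps))
  expect_equal(cmp$distance, 0)
  expect_equal(cmp$fractions$predicted, cmp$fractions$observed)
  expect_equal(nrow(cmp$fractions), 4L)
  raw <- normalize_trace(synth_lane_trace(lane_model(), seed = 1))
  expect_error(compare_densitometry(pred$mean, raw), "aligned")
})

test_that("blocking and mixtures shift mass toward unlinked dimers", {
  base <- simulate_linkage_study(small_config(seed = 31))
  mix <- simulate_linkage_study(small_config(
    seed = 31, population = list(p0 = 0.25, p1 = 0.5, p2 = 0.25)
  ))
  blocked <- simulate_linkage_study(small_config(seed = 31, blocking_p = 0.75))
  f <- function(r) summary_fractions(pooled_distribution(r))$fraction
  fb <- f(base); fm <- f(mix); fp <- f(blocked)
  expect_gt(fm[1], fb[1]) # mixture: more free dimers
  expect_lt(fm[4], fb[4]) # mixture: less >10x mass
  expect_gt(fp[1], fb[1]) # blocking: more free dimers
})
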