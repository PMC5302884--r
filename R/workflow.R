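#' Read and validate a run configuration
#'
#' Configurations drive the reproducible workflow functions.  They are plain
#' lists (or YAML files) with fields `lattice` (`geometry`, `rows`, `cols`),
#' `population` (`p0`, `p1`, `p2`), `blocking_p`, `replicates` and `seed`,
#' plus an optional `axis` block (`monomer_kda`, `sigma0`, `sigma1`).
#' Missing fields take the package defaults; every resolved value is written
#' into the run manifest so "default" is never ambiguous.  Validation errors
#' name the offending field path.
#'
#' @param config A list or the path of a YAML file.
#' @return A validated config list of class `bak_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a YAML file path")

  get_num <- function(x, path, default, lo = -Inf, hi = Inf) {
    v <- x %||% default
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < lo || v > hi) {
      stopf("config field '%s' must be a number in [%s, %s]", path, lo, hi)
    }
    v
  }
  lat <- config$lattice %||% list()
  geometry <- lat$geometry %||% "hexagonal"
  if (!geometry %in% c("hexagonal", "square")) {
    stopf("config field 'lattice.geometry' must be 'hexagonal' or 'square'")
  }
  pop <- config$population %||% list()
  out <- list(
    lattice = list(
      geometry = geometry,
      rows = get_num(lat$rows, "lattice.rows", 100, 3),
      cols = get_num(lat$cols, "lattice.cols", 100, 3)
    ),
    population = list(
      p0 = get_num(pop$p0, "population.p0", 0, 0, 1),
      p1 = get_num(pop$p1, "population.p1", 0, 0, 1),
      p2 = get_num(pop$p2, "population.p2", 1, 0, 1)
    ),
    blocking_p = get_num(config$blocking_p, "blocking_p", 0, 0, 1),
    replicates = get_num(config$replicates, "replicates", 30, 1),
    seed = get_num(config$seed, "seed", 1),
    axis = list(
      monomer_kda = get_num(config$axis$monomer_kda, "axis.monomer_kda",
                            23.4, 1e-6),
      sigma0 = get_num(config$axis$sigma0, "axis.sigma0", 0.015, 1e-9),
      sigma1 = get_num(config$axis$sigma1, "axis.sigma1", 0.004, 0)
    )
  )
  if (abs(with(out$population, p0 + p1 + p2) - 1) > 1e-8) {
    stopf("config fields 'population.p0/p1/p2' must sum to 1")
  }
  structure(out, class = c("bak_config", "list"))
}

config_axis <- function(config) {
  axis_model(monomer_kda = config$axis$monomer_kda,
             sigma0 = config$axis$sigma0, sigma1 = config$axis$sigma1)
}

#' Run a replicated linkage study from a configuration
#'
#' Builds the lattice, runs the replicated stochastic linkage pipeline, and
#' (optionally) writes one size-distribution CSV per replicate, an aggregate
#' CSV pooling all replicates, and a JSON manifest recording every resolved
#' parameter and seed — enough to reproduce the outputs bit for bit.
#'
#' @param config A config list or YAML path (see [read_run_config()]).
#' @param out_dir Optional output directory.
#' @return The `bak_replicates` tibble, invisibly carrying the lattice in
#'   attribute `lattice`.
#' @export
simulate_linkage_study <- function(config, out_dir = NULL) {
  config <- read_run_config(config)
  lat <- build_lattice(config$lattice$geometry, config$lattice$rows,
                       config$lattice$cols)
  pop <- with(config$population, population_spec(p0, p1, p2))
  reps <- run_replicates(lat, pop, p = config$blocking_p,
                         replicates = config$replicates, seed = config$seed)
  attr(reps, "lattice") <- lat
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (d in seq_len(config$replicates)) {
      one <- dplyr::filter(tibble::as_tibble(reps), .data$replicate == d)
      write.csv(
        data.frame(size_dimer_units = one$size, count = one$count),
        file.path(out_dir, sprintf("sizedist_rep%02d.csv", d)),
        row.names = FALSE
      )
    }
    agg <- dplyr::summarise(
      dplyr::group_by(tibble::as_tibble(reps), .data$size),
      count = sum(.data$count), .groups = "drop"
    )
    write.csv(
      data.frame(size_dimer_units = agg$size, count = agg$count),
      file.path(out_dir, "sizedist_pooled.csv"), row.names = FALSE
    )
    write_run_manifest(
      file.path(out_dir, "manifest.json"), config,
      extras = list(
        lattice = jsonlite::fromJSON(lattice_json(lat)),
        n_eligible_expected = nrow(lat$edges) * (1 - config$blocking_p),
        sub_seeds = attr(reps, "params")$sub_seeds
      )
    )
  }
  invisible(reps)
}

#' Predict per-replicate and mean densitometry from simulated distributions
#'
#' The analogue of overlaying and averaging predicted densitometry plots:
#' each replicate size distribution becomes a predicted trace on a shared
#' grid; the traces are analytically aligned and averaged.
#'
#' @param reps A `bak_replicates` tibble (or list of size distributions).
#' @param axis A [axis_model()].
#' @param out_dir Optional directory for per-replicate and mean trace CSVs.
#' @return A list with `traces` (aligned `bnp_trace` per replicate) and
#'   `mean` (the average trace with pointwise sd).
#' @export
predict_study_densitometry <- function(reps, axis = axis_model(),
                                       out_dir = NULL) {
  dists <- if (inherits(reps, "bak_replicates")) {
    replicate_distributions(reps)
  } else if (is.list(reps) && !is.data.frame(reps)) {
    lapply(reps, as_sizedist)
  } else {
    list(as_sizedist(reps))
  }
  if (!length(dists)) stopf("no size distributions supplied")
  # shared grid covering every replicate's bands
  kmax <- max(vapply(dists, function(d) max(d$size), 1))
  grid <- seq(band_position(axis, 1) - 4 * band_sigma(axis, 1),
              band_position(axis, kmax) + 4 * band_sigma(axis, kmax),
              length.out = 800L)
  traces <- lapply(dists, function(d) {
    align_predicted(predicted_densitometry(d, axis, grid = grid))
  })
  mean_trace <- average_traces(traces)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(traces)) {
      write_trace_csv(traces[[i]],
                      file.path(out_dir, sprintf("predicted_rep%02d.csv", i)))
    }
    write_trace_csv(mean_trace, file.path(out_dir, "predicted_mean.csv"))
  }
  list(traces = traces, mean = mean_trace)
}

#' Process a set of experimental (or synthetic) lane traces
#'
#' The lane-processing protocol: each trace is normalised to unit area, then
#' landmark-aligned (4x peak to 0, ~720 kDa minimum to 1); the aligned
#' replicates are averaged.  Traces whose landmarks cannot be detected are
#' reported in `failures` and excluded; processing continues with the rest.
#'
#' @param traces A list of `bnp_trace` objects or a character vector of
#'   trace CSV paths.
#' @param spec An [alignment_spec()].
#' @param out_dir Optional directory for aligned trace CSVs and the mean.
#' @return A list with `traces` (aligned), `mean`, `landmarks` (tibble:
#'   trace, detected raw landmark positions) and `failures` (tibble: trace,
#'   error message; zero rows when all lanes align).
#' @export
process_trace_set <- function(traces, spec = alignment_spec(),
                              out_dir = NULL) {
  if (is.character(traces)) {
    names <- basename(traces)
    traces <- lapply(traces, read_trace_csv)
  } else {
    names <- sprintf("trace_%02d", seq_along(traces))
  }
  if (!length(traces)) stopf("no traces supplied")
  aligned <- list()
  marks <- list()
  fails <- list()
  for (i in seq_along(traces)) {
    res <- tryCatch(
      align_trace(normalize_trace(traces[[i]]), spec),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <-
        tibble::tibble(trace = names[i], error = conditionMessage(res))
    } else {
      aligned[[length(aligned) + 1L]] <- res
      lm <- attr(res, "landmarks")
      marks[[length(marks) + 1L]] <- tibble::tibble(
        trace = names[i],
        peak_4x_raw = lm$peak_4x_raw,
        min_720_raw = lm$min_720_raw
      )
    }
  }
  if (!length(aligned)) stopf("alignment failed for every supplied trace")
  mean_trace <- average_traces(aligned)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(aligned)) {
      write_trace_csv(aligned[[i]],
                      file.path(out_dir, sprintf("aligned_%02d.csv", i)))
    }
    write_trace_csv(mean_trace, file.path(out_dir, "aligned_mean.csv"))
  }
  list(
    traces = aligned,
    mean = mean_trace,
    landmarks = dplyr::bind_rows(marks),
    failures = if (length(fails)) dplyr::bind_rows(fails) else
      tibble::tibble(trace = character(), error = character())
  )
}

#' Compare predicted and observed mean densitometry
#'
#' Quantifies concordance between a predicted mean trace and a processed
#' observed mean trace: L1 distance on the aligned axis, plus (when the size
#' distributions are supplied) a side-by-side table of mass fractions in the
#' standard bins.
#'
#' @param predicted,observed Aligned, unit-area `bnp_trace` objects.
#' @param predicted_dist,observed_dist Optional size distributions backing
#'   each trace, for the bin-fraction table.
#' @return A list with `distance` and `fractions` (tibble or `NULL`).
#' @export
compare_densitometry <- function(predicted, observed,
                                 predicted_dist = NULL,
                                 observed_dist = NULL) {
  if (!is_aligned(predicted) || !is_aligned(observed)) {
    stopf("both traces must be aligned before comparison")
  }
  fractions <- NULL
  if (!is.null(predicted_dist) && !is.null(observed_dist)) {
    fp <- summary_fractions(predicted_dist)
    fo <- summary_fractions(observed_dist)
    fractions <- dplyr::left_join(
      dplyr::rename(fp, predicted = "fraction"),
      dplyr::rename(fo, observed = "fraction"),
      by = "bin"
    )
  }
  list(distance = trace_distance(predicted, observed), fractions = fractions)
}

write_run_manifest <- function(path, config, extras = list()) {
  manifest <- c(
    list(
      package = "baklink",
      version = as.character(utils::packageVersion("baklink")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = unclass(config)
    ),
    extras
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
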