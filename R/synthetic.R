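#' Default ground-truth size distribution for synthetic lanes
#'
#' A hand-designed "lane-like" oligomer distribution with the qualitative
#' shape of an efficient inter-dimer crosslinking lane: negligible free
#' dimers, a prominent 4x species, resolved 6x-10x species, and a broad
#' population of large (>10x) complexes.  Chosen once so that both alignment
#' landmarks (the 4x peak and a clean local minimum near 720 kDa) exist
#' unambiguously in the noise-free trace; it is a synthetic stand-in, not a
#' digitised experimental lane.
#'
#' The profile has four parts: discrete bands at 1-5 dimer units dominated by
#' the 4x species; a mid-size plateau (6-12 dimer units) whose counts fall as
#' `1/k^2` so its mass density is roughly flat on the log-mass axis; an empty
#' window around 13-19 dimer units (~600-900 kDa) producing the
#' characteristic deep minimum near 720 kDa; and a broad Gaussian hump of
#' large complexes centred at 28 dimer units.
#'
#' @return A `bak_sizedist` tibble.
#' @export
synthetic_lane_distribution <- function() {
  k <- 1:60
  count <- numeric(60)
  count[1:5] <- c(1, 40, 14, 9, 6)
  count[6:12] <- 450 / (6:12)^2
  count[13:60] <- 30 * exp(-((13:60) - 28)^2 / (2 * 4^2))
  as_sizedist(tibble::tibble(size = k, count = count))
}

#' Synthetic BNP lane model
#'
#' Describes how synthetic replicate lane traces are generated: a true
#' oligomer size distribution rendered through the axis model
#' ([predicted_densitometry()]), distorted by a per-replicate affine axis
#' error (emulating replicate-to-replicate variation in electrophoretic
#' migration), offset by a constant baseline, and corrupted with additive
#' i.i.d. Gaussian noise, clipped at zero.
#'
#' @param truth True size distribution (default
#'   [synthetic_lane_distribution()]).
#' @param axis A [axis_model()].
#' @param noise_sd Additive Gaussian noise standard deviation per sample
#'   point (intensity units; the noise-free peak intensities are of order 1
#'   to 5).
#' @param baseline Constant baseline offset (intensity units).
#' @param offset_sd Per-replicate axis offset is drawn from
#'   `Normal(0, offset_sd)` (axis units).
#' @param scale_sd Per-replicate axis scale is drawn from
#'   `Normal(1, scale_sd)`, truncated to positive values.
#' @param grid Fixed sampling grid shared by all replicates (the "pixels" of
#'   the digitised lane); default covers the undistorted trace with margin.
#' @param n_grid Grid resolution.
#' @return A `bak_lane_model` object.
#' @export
lane_model <- function(truth = synthetic_lane_distribution(),
                       axis = axis_model(),
                       noise_sd = 0.005, baseline = 0.05,
                       offset_sd = 0.03, scale_sd = 0.05,
                       grid = NULL, n_grid = 700L) {
  stopifnot(noise_sd >= 0, baseline >= 0, offset_sd >= 0, scale_sd >= 0)
  truth <- as_sizedist(truth)
  m <- mass_weight(truth)
  centers <- band_position(axis, m$size)
  sigmas <- band_sigma(axis, m$size)
  if (is.null(grid)) {
    # margin absorbs the largest plausible distortion (|offset| + 20% scale)
    lo <- min(centers - 4 * sigmas)
    hi <- max(centers + 4 * sigmas)
    pad <- 0.15 + 0.25 * max(abs(lo), abs(hi))
    grid <- seq(lo - pad, hi + pad, length.out = n_grid)
  }
  structure(
    list(truth = truth, mass = m, axis = axis, centers = centers,
         sigmas = sigmas, noise_sd = noise_sd, baseline = baseline,
         offset_sd = offset_sd, scale_sd = scale_sd, grid = grid),
    class = "bak_lane_model"
  )
}

# Noise-free, undistorted trace of the model on its own grid.
lane_model_clean_trace <- function(model) {
  new_trace(model$grid,
            gaussian_mixture(model$grid, model$centers, model$sigmas,
                             model$mass$mass),
            aligned = FALSE, axis = model$axis)
}

#' Generate one synthetic lane trace
#'
#' Draws an affine axis distortion (offset, scale), renders the model's true
#' distribution with band centres at `offset + scale * centre` and widths
#' `scale * sigma`, samples it on the model's fixed grid, adds the baseline
#' and Gaussian noise, and clips at zero.  The ground truth (distribution,
#' distortion, distorted landmark positions) is attached so tests can verify
#' recovery.
#'
#' @param model A [lane_model()].
#' @param seed Optional integer seed; fixed seed gives a bit-identical trace.
#' @return A `bnp_trace` with attribute `ground_truth` (list: `distribution`,
#'   `offset`, `scale`, `landmarks`).
#' @export
synth_lane_trace <- function(model, seed = NULL) {
  stopifnot(inherits(model, "bak_lane_model"))
  with_optional_seed(seed, {
    offset <- rnorm(1, 0, model$offset_sd)
    scale <- 0
    while (scale <= 0) scale <- rnorm(1, 1, model$scale_sd)
    y <- gaussian_mixture(model$grid, offset + scale * model$centers,
                          scale * model$sigmas, model$mass$mass)
    y <- y + model$baseline
    if (model$noise_sd > 0) y <- y + rnorm(length(y), 0, model$noise_sd)
    y <- pmax(y, 0)
    lm_true <- true_landmarks(model)
    tr <- new_trace(model$grid, y, aligned = FALSE, axis = model$axis)
    attr(tr, "ground_truth") <- list(
      distribution = model$truth,
      offset = offset,
      scale = scale,
      landmarks = c(peak_4x = offset + scale * lm_true[["peak_4x"]],
                    min_720 = offset + scale * lm_true[["min_720"]])
    )
    tr
  })
}

# Landmarks of the noise-free undistorted trace, found with the detector the
# alignment step uses (cached on first use).
true_landmarks <- function(model) {
  cached <- attr(model, "true_landmarks")
  if (!is.null(cached)) return(cached)
  clean <- lane_model_clean_trace(model)
  spec <- alignment_spec(axis = model$axis)
  smooth <- moving_average(clean$intensity, 3L)
  c(peak_4x = find_landmark(clean$position, smooth, spec$window_a, "max",
                            "4x peak"),
    min_720 = find_landmark(clean$position, smooth, spec$window_b, "min",
                            "720 kDa minimum"))
}

#' Generate a set of synthetic replicate lanes
#'
#' Independent distortions and noise per replicate, with deterministic
#' per-replicate sub-seeds derived from the master seed.
#'
#' @param model A [lane_model()].
#' @param n Number of replicate lanes (9 matches the replication of the
#'   experimental lane protocol; 30 matches the simulated-replicate scale).
#' @param seed Master seed.
#' @return A list of `n` `bnp_trace` objects, each with its `ground_truth`
#'   attribute.
#' @export
synth_replicate_set <- function(model, n = 9L, seed = 1L) {
  stopifnot(n >= 1L)
  lapply(seq_len(n), function(r) synth_lane_trace(model, sub_seed(seed, r)))
}

#' Write synthetic fixture lanes to disk
#'
#' Emits one CSV per replicate lane plus a JSON ground-truth manifest, a
#' file layout consumable by [process_trace_set()] and by external tools.
#'
#' @param dir Output directory (created if missing).
#' @inheritParams synth_replicate_set
#' @param model A [lane_model()].
#' @return Invisibly, the paths of the written trace CSVs.
#' @export
make_synthetic_fixtures <- function(dir, model = lane_model(), n = 9L,
                                    seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  traces <- synth_replicate_set(model, n, seed)
  paths <- file.path(dir, sprintf("lane_%02d.csv", seq_len(n)))
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    write_trace_csv(traces[[i]], paths[i])
    gt <- attr(traces[[i]], "ground_truth")
    truth[[i]] <- list(file = basename(paths[i]), offset = gt$offset,
                       scale = gt$scale, landmarks = as.list(gt$landmarks))
  }
  manifest <- list(
    generator = "baklink::make_synthetic_fixtures",
    synthetic = TRUE,
    n = n, seed = seed,
    noise_sd = model$noise_sd, baseline = model$baseline,
    offset_sd = model$offset_sd, scale_sd = model$scale_sd,
    truth_distribution = as.list(tibble::as_tibble(model$truth)),
    replicates = truth
  )
  jsonlite::write_json(manifest, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
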