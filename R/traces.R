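#' Normalise a densitometry trace to unit area
#'
#' Each lane is expressed as a fraction of its total intensity: intensities
#' are divided by the trapezoidal area under the curve, so the trace
#' integrates to 1 and lanes of different exposure become comparable.
#' Idempotent; positions are untouched.
#'
#' @param trace A `bnp_trace`.
#' @return A unit-area `bnp_trace`.
#' @export
normalize_trace <- function(trace) {
  check_trace(trace)
  area <- trace_area(trace)
  if (!is.finite(area) || area <= 0) {
    stopf("cannot normalise a trace with zero total intensity")
  }
  new_trace(trace$position, trace$intensity / area,
            aligned = is_aligned(trace),
            landmarks = attr(trace, "landmarks"),
            axis = attr(trace, "axis"))
}

#' Landmark windows for two-point trace alignment
#'
#' Replicate lanes show small variations in electrophoretic migration; they
#' are corrected by an affine rescaling of each lane's axis so that two
#' landmarks coincide across replicates: the maximum corresponding to the
#' Bak 4x species (mapped to 0) and the characteristic minimum near 720 kDa
#' (mapped to 1).  Each landmark is searched for inside a window on the raw
#' axis; defaults derive from the axis model (4x band centre +/- 0.1, the
#' 720 kDa position +/- 0.2).
#'
#' @param window_a Numeric length-2: search window for the 4x peak.
#' @param window_b Numeric length-2: search window for the ~720 kDa minimum;
#'   must lie entirely to the right of `window_a`.  The default is wider than
#'   `window_a` because a scale distortion displaces positions near 1.3 of
#'   the axis far more than positions near the 4x anchor.
#' @param axis Axis model used to derive the default windows.
#' @return A `bak_alignment` object.
#' @export
alignment_spec <- function(window_a = NULL, window_b = NULL,
                           axis = axis_model()) {
  if (is.null(window_a)) window_a <- band_position(axis, 2) + c(-0.1, 0.1)
  if (is.null(window_b)) window_b <- mass_position(axis, 720) + c(-0.35, 0.35)
  stopifnot(length(window_a) == 2L, length(window_b) == 2L,
            window_a[1] < window_a[2], window_b[1] < window_b[2])
  if (window_a[2] >= window_b[1]) {
    stopf("the 4x-peak window must lie entirely left of the 720 kDa window")
  }
  structure(list(window_a = window_a, window_b = window_b),
            class = "bak_alignment")
}

# Windows on the aligned axis, where the landmarks sit at 0 and 1 by
# construction; used so that re-aligning an aligned trace is the identity.
alignment_spec_aligned <- function() {
  structure(list(window_a = c(-0.15, 0.15), window_b = c(0.8, 1.2)),
            class = "bak_alignment")
}

#' Align a trace to the 4x-peak / 720 kDa landmarks
#'
#' Detects the 4x peak (a strict local maximum inside `window_a`) and the
#' ~720 kDa minimum (a strict local minimum inside `window_b`) after light
#' smoothing (moving average, width 3 samples; ties broken toward the window
#' centre), then applies the affine map sending the detected peak to 0 and
#' the detected minimum to 1.  Intensities are unchanged.  Aligning an
#' already-aligned trace with the default spec is the identity, because its
#' landmarks already sit at 0 and 1.
#'
#' @param trace A `bnp_trace`.
#' @param spec An [alignment_spec()]; when omitted, defaults are taken on the
#'   raw axis, or on the aligned axis if the trace is already aligned.
#' @return The aligned `bnp_trace`, with attribute `landmarks` recording the
#'   detected raw positions and the affine map.
#' @export
align_trace <- function(trace, spec = NULL) {
  check_trace(trace)
  if (is.null(spec)) {
    spec <- if (is_aligned(trace)) alignment_spec_aligned() else alignment_spec()
  }
  stopifnot(inherits(spec, "bak_alignment"))
  smooth <- moving_average(trace$intensity, 3L)
  x_a <- find_landmark(trace$position, smooth, spec$window_a, "max",
                       "4x peak")
  x_b <- find_landmark(trace$position, smooth, spec$window_b, "min",
                       "720 kDa minimum")
  new_pos <- (trace$position - x_a) / (x_b - x_a)
  new_trace(
    new_pos, trace$intensity, aligned = TRUE,
    landmarks = list(
      peak_4x_raw = x_a, min_720_raw = x_b,
      offset = -x_a / (x_b - x_a), scale = 1 / (x_b - x_a)
    ),
    axis = attr(trace, "axis")
  )
}

# Strict local extremum of y inside the window; among candidates pick the
# most extreme smoothed value, ties toward the window centre.
find_landmark <- function(x, y, window, type = c("max", "min"), label) {
  type <- match.arg(type)
  n <- length(x)
  idx <- which(x >= window[1] & x <= window[2])
  idx <- idx[idx > 1L & idx < n]
  if (length(idx)) {
    if (type == "max") {
      keep <- y[idx] > y[idx - 1L] & y[idx] > y[idx + 1L]
    } else {
      keep <- y[idx] < y[idx - 1L] & y[idx] < y[idx + 1L]
    }
    idx <- idx[keep]
  }
  if (!length(idx)) {
    stopf("alignment failure: no %s found in window [%.3f, %.3f]",
          label, window[1], window[2])
  }
  val <- y[idx]
  best <- if (type == "max") val == max(val) else val == min(val)
  idx <- idx[best]
  if (length(idx) > 1L) {
    centre <- mean(window)
    idx <- idx[which.min(abs(x[idx] - centre))]
  }
  refine_vertex(x, y, idx)
}

# Sub-grid refinement: vertex of the parabola through the extremum sample and
# its two neighbours (regular grids assumed locally); falls back to the grid
# point when the three points are collinear or the vertex escapes the cell.
refine_vertex <- function(x, y, i) {
  y1 <- y[i - 1L]
  y2 <- y[i]
  y3 <- y[i + 1L]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(x[i])
  delta <- 0.5 * (y1 - y3) / denom
  if (abs(delta) > 1) return(x[i])
  x[i] + delta * (x[i + 1L] - x[i - 1L]) / 2
}

#' Analytically align a predicted densitometry trace
#'
#' Predicted traces carry their axis model, so the landmark positions are
#' known exactly: the 4x band centre and the 720 kDa axis position.  This
#' applies the corresponding affine map without any peak detection, putting
#' model predictions on the same aligned axis as processed experimental
#' lanes.
#'
#' @param trace A `bnp_trace` with an attached axis model (e.g. from
#'   [predicted_densitometry()]).
#' @return The aligned `bnp_trace`.
#' @export
align_predicted <- function(trace) {
  check_trace(trace)
  axis <- attr(trace, "axis")
  if (is.null(axis)) stopf("trace has no attached axis model; use align_trace()")
  if (is_aligned(trace)) return(trace)
  x_a <- band_position(axis, 2)
  x_b <- mass_position(axis, 720)
  new_trace((trace$position - x_a) / (x_b - x_a), trace$intensity,
            aligned = TRUE,
            landmarks = list(peak_4x_raw = x_a, min_720_raw = x_b,
                             offset = -x_a / (x_b - x_a),
                             scale = 1 / (x_b - x_a)),
            axis = axis)
}

#' Average a set of aligned traces
#'
#' Resamples every trace by linear interpolation onto a common regular grid
#' spanning the intersection of their position ranges, then returns the
#' pointwise mean and standard deviation.
#'
#' @param traces A list of aligned `bnp_trace` objects.
#' @param n_grid Grid resolution (default 500 points).
#' @param require_aligned Insist that every input carries the aligned flag.
#' @return A `bnp_trace` tibble on the common grid with columns `position`,
#'   `intensity` (the mean) and `sd`, plus attribute `n_traces`.
#' @export
average_traces <- function(traces, n_grid = 500L, require_aligned = TRUE) {
  if (inherits(traces, "bnp_trace")) traces <- list(traces)
  if (!length(traces)) stopf("no traces to average")
  lapply(traces, check_trace)
  if (require_aligned && !all(vapply(traces, is_aligned, TRUE))) {
    stopf("all traces must be aligned before averaging (see align_trace())")
  }
  lo <- max(vapply(traces, function(t) min(t$position), 1))
  hi <- min(vapply(traces, function(t) max(t$position), 1))
  if (lo >= hi) stopf("traces have no common support; cannot average")
  grid <- seq(lo, hi, length.out = n_grid)
  ys <- vapply(traces, function(t) {
    approx(t$position, t$intensity, xout = grid)$y
  }, numeric(n_grid))
  ys <- matrix(ys, nrow = n_grid)
  mean_y <- rowMeans(ys)
  sd_y <- if (ncol(ys) > 1L) apply(ys, 1L, sd) else rep(0, n_grid)
  out <- new_trace(grid, pmax(mean_y, 0),
                   aligned = all(vapply(traces, is_aligned, TRUE)),
                   axis = attr(traces[[1L]], "axis"))
  out$sd <- sd_y
  attr(out, "n_traces") <- length(traces)
  out
}

#' L1 distance between two aligned unit-area traces
#'
#' Operationalises curve concordance: both traces are interpolated onto a
#' common grid spanning the union of their ranges (zero outside their own
#' support) and the integral of the absolute difference is returned.  Zero
#' iff the traces agree on the grid; symmetric; satisfies the triangle
#' inequality; two unit-area traces with disjoint support are at distance 2.
#'
#' @param a,b Aligned `bnp_trace` objects, normalised to unit area.
#' @param n_grid Comparison grid resolution.
#' @return A non-negative number.
#' @export
trace_distance <- function(a, b, n_grid = 1000L) {
  check_trace(a)
  check_trace(b)
  if (!is_aligned(a) || !is_aligned(b)) {
    stopf("trace_distance requires aligned traces (see align_trace())")
  }
  grid <- seq(min(a$position[1], b$position[1]),
              max(max(a$position), max(b$position)),
              length.out = n_grid)
  ya <- approx(a$position, a$intensity, xout = grid, yleft = 0, yright = 0)$y
  yb <- approx(b$position, b$intensity, xout = grid, yleft = 0, yright = 0)$y
  trapz(grid, abs(ya - yb))
}

#' Restrict a trace to an axis interval
#'
#' Keeps the samples inside `[lo, hi]`.  Useful for comparing traces over a
#' shared analysis window when their recorded ranges differ (e.g. after
#' per-replicate affine alignment).
#'
#' @param trace A `bnp_trace`.
#' @param lo,hi Interval bounds on the trace's current axis.
#' @return The cropped `bnp_trace`.
#' @export
crop_trace <- function(trace, lo, hi) {
  check_trace(trace)
  keep <- trace$position >= lo & trace$position <= hi
  if (sum(keep) < 2L) stopf("cropping to [%g, %g] leaves fewer than 2 samples", lo, hi)
  new_trace(trace$position[keep], trace$intensity[keep],
            aligned = is_aligned(trace),
            landmarks = attr(trace, "landmarks"),
            axis = attr(trace, "axis"))
}

check_trace <- function(trace) {
  if (!inherits(trace, "bnp_trace")) {
    if (is.data.frame(trace) && all(c("position", "intensity") %in% names(trace))) {
      return(invisible(TRUE))
    }
    stopf("expected a bnp_trace (see new_trace())")
  }
  invisible(TRUE)
}

#' Read / write densitometry traces as two-column CSV
#'
#' Traces travel as plain CSV with columns `position` and `intensity`; a JSON
#' sidecar (`<file>.meta.json`) carries the aligned flag and landmark
#' annotations when present.
#'
#' @param trace A `bnp_trace`.
#' @param path CSV file path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a `bnp_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  check_trace(trace)
  write.csv(data.frame(position = trace$position,
                       intensity = trace$intensity),
            path, row.names = FALSE)
  meta <- list(aligned = is_aligned(trace),
               landmarks = attr(trace, "landmarks"))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("position", "intensity") %in% names(df))) {
    stopf("trace CSV must have columns 'position' and 'intensity': %s", path)
  }
  aligned <- FALSE
  landmarks <- NULL
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    aligned <- isTRUE(meta$aligned)
    landmarks <- meta$landmarks
  }
  new_trace(df$position, df$intensity, aligned = aligned, landmarks = landmarks)
}

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".meta.json")
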