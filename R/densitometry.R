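#' Gel-axis model for predicted blue-native PAGE densitometry
#'
#' Maps oligomer size to a position on the gel axis and assigns each band a
#' smearing bandwidth.  Migration on BNP gels is approximately linear in
#' log-mass, so a complex of `k` dimer units (mass `2 * k * monomer_kda`)
#' is centred at `a + b * log(mass)`; the intercept and slope are fixed so
#' that sizes `k_ref` land at positions `pos_ref` (defaults: k = 1 at -0.2
#' and k = 25 at 1.6 on the aligned axis, reproducing the non-linear band
#' spacing of real gels).  Band smearing grows with molecular weight, so the
#' Gaussian kernel bandwidth increases linearly in `k`:
#' `sigma(k) = sigma0 + sigma1 * k`.
#'
#' @param monomer_kda Monomer molecular mass in kDa (human Bak: 23.4); used
#'   for axis labelling and for expressing absolute masses (e.g. the 720 kDa
#'   landmark) on the axis.
#' @param k_ref,pos_ref Two oligomer sizes (dimer units) and the axis
#'   positions they are pinned to.
#' @param sigma0,sigma1 Bandwidth schedule intercept and slope (axis units);
#'   both must be positive.
#' @return A `bak_axis` object.
#' @export
axis_model <- function(monomer_kda = 23.4, k_ref = c(1, 25),
                       pos_ref = c(-0.2, 1.6),
                       sigma0 = 0.015, sigma1 = 0.004) {
  stopifnot(length(k_ref) == 2L, length(pos_ref) == 2L,
            k_ref[1] < k_ref[2], pos_ref[1] < pos_ref[2],
            sigma0 > 0, sigma1 >= 0, monomer_kda > 0)
  b <- (pos_ref[2] - pos_ref[1]) / (log(k_ref[2]) - log(k_ref[1]))
  a <- pos_ref[1] - b * log(2 * k_ref[1] * monomer_kda)
  structure(
    list(monomer_kda = monomer_kda, a = a, b = b,
         sigma0 = sigma0, sigma1 = sigma1),
    class = "bak_axis"
  )
}

#' Axis position of a complex of k dimer units
#' @param axis A [axis_model()].
#' @param k Oligomer size in dimer units (vectorised).
#' @return Axis positions (strictly increasing in `k`).
#' @export
band_position <- function(axis, k) {
  stopifnot(inherits(axis, "bak_axis"), all(k > 0))
  axis$a + axis$b * log(2 * k * axis$monomer_kda)
}

#' Axis position of an absolute molecular mass
#' @param axis A [axis_model()].
#' @param kda Mass in kDa (e.g. 720 for the characteristic BNP minimum).
#' @return Axis positions.
#' @export
mass_position <- function(axis, kda) {
  stopifnot(inherits(axis, "bak_axis"), all(kda > 0))
  axis$a + axis$b * log(kda)
}

#' Smearing bandwidth of the band for k dimer units
#' @inheritParams band_position
#' @return Gaussian kernel standard deviations (axis units).
#' @export
band_sigma <- function(axis, k) {
  stopifnot(inherits(axis, "bak_axis"))
  axis$sigma0 + axis$sigma1 * k
}

#' Mass-weight an oligomer size distribution
#'
#' Converts complex counts to the relative abundance of Bak molecules in each
#' complex: the count at size `k` is multiplied by `k` (the count of 2x
#' complexes by 1, of 4x complexes by 2, of 6x complexes by 3, ...), because
#' a complex of `k` dimers binds `k` dimers' worth of antibody signal on a
#' western blot.  The weighted masses are then normalised to sum to 1.
#'
#' @param dist A size distribution (`bak_sizedist`, `bak_linkage` or a data
#'   frame with `size` and `count`).
#' @return A tibble with columns `size`, `mass_raw` (`size * count`, summing
#'   to the total dimer count) and `mass` (normalised to sum 1).
#' @examples
#' mass_weight(data.frame(size = c(1, 2), count = c(2, 1)))
#' @export
mass_weight <- function(dist) {
  d <- as_sizedist(dist)
  if (nrow(d) == 0L || sum(d$count) == 0) stopf("empty size distribution")
  raw <- d$size * d$count
  tibble::tibble(size = d$size, mass_raw = raw, mass = raw / sum(raw))
}

#' Mass fractions in the standard BNP bins
#'
#' Fractions of total Bak (dimer-unit mass) found as free dimers (2x,
#' `k = 1`), tetramers (4x, `k = 2`), mid-sized complexes (6x-10x,
#' `k = 3..5`) and large complexes (>10x, `k > 5`).
#'
#' @inheritParams mass_weight
#' @return A tibble with columns `bin` and `fraction`; fractions are
#'   non-negative and sum to 1.
#' @export
summary_fractions <- function(dist) {
  m <- mass_weight(dist)
  bin <- cut(m$size, breaks = c(0, 1, 2, 5, Inf),
             labels = c("2x", "4x", "6x-10x", ">10x"))
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, mass = m$mass), bin,
                    .drop = FALSE),
    fraction = sum(mass), .groups = "drop"
  )
  out$bin <- as.character(out$bin)
  out
}

#' Predicted BNP densitometry of a size distribution
#'
#' The simulated oligomer-size distribution is turned into the lane profile a
#' western blot would show: counts are mass-weighted ([mass_weight()]), each
#' size is placed at its log-mass position on the gel axis, and each band is
#' spread with a Gaussian kernel whose width grows with size, so that bands
#' smear and run into one another at high molecular weight.
#'
#' @param dist A size distribution, a `bak_linkage`, or the output of
#'   [mass_weight()] (columns `size`, `mass`).
#' @param axis A [axis_model()].
#' @param grid Sampling positions; default is a regular grid covering every
#'   band centre plus 4 standard deviations, so that less than 1% of the
#'   total area is truncated.  A warning is raised for a user grid that does
#'   not cover all bands.
#' @param n_grid Number of grid points when `grid` is not supplied.
#' @return A `bnp_trace` tibble (`position`, `intensity`) with unit area up
#'   to grid truncation; the axis model is attached for later analytic
#'   alignment.
#' @export
predicted_densitometry <- function(dist, axis = axis_model(), grid = NULL,
                                   n_grid = 600L) {
  m <- if (is.data.frame(dist) && all(c("size", "mass") %in% names(dist))) {
    dist
  } else {
    mass_weight(dist)
  }
  centers <- band_position(axis, m$size)
  sigmas <- band_sigma(axis, m$size)
  if (is.null(grid)) {
    grid <- seq(min(centers - 4 * sigmas), max(centers + 4 * sigmas),
                length.out = n_grid)
  } else {
    if (min(grid) > min(centers - 4 * sigmas) ||
        max(grid) < max(centers + 4 * sigmas)) {
      warn("grid does not cover all band centres +/- 4 sd; area will be truncated")
    }
  }
  intensity <- gaussian_mixture(grid, centers, sigmas, m$mass)
  new_trace(grid, intensity, aligned = FALSE, axis = axis)
}

# Sum of weighted Gaussian densities evaluated on a grid.
gaussian_mixture <- function(grid, centers, sigmas, weights) {
  y <- numeric(length(grid))
  for (i in seq_along(centers)) {
    y <- y + weights[i] * dnorm(grid, centers[i], sigmas[i])
  }
  y
}

#' Construct a densitometry trace
#'
#' @param position Strictly increasing axis positions.
#' @param intensity Non-negative intensities, same length.
#' @param aligned Has the trace been landmark-aligned (4x peak at 0, 720 kDa
#'   minimum at 1)?
#' @param landmarks Optional named list/vector of landmark positions.
#' @param axis Optional `bak_axis` the trace was generated under.
#' @return A `bnp_trace` tibble.
#' @export
new_trace <- function(position, intensity, aligned = FALSE, landmarks = NULL,
                      axis = NULL) {
  position <- as.numeric(position)
  intensity <- as.numeric(intensity)
  if (length(position) != length(intensity) || length(position) < 2L) {
    stopf("position and intensity must be equal-length vectors (n >= 2)")
  }
  if (any(diff(position) <= 0)) stopf("positions must be strictly increasing")
  if (any(intensity < 0)) stopf("intensities must be non-negative")
  structure(
    tibble::tibble(position = position, intensity = intensity),
    aligned = isTRUE(aligned),
    landmarks = landmarks,
    axis = axis,
    class = c("bnp_trace", class(tibble::tibble()))
  )
}

trace_area <- function(trace) trapz(trace$position, trace$intensity)

is_aligned <- function(trace) isTRUE(attr(trace, "aligned"))
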