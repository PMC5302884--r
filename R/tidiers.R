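# broom-style summaries of fitted/simulated objects.

#' Tidy a linkage result into a component table
#'
#' @param x A `bak_linkage`.
#' @param ... Unused.
#' @return A tibble with one row per oligomer: `component`, `size`
#'   (dimer units).
#' @export
tidy.bak_linkage <- function(x, ...) {
  tibble::tibble(component = seq_along(x$component_sizes),
                 size = x$component_sizes)
}

#' One-row summary of a linkage result
#'
#' @param x A `bak_linkage`.
#' @param ... Unused.
#' @return A one-row tibble: cell, link and component counts, mean and
#'   maximum oligomer size, fraction of unlinked dimers, and the remaining
#'   free cysteine count.
#' @export
glance.bak_linkage <- function(x, ...) {
  sizes <- x$component_sizes
  tibble::tibble(
    n_cells = x$n_cells,
    n_links = nrow(x$links),
    n_components = length(sizes),
    mean_size = mean(sizes),
    max_size = max(sizes),
    dimer_fraction = sum(sizes == 1L) / sum(sizes),
    free_cysteines = sum(x$free)
  )
}

#' Tidy replicated runs
#'
#' @param x A `bak_replicates` tibble.
#' @param ... Unused.
#' @return A tibble with columns `replicate`, `size`, `count`.
#' @export
tidy.bak_replicates <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Per-study summary of replicated runs
#'
#' @param x A `bak_replicates` tibble.
#' @param ... Unused.
#' @return A one-row tibble with the replicate count and the across-replicate
#'   mean of mean oligomer size and of the unlinked-dimer mass fraction.
#' @export
glance.bak_replicates <- function(x, ...) {
  per <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$replicate),
    mean_size = sum(.data$size * .data$count) / sum(.data$count),
    dimer_mass_fraction =
      sum(.data$size * .data$count * (.data$size == 1L)) /
      sum(.data$size * .data$count),
    .groups = "drop"
  )
  tibble::tibble(
    replicates = nrow(per),
    mean_size = mean(per$mean_size),
    dimer_mass_fraction = mean(per$dimer_mass_fraction)
  )
}
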