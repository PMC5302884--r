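#' Build a toroidal 2D lattice of Bak dimers
#'
#' Constructs a finite hexagonal or square grid wrapped on a torus, the
#' geometric substrate on which dimer-dimer crosslinking is simulated.  Every
#' cell represents one BH3:groove Bak dimer; edges join immediately adjacent
#' dimers, the only pairs close enough (about 4 angstroms for the
#' copper-phenanthroline chemistry) to form a disulphide link.
#'
#' Hexagonal cells use axial coordinates `(q, r)` stored row-major on a
#' `rows x cols` rectangle; the six neighbour offsets `(dq, dr)` are, in
#' direction order 0..5:
#' `(+1,0), (+1,-1), (0,-1), (-1,0), (-1,+1), (0,+1)`.
#' Square cells use direction order 0..3 with offsets
#' `(+1,0), (0,-1), (-1,0), (0,+1)`.
#' The torus wrap is plain modular arithmetic on both axes of the rectangular
#' store (no shear on wrap), so direction `d` and direction `d + degree/2` are
#' always mutually inverse and every cell has full degree: 6 (hexagonal) or 4
#' (square).  Dimensions below 3 are rejected because wrapping then creates
#' two distinct edges between the same cell pair, i.e. a multigraph torus.
#'
#' @param geometry `"hexagonal"` (default, closest packing of dimers on a
#'   plane) or `"square"`.
#' @param rows,cols Grid dimensions; both must be at least 3.
#' @return An object of class `bak_lattice`: a list with elements `geometry`,
#'   `rows`, `cols`, `n_cells`, `degree`, `adjacency` (an
#'   `n_cells x degree` integer matrix, column `d+1` holding the neighbour in
#'   direction `d`) and `edges`, a tibble with one row per unordered cell pair
#'   (`edge`, `from`, `to`, `dir`, where `dir` is the direction of `to` seen
#'   from `from`).
#' @examples
#' lat <- build_lattice("hexagonal", 10, 10)
#' lat$n_cells      # 100
#' nrow(lat$edges)  # 300
#' @export
build_lattice <- function(geometry = c("hexagonal", "square"),
                          rows = 100L, cols = 100L) {
  geometry <- match.arg(geometry)
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 3L || cols < 3L) {
    stopf(paste(
      "rows and cols must both be >= 3: smaller tori wrap a cell onto the",
      "same neighbour twice, creating duplicate edges between one cell pair."
    ))
  }
  offs <- lattice_offsets(geometry)
  degree <- nrow(offs)
  n <- rows * cols

  # Row-major axial coordinates: cell id = r*cols + q + 1.
  q <- rep(0:(cols - 1L), times = rows)
  r <- rep(0:(rows - 1L), each = cols)
  adjacency <- matrix(0L, nrow = n, ncol = degree)
  for (d in seq_len(degree)) {
    qn <- (q + offs[d, 1L]) %% cols
    rn <- (r + offs[d, 2L]) %% rows
    adjacency[, d] <- rn * cols + qn + 1L
  }

  # Emitting only the first degree/2 directions lists each edge exactly once
  # (the remaining directions are their inverses).
  half <- degree %/% 2L
  from <- rep(seq_len(n), times = half)
  dir <- rep(0:(half - 1L), each = n)
  to <- as.vector(adjacency[, seq_len(half)])
  edges <- tibble::tibble(
    edge = seq_along(from),
    from = from,
    to = to,
    dir = dir
  )

  structure(
    list(
      geometry = geometry,
      rows = rows,
      cols = cols,
      n_cells = n,
      degree = degree,
      adjacency = adjacency,
      edges = edges
    ),
    class = "bak_lattice"
  )
}

lattice_offsets <- function(geometry) {
  switch(geometry,
    hexagonal = matrix(
      c(1L, 0L, 1L, -1L, 0L, -1L, -1L, 0L, -1L, 1L, 0L, 1L),
      ncol = 2L, byrow = TRUE
    ),
    square = matrix(
      c(1L, 0L, 0L, -1L, -1L, 0L, 0L, 1L),
      ncol = 2L, byrow = TRUE
    )
  )
}

#' @export
print.bak_lattice <- function(x, ...) {
  cat(sprintf(
    "<bak_lattice> %s %d x %d torus: %d cells (degree %d), %d edges\n",
    x$geometry, x$rows, x$cols, x$n_cells, x$degree, nrow(x$edges)
  ))
  invisible(x)
}

#' Classify the geometry of a double linkage
#'
#' A dimer that has formed two disulphide links has one of a small number of
#' link geometries, determined entirely by the two direction labels of its
#' links.  On a hexagonal lattice the classes are `reciprocal` (both links to
#' the same neighbour), `opposite` (180 degrees apart), `obtuse` (120
#' degrees) and `acute` (60 degrees); on a square lattice they are
#' `reciprocal`, `opposite` (180 degrees) and `perpendicular` (90 degrees).
#'
#' @param dir_a,dir_b Direction labels (integers in `0:5` for hexagonal,
#'   `0:3` for square); vectors are recycled to a common length.
#' @param geometry `"hexagonal"` or `"square"`.
#' @return A character vector of class labels.
#' @examples
#' classify_double_linkage(0, 3, "hexagonal")  # "opposite"
#' classify_double_linkage(0, 1, "hexagonal")  # "acute"
#' @export
classify_double_linkage <- function(dir_a, dir_b,
                                    geometry = c("hexagonal", "square")) {
  geometry <- match.arg(geometry)
  degree <- if (geometry == "hexagonal") 6L else 4L
  dir_a <- as.integer(dir_a)
  dir_b <- as.integer(dir_b)
  if (anyNA(dir_a) || anyNA(dir_b) ||
      any(dir_a < 0L | dir_a >= degree | dir_b < 0L | dir_b >= degree)) {
    stopf("direction labels must be integers in 0:%d for %s geometry",
          degree - 1L, geometry)
  }
  diff <- (dir_a - dir_b) %% degree
  diff <- pmin(diff, degree - diff) # angular separation in direction steps
  if (geometry == "hexagonal") {
    c("reciprocal", "acute", "obtuse", "opposite")[diff + 1L]
  } else {
    c("reciprocal", "perpendicular", "opposite")[diff + 1L]
  }
}

#' Names of the double-linkage classes for a lattice geometry
#' @param geometry `"hexagonal"` or `"square"`.
#' @return Character vector of class labels in conventional order.
#' @export
linkage_classes <- function(geometry = c("hexagonal", "square")) {
  geometry <- match.arg(geometry)
  if (geometry == "hexagonal") {
    c("opposite", "obtuse", "acute", "reciprocal")
  } else {
    c("opposite", "perpendicular", "reciprocal")
  }
}

#' Serialize a lattice description to JSON
#'
#' Writes the defining spec plus derived counts (not the full adjacency) as a
#' JSON string, suitable for embedding in a run manifest.
#'
#' @param lattice A `bak_lattice`.
#' @return A JSON string.
#' @export
lattice_json <- function(lattice) {
  stopifnot(inherits(lattice, "bak_lattice"))
  jsonlite::toJSON(
    list(
      geometry = lattice$geometry,
      rows = lattice$rows,
      cols = lattice$cols,
      n_cells = lattice$n_cells,
      degree = lattice$degree,
      n_edges = nrow(lattice$edges)
    ),
    auto_unbox = TRUE
  )
}

# Direction of the link as seen from each endpoint: from -> dir, to -> inverse.
inverse_direction <- function(dir, degree) (dir + degree %/% 2L) %% degree
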