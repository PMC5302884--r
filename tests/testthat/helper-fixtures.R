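# Small graphs and lattices shared across tests; everything is generated in
# code, nothing is read from disk.

ring_graph <- function(n) link_graph(n, 1:n, c(2:n, 1))

path_graph <- function(n) link_graph(n, 1:(n - 1), 2:n)

# A hexagonal lattice restricted (via the eligible-edge set) to the six
# spokes of one centre cell: the centre can double-link, its neighbours can
# accept links, every other cell is inert.
hex_star <- function() {
  lat <- build_lattice("hexagonal", 5, 5)
  centre <- 13L # row 2, col 2 (0-based), comfortably interior
  spokes <- lat$edges$edge[lat$edges$from == centre | lat$edges$to == centre]
  caps <- rep(0L, lat$n_cells)
  caps[centre] <- 2L
  caps[lat$adjacency[centre, ]] <- 2L
  list(lattice = lat, centre = centre, spokes = spokes, caps = caps)
}

trapz <- baklink:::trapz

expect_within <- function(value, target, tol) {
  expect_true(abs(value - target) <= tol,
              label = sprintf("|%g - %g| <= %g", value, target, tol))
}
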