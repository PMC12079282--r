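#' Covalent bond graph and bond-count (lag) matrix
#'
#' Two atoms are bonded when their distance does not exceed the sum of their
#' covalent radii inflated by `tolerance`. The lag matrix counts bonds along
#' shortest paths (breadth-first search); unreachable pairs are `Inf`.
#' Path-length (lag) cutoff schemes consume this graph.
#'
#' @param mol a [molecule()].
#' @param tolerance fractional slack on the covalent radii sum; default 0.25.
#' @param radii named element -> covalent radius vector; default the shipped
#'   table.
#' @return list with `adjacency` (logical matrix) and `lag` (numeric matrix,
#'   bond counts, `Inf` for disconnected pairs), class `"bond_graph"`.
#' @export
bond_graph <- function(mol, tolerance = 0.25, radii = covalent_radii()) {
  stopifnot(inherits(mol, "molecule"))
  r <- radii[mol$elements]
  if (anyNA(r)) {
    stop("no covalent radius for element(s): ",
         paste(unique(mol$elements[is.na(r)]), collapse = ", "))
  }
  n <- mol$n_atoms
  D <- distance_matrix(mol)
  thresh <- outer(r, r, `+`) * (1 + tolerance)
  adj <- D <= thresh & !diag(TRUE, n)
  adj <- adj | t(adj)
  lag <- matrix(Inf, n, n)
  diag(lag) <- 0
  for (start in seq_len(n)) {
    # breadth-first search from `start`
    dist <- rep(Inf, n)
    dist[start] <- 0
    frontier <- start
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ] & is.infinite(dist))
        dist[nb] <- d
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    lag[start, ] <- dist
  }
  structure(list(adjacency = adj, lag = lag, n_atoms = n), class = "bond_graph")
}
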