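# N-tuple spatial (dis)similarity matrices and tensors.
#
# The order-2 matrix G holds a pairwise coordinate metric; the order-3 and
# order-4 tensors extend it to triples and quadruples of atoms. Entries can
# be masked by a cutoff scheme (keep-all, bond-count lag, or a geometric
# distance window) and then normalized (simple stochastic, double
# stochastic, or mutual probability), optionally followed by a matrix power
# (order 2 only). Cutoff precedes normalization, so stochastic rows
# renormalize over the surviving neighbors.

# ---- metric registry --------------------------------------------------------

default_metric_registry <- function() {
  list(
    CH = list(
      fn = function(coords) chebyshev_distances(coords),
      desc = "Chebyshev (max coordinate difference)"
    ),
    BH = list(
      fn = NULL,  # gated: no formula configured by default
      desc = "Bhattacharyya (register an explicit formula to enable)"
    )
  )
}

#' Register a pair metric under a token
#'
#' @param token metric token (e.g. `"BH"`).
#' @param fn function taking an `n x 3` coordinate matrix and returning the
#'   symmetric `n x n` metric matrix with zero diagonal.
#' @param desc one-line description.
#' @export
register_metric <- function(token, fn, desc = token) {
  reg <- metric_registry()
  reg[[token]] <- list(fn = fn, desc = desc)
  .midas_env$metrics <- reg
  invisible(reg)
}

#' The current metric registry
#' @export
metric_registry <- function() {
  if (is.null(.midas_env$metrics)) .midas_env$metrics <- default_metric_registry()
  .midas_env$metrics
}

minkowski_distances <- function(coords, p) {
  n <- nrow(coords)
  # scale by the largest component difference so large p cannot overflow
  M <- chebyshev_distances(coords)
  scale <- max(M, 1e-300)
  D <- matrix(0, n, n)
  for (d in 1:3) {
    D <- D + (abs(outer(coords[, d], coords[, d], `-`)) / scale)^p
  }
  scale * D^(1 / p)
}

chebyshev_distances <- function(coords) {
  n <- nrow(coords)
  D <- matrix(0, n, n)
  for (d in 1:3) {
    D <- pmax(D, abs(outer(coords[, d], coords[, d], `-`)))
  }
  D
}

#' Resolve a metric token to a pairwise-distance function
#'
#' Grammar: `M<k>` is the Minkowski metric of order `k` when `k < 10` and of
#' fractional order `k/10` when `k >= 10` (so `M3` is p = 3, `M12` is
#' p = 1.2, `M15` is p = 1.5). `CH` is Chebyshev. Other tokens are looked up
#' in the registry; unknown tokens raise a configuration error listing what
#' is registered.
#'
#' @param metric_id metric token.
#' @return function: coordinate matrix -> symmetric metric matrix.
#' @export
resolve_metric <- function(metric_id) {
  m <- regmatches(metric_id, regexec("^M([0-9]+)$", metric_id))[[1]]
  if (length(m) == 2L) {
    k <- as.integer(m[2L])
    p <- if (k >= 10L) k / 10 else k
    if (p <= 0) stop("Minkowski order must be positive (token ", metric_id, ")")
    return(function(coords) minkowski_distances(coords, p))
  }
  reg <- metric_registry()
  entry <- reg[[metric_id]]
  if (is.null(entry)) {
    stop("unregistered metric token '", metric_id, "'; registry: ",
         paste(c("M<k>", names(reg)), collapse = ", "))
  }
  if (is.null(entry$fn)) {
    stop("metric '", metric_id, "' is registered but has no formula configured; ",
         "supply one with register_metric()")
  }
  entry$fn
}

# ---- tuple matrix construction ---------------------------------------------

new_tuple_matrix <- function(entries, order, metric_id, n_atoms,
                             normalization = "NS", power = 1L,
                             cutoff = cutoff_scheme("KA")) {
  structure(
    list(entries = entries, order = order, metric_id = metric_id,
         n_atoms = n_atoms, normalization = normalization, power = power,
         cutoff = cutoff),
    class = "tuple_matrix"
  )
}

#' @export
print.tuple_matrix <- function(x, ...) {
  cat("<tuple_matrix> order", x$order, "metric", x$metric_id,
      "norm", paste0(x$normalization, x$power),
      "cutoff", format_cutoff(x$cutoff), "on", x$n_atoms, "atoms\n")
  invisible(x)
}

#' Order-2 pairwise metric matrix of a molecule
#'
#' @param mol a [molecule()].
#' @param metric_id metric token, see [resolve_metric()].
#' @return a `tuple_matrix` of order 2 (symmetric, zero diagonal).
#' @export
pair_matrix <- function(mol, metric_id = "M2") {
  stopifnot(inherits(mol, "molecule"))
  fn <- resolve_metric(metric_id)
  D <- fn(mol$coords)
  diag(D) <- 0
  new_tuple_matrix(D, 2L, metric_id, mol$n_atoms)
}

# res[i1,...,in] = D[i_{slots[1]}, i_{slots[2]}] for an order-`ord` array;
# aperm() takes the inverse of the index-target permutation
pair_term <- function(D, slots, ord) {
  n <- nrow(D)
  X <- array(D, rep(n, ord))  # X[a,b,...] = D[a,b]
  aperm(X, order(c(slots, setdiff(seq_len(ord), slots))))
}

tuple_slots <- function(ord) {
  utils::combn(ord, 2L, simplify = FALSE)
}

repeated_index_mask <- function(n, ord) {
  # TRUE where at least two tuple indices coincide
  idx <- lapply(seq_len(ord), function(d) {
    aperm(array(rep(seq_len(n), prod(rep(n, ord - 1L))), rep(n, ord)),
          order(c(d, setdiff(seq_len(ord), d))))
  })
  mask <- array(FALSE, rep(n, ord))
  for (a in seq_len(ord - 1L)) {
    for (b in (a + 1L):ord) {
      mask <- mask | (idx[[a]] == idx[[b]])
    }
  }
  mask
}

#' Order-3 or order-4 spatial (dis)similarity tensor
#'
#' The tuple entry is the sum of the pairwise metric over all pairs within
#' the tuple (3 pairs for triples, 6 for quadruples), which keeps the tensor
#' symmetric under any permutation of its indices and reduces to the pair
#' metric at order 2. Tuples with repeated atom indices are set to 0.
#'
#' @param mol a [molecule()].
#' @param order 3 or 4.
#' @param metric_id metric token.
#' @return a `tuple_matrix` whose `entries` is an order-3/4 array.
#' @export
tuple_tensor <- function(mol, order, metric_id = "M2") {
  stopifnot(inherits(mol, "molecule"))
  order <- as.integer(order)
  if (!order %in% c(3L, 4L)) stop("order must be 3 or 4")
  if (mol$n_atoms < order) {
    stop("molecule has ", mol$n_atoms, " atoms; need at least ", order)
  }
  fn <- resolve_metric(metric_id)
  D <- fn(mol$coords)
  diag(D) <- 0
  n <- mol$n_atoms
  T <- array(0, rep(n, order))
  for (sl in tuple_slots(order)) {
    T <- T + pair_term(D, sl, order)
  }
  T[repeated_index_mask(n, order)] <- 0
  new_tuple_matrix(T, order, metric_id, n)
}

# ---- cutoff schemes ---------------------------------------------------------

#' Construct a cutoff scheme
#'
#' `KA` keeps all entries; `LGP` zeroes every entry whose tuple contains a
#' pair more than `lag_max` bonds apart; `LGL` zeroes every entry whose
#' tuple contains a pair whose geometric distance falls outside
#' `[window[1], window[2]]` Angstrom.
#'
#' @param kind `"KA"`, `"LGP"` or `"LGL"`.
#' @param lag_max maximum bond count for `LGP` (>= 1).
#' @param window length-2 numeric `c(a, b)` with `0 < a < b`, for `LGL`.
#' @export
cutoff_scheme <- function(kind = c("KA", "LGP", "LGL"), lag_max = NULL, window = NULL) {
  kind <- match.arg(kind)
  if (kind == "LGP") {
    if (is.null(lag_max) || lag_max < 1) stop("LGP needs lag_max >= 1")
    lag_max <- as.integer(lag_max)
  }
  if (kind == "LGL") {
    if (is.null(window) || length(window) != 2L || !all(window > 0) ||
        window[1] >= window[2]) {
      stop("LGL needs a window c(a, b) with 0 < a < b")
    }
  }
  structure(list(kind = kind, lag_max = lag_max, window = window),
            class = "cutoff_scheme")
}

format_cutoff <- function(sc) {
  switch(sc$kind,
         KA = "KA",
         LGP = sprintf("LGP[%d]", sc$lag_max),
         LGL = sprintf("LGL[%g-%g]", sc$window[1], sc$window[2]))
}

#' Apply a cutoff scheme to a tuple matrix or tensor
#'
#' Must be applied before normalization, so that stochastic rows renormalize
#' over the surviving neighbors.
#'
#' @param M a `tuple_matrix`.
#' @param scheme a [cutoff_scheme()].
#' @param graph a [bond_graph()] (required for `LGP`).
#' @param mol the source [molecule()] (required for `LGL` at order > 2, and
#'   for `LGL` at order 2 when the metric is not the geometric distance
#'   itself).
#' @export
apply_cutoff <- function(M, scheme, graph = NULL, mol = NULL) {
  stopifnot(inherits(M, "tuple_matrix"), inherits(scheme, "cutoff_scheme"))
  if (scheme$kind == "KA") {
    M$cutoff <- scheme
    return(M)
  }
  pair_ok <- switch(scheme$kind,
    LGP = {
      if (is.null(graph)) stop("LGP cutoff requires a bond_graph")
      graph$lag <= scheme$lag_max
    },
    LGL = {
      if (is.null(mol)) stop("LGL cutoff requires the source molecule")
      D <- distance_matrix(mol)
      D >= scheme$window[1] & D <= scheme$window[2]
    })
  diag(pair_ok) <- TRUE
  n <- M$n_atoms
  if (M$order == 2L) {
    M$entries[!pair_ok] <- 0
  } else {
    keep <- array(TRUE, rep(n, M$order))
    for (sl in tuple_slots(M$order)) {
      keep <- keep & (pair_term(pair_ok * 1, sl, M$order) > 0)
    }
    M$entries[!keep] <- 0
  }
  M$cutoff <- scheme
  M
}

# ---- normalizations ---------------------------------------------------------

#' Normalize a tuple matrix (NS / SS / DS / MP) and apply a matrix power
#'
#' * `NS`: entries unchanged (non-stochastic).
#' * `SS`: each row — for order > 2 each leading-index slice — divided by
#'   its sum (simple stochastic).
#' * `DS`: Sinkhorn row/column alternation until every row and column sum is
#'   within `tol` of 1 (double stochastic; order 2 only).
#' * `MP`: every entry divided by the grand sum (mutual probability).
#'
#' The result is then raised to the matrix `power` (order 2 only; `power = 0`
#' gives the identity matrix, `power = 1` leaves the normalized matrix).
#'
#' @param M a `tuple_matrix` with nonnegative entries.
#' @param scheme `"NS"`, `"SS"`, `"DS"` or `"MP"`.
#' @param power integer >= 0 matrix power (order 2 only for `power != 1`).
#' @param tol Sinkhorn convergence tolerance.
#' @param max_iter Sinkhorn alternation cap.
#' @param zero_rows `"error"` (default) raises on an all-zero row/slice under
#'   SS/DS; `"keep"` leaves such a row zero, which is the behavior used when
#'   a cutoff has already emptied a neighborhood.
#' @export
normalize_matrix <- function(M, scheme = c("NS", "SS", "DS", "MP"),
                             power = 1L, tol = 1e-8, max_iter = 10000L,
                             zero_rows = c("error", "keep")) {
  stopifnot(inherits(M, "tuple_matrix"))
  scheme <- match.arg(scheme)
  zero_rows <- match.arg(zero_rows)
  if (any(M$entries < 0)) stop("normalization requires nonnegative entries")
  E <- M$entries
  if (scheme == "SS") {
    if (M$order == 2L) {
      rs <- rowSums(E)
      if (any(rs == 0) && zero_rows == "error") {
        stop("zero row(s) under SS normalization: ",
             paste(which(rs == 0), collapse = ", "))
      }
      rs[rs == 0] <- 1
      E <- E / rs
    } else {
      n <- M$n_atoms
      flat <- matrix(E, nrow = n)  # rows = leading index, columns = the rest
      rs <- rowSums(flat)
      if (any(rs == 0) && zero_rows == "error") {
        stop("zero leading-index slice(s) under SS normalization: ",
             paste(which(rs == 0), collapse = ", "))
      }
      rs[rs == 0] <- 1
      E <- array(flat / rs, dim(E))
    }
  } else if (scheme == "DS") {
    if (M$order != 2L) stop("double-stochastic normalization is implemented for order 2 only")
    rs <- rowSums(E); cs <- colSums(E)
    if ((any(rs == 0) || any(cs == 0)) && zero_rows == "error") {
      stop("zero row/column under DS normalization")
    }
    it <- 0L
    repeat {
      rs <- rowSums(E); rs[rs == 0] <- 1
      E <- E / rs
      cs <- colSums(E); cs[cs == 0] <- 1
      E <- sweep(E, 2L, cs, `/`)
      it <- it + 1L
      dev <- max(abs(rowSums(E) - 1), abs(colSums(E) - 1))
      if (dev < tol) break
      if (it >= max_iter) {
        stop("Sinkhorn alternation did not converge within ", max_iter,
             " iterations (deviation ", signif(dev, 3), ")")
      }
    }
  } else if (scheme == "MP") {
    g <- sum(E)
    if (g > 0) E <- E / g
  }
  power <- as.integer(power)
  if (power < 0L) stop("matrix power must be >= 0")
  if (power != 1L) {
    if (M$order != 2L) stop("matrix powers are defined for order 2 only")
    E <- matrix_power(E, power)
  }
  M$entries <- E
  M$normalization <- scheme
  M$power <- power
  M
}

matrix_power <- function(A, k) {
  n <- nrow(A)
  out <- diag(n)
  base <- A
  while (k > 0L) {
    if (k %% 2L == 1L) out <- out %*% base
    base <- base %*% base
    k <- k %/% 2L
  }
  out
}
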