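#' Gasteiger-Marsili partial charges (PEOE)
#'
#' Partial equalization of orbital electronegativity: each atom's
#' electronegativity is a quadratic in its current charge,
#' chi(q) = a + b q + c q^2, and at iteration k every bond transfers charge
#' from its less to its more electronegative end, proportional to the
#' electronegativity difference, scaled by the donor's cation
#' electronegativity (a + b + c) and attenuated by `damping^k`. Updates are
#' simultaneous across bonds within an iteration, so the total charge is
#' conserved exactly.
#'
#' Elements without PEOE parameters (notably the transition metals Ru, Rh,
#' Os, Ir): with `metal_fallback = TRUE` (default) such an atom keeps its
#' formal charge fixed and is excluded from transfer steps; with
#' `metal_fallback = FALSE` the function raises a parameterization error.
#'
#' @param mol a [molecule()].
#' @param n_iter number of damped iterations (classic scheme: 6).
#' @param damping attenuation base in (0, 1) (classic scheme: 0.5).
#' @param graph optional precomputed [bond_graph()].
#' @param metal_fallback logical; see Details.
#' @return numeric vector of per-atom charges, in e, summing to
#'   `mol$total_charge` to machine precision.
#' @export
gasteiger_charges <- function(mol, n_iter = 6L, damping = 0.5, graph = NULL,
                              metal_fallback = TRUE) {
  stopifnot(inherits(mol, "molecule"))
  if (damping <= 0 || damping >= 1) stop("damping must lie in (0, 1)")
  if (n_iter < 1L) stop("n_iter must be >= 1")
  pars <- peoe_params()
  have <- mol$elements %in% rownames(pars)
  if (!all(have) && !metal_fallback) {
    stop("no PEOE parameters for element(s): ",
         paste(unique(mol$elements[!have]), collapse = ", "),
         " (metal_fallback disabled)")
  }
  n <- mol$n_atoms
  q <- as.numeric(mol$formal_charges)
  # atoms outside the parameterization hold their formal charge and do not
  # exchange; any residual molecular charge is spread over the active atoms
  active <- which(have)
  residual <- mol$total_charge - sum(q)
  if (abs(residual) > 0) {
    sink <- if (length(active)) active else seq_len(n)
    q[sink] <- q[sink] + residual / length(sink)
  }
  if (length(active) < 2L) return(q)
  if (is.null(graph)) graph <- bond_graph(mol)
  bonds <- which(graph$adjacency & upper.tri(graph$adjacency), arr.ind = TRUE)
  if (nrow(bonds)) {
    keep <- have[bonds[, 1L]] & have[bonds[, 2L]]
    bonds <- bonds[keep, , drop = FALSE]
  }
  if (!nrow(bonds)) return(q)
  a <- b <- cc <- rep(NA_real_, n)
  a[have] <- pars[mol$elements[have], "a"]
  b[have] <- pars[mol$elements[have], "b"]
  cc[have] <- pars[mol$elements[have], "c"]
  chi_plus <- a + b + cc
  for (k in seq_len(n_iter)) {
    chi <- a + b * q + cc * q^2
    dq <- numeric(n)
    att <- damping^k
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1L]; j <- bonds[r, 2L]
      if (chi[i] == chi[j]) next
      lo <- if (chi[i] < chi[j]) i else j
      hi <- if (lo == i) j else i
      amt <- (chi[hi] - chi[lo]) / chi_plus[lo] * att
      dq[lo] <- dq[lo] + amt
      dq[hi] <- dq[hi] - amt
    }
    q <- q + dq
  }
  q
}

#' PEOE electronegativity parameter table
#'
#' Element-level a, b, c coefficients of chi(q) = a + b q + c q^2 (eV).
#' @return matrix with rownames = element symbols, columns a, b, c.
#' @export
peoe_params <- function() {
  if (!is.null(.midas_env$peoe)) return(.midas_env$peoe)
  f <- system.file("extdata", "peoe_params.csv", package = "midasqspr")
  d <- utils::read.csv(f, stringsAsFactors = FALSE)
  m <- as.matrix(d[, c("a", "b", "c")])
  rownames(m) <- d$element
  .midas_env$peoe <- m
  m
}
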