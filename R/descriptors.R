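# Descriptor names, local vertex invariants (LOVIs) and global descriptors.
#
# A descriptor name is an underscore-delimited token string, e.g.
#   I50_F_AB_nCi_2_M12_SS1_T_LGP[5]_s_MID
# position: 1 aggregator; 2 algebraic form (F linear, B bilinear,
# Q quadratic); 3-4 flags (recorded verbatim); 5 tuple order; 6 metric;
# 7 normalization + matrix power; 8 scope (T total, L local); 9 cutoff;
# 10 weight property id(s), hyphen-separated; 11 literal suffix MID.

AGGREGATOR_TOKENS <- c("S", "GM", "VC", "I50", "AM", "N1", "N2", "MAX", "MIN", "V", "RA")

#' Parse a descriptor name into its specification
#'
#' @param name descriptor name string.
#' @return object of class `"descriptor_spec"`: aggregator, form, flags,
#'   tuple_order, metric_id, normalization, power, scope, cutoff, weights,
#'   and the canonical `name`.
#' @export
parse_descriptor_name <- function(name) {
  name <- gsub("–", "-", name)  # tolerate en dashes in windows
  tok <- strsplit(name, "_", fixed = TRUE)[[1]]
  if (length(tok) != 11L) {
    stop("descriptor name must have 11 underscore-delimited tokens, got ",
         length(tok), " in '", name, "'")
  }
  perr <- function(pos, what) {
    stop("descriptor '", name, "': unknown ", what, " token '", tok[pos],
         "' at position ", pos)
  }
  if (!tok[1] %in% AGGREGATOR_TOKENS) perr(1, "aggregator")
  form <- switch(tok[2], F = "linear", B = "bilinear", Q = "quadratic", perr(2, "form"))
  # positions 3-4: atom-based / non-chiral flags, preserved verbatim
  if (!tok[3] %in% c("AB")) perr(3, "flag")
  if (!tok[4] %in% c("nCi")) perr(4, "flag")
  ord <- suppressWarnings(as.integer(tok[5]))
  if (is.na(ord) || !ord %in% 2:4) perr(5, "tuple order")
  metric_id <- tok[6]
  # validate the metric token now so a bad name fails at parse time
  tryCatch(resolve_metric(metric_id), error = function(e) perr(6, "metric"))
  nm <- regmatches(tok[7], regexec("^(NS|SS|DS|MP)([0-9]+)?$", tok[7]))[[1]]
  if (length(nm) < 2L) perr(7, "normalization")
  normalization <- nm[2]
  power <- if (nzchar(nm[3])) as.integer(nm[3]) else 1L
  scope <- switch(tok[8], T = "total", L = "local", perr(8, "scope"))
  cutoff <- parse_cutoff_token(tok[9], name, 9L)
  weights <- strsplit(tok[10], "-", fixed = TRUE)[[1]]
  if (!all(weights %in% PROPERTY_IDS)) perr(10, "weight property")
  nw <- length(weights)
  if (form == "bilinear" && nw != 2L) {
    stop("descriptor '", name, "': bilinear form needs exactly 2 weights, got ", nw)
  }
  if (form != "bilinear" && nw != 1L) {
    stop("descriptor '", name, "': ", form, " form needs exactly 1 weight, got ", nw)
  }
  if (tok[11] != "MID") perr(11, "suffix")
  spec <- structure(
    list(aggregator = tok[1], form = form, flags = tok[3:4],
         tuple_order = ord, metric_id = metric_id,
         normalization = normalization, power = power, scope = scope,
         cutoff = cutoff, weights = weights),
    class = "descriptor_spec"
  )
  spec$name <- format_descriptor_spec(spec)
  spec
}

parse_cutoff_token <- function(tk, name, pos) {
  if (tk == "KA") return(cutoff_scheme("KA"))
  m <- regmatches(tk, regexec("^LGP\\[([0-9]+)\\]$", tk))[[1]]
  if (length(m) == 2L) return(cutoff_scheme("LGP", lag_max = as.integer(m[2])))
  m <- regmatches(tk, regexec("^LGL\\[([0-9.]+)-([0-9.]+)\\]$", tk))[[1]]
  if (length(m) == 3L) {
    return(cutoff_scheme("LGL", window = c(as.numeric(m[2]), as.numeric(m[3]))))
  }
  if (grepl("^ANG", tk)) {
    stop("descriptor '", name, "': angular cutoff '", tk, "' is recognized but not implemented")
  }
  stop("descriptor '", name, "': unknown cutoff token '", tk, "' at position ", pos)
}

#' Format a descriptor specification back into its canonical name
#' @param spec a `descriptor_spec`.
#' @export
format_descriptor_spec <- function(spec) {
  form_tok <- switch(spec$form, linear = "F", bilinear = "B", quadratic = "Q")
  norm_tok <- paste0(spec$normalization, spec$power)
  scope_tok <- switch(spec$scope, total = "T", local = "L")
  paste(spec$aggregator, form_tok, spec$flags[1], spec$flags[2],
        spec$tuple_order, spec$metric_id, norm_tok, scope_tok,
        format_cutoff(spec$cutoff), paste(spec$weights, collapse = "-"),
        "MID", sep = "_")
}

#' @export
print.descriptor_spec <- function(x, ...) {
  cat("<descriptor_spec>", x$name, "\n")
  invisible(x)
}

#' Build the weighted molecular vector for one atomic property
#'
#' @param mol a [molecule()].
#' @param property_id one of [PROPERTY_IDS]; `"c"` triggers a (cached) PEOE
#'   charge computation with default settings.
#' @param tables property table set.
#' @param charge_cache environment used to cache per-molecule charges.
#' @return numeric vector in atom order.
#' @export
build_weight_vector <- function(mol, property_id, tables = atomic_property_tables(),
                                charge_cache = NULL) {
  if (!property_id %in% PROPERTY_IDS) {
    stop("unknown property id '", property_id, "'")
  }
  if (property_id == "c") {
    if (!is.null(charge_cache)) {
      key <- mol$id
      if (!is.null(charge_cache[[key]])) return(charge_cache[[key]])
      q <- gasteiger_charges(mol)
      charge_cache[[key]] <- q
      return(q)
    }
    return(gasteiger_charges(mol))
  }
  vapply(mol$elements, property_lookup, numeric(1),
         property_id = property_id, tables = tables, USE.NAMES = FALSE)
}

# processed structural matrix/tensor: canonical frame -> metric -> cutoff ->
# normalization -> power. The canonical frame makes frame-dependent metrics
# (Minkowski p != 2, Chebyshev) invariant under rigid motion of the input.
processed_matrix <- function(mol, spec, graph = NULL) {
  mol <- canonicalize_molecule(mol)
  M <- if (spec$tuple_order == 2L) pair_matrix(mol, spec$metric_id)
       else tuple_tensor(mol, spec$tuple_order, spec$metric_id)
  if (spec$cutoff$kind != "KA") {
    if (spec$cutoff$kind == "LGP" && is.null(graph)) graph <- bond_graph(mol)
    M <- apply_cutoff(M, spec$cutoff, graph = graph, mol = mol)
  }
  zr <- if (spec$cutoff$kind == "KA") "error" else "keep"
  normalize_matrix(M, spec$normalization, power = spec$power, zero_rows = zr)
}

#' Local vertex invariants of a molecule under a descriptor specification
#'
#' With the processed matrix/tensor g, the per-atom values are
#' linear: `L_i = sum_j g(i,j) x_j` (unit probe row);
#' quadratic: `L_i = x_i sum_j g(i,j) x_j`;
#' bilinear: `L_i = x_i sum_j g(i,j) y_j`.
#' For orders 3 and 4 the inner sums run over the remaining tuple indices
#' with the second weight vector applied at every non-leading position.
#' The LOVIs always sum to the full algebraic form value.
#'
#' @param mol a [molecule()].
#' @param spec a `descriptor_spec` (or a name string).
#' @param tables property table set.
#' @param graph optional [bond_graph()] (needed for LGP cutoffs; computed on
#'   demand).
#' @return numeric per-atom vector with attribute `"spec"`.
#' @export
compute_lovis <- function(mol, spec, tables = atomic_property_tables(), graph = NULL) {
  if (is.character(spec)) spec <- parse_descriptor_name(spec)
  stopifnot(inherits(mol, "molecule"), inherits(spec, "descriptor_spec"))
  if (spec$scope == "local") {
    stop("local-scope descriptors are represented in the grammar but not implemented")
  }
  if (mol$n_atoms < spec$tuple_order) {
    stop("molecule '", mol$id, "' has ", mol$n_atoms,
         " atoms; tuple order ", spec$tuple_order, " requires at least that many")
  }
  x <- build_weight_vector(mol, spec$weights[1], tables)
  y <- if (spec$form == "bilinear") build_weight_vector(mol, spec$weights[2], tables) else x
  M <- processed_matrix(mol, spec, graph)
  n <- mol$n_atoms
  ord <- spec$tuple_order
  # inner_i = sum over non-leading tuple indices of g * (weight at each slot)
  inner_with <- function(w) {
    if (ord == 2L) {
      as.numeric(M$entries %*% w)
    } else {
      flat <- matrix(M$entries, nrow = n)
      wprod <- w
      for (d in seq_len(ord - 2L)) wprod <- as.vector(outer(wprod, w))
      as.numeric(flat %*% wprod)
    }
  }
  L <- switch(spec$form,
    linear    = inner_with(x),
    quadratic = x * inner_with(x),
    bilinear  = x * inner_with(y))
  attr(L, "spec") <- spec
  L
}

#' Aggregate LOVIs into a global descriptor value
#'
#' `S` sum; `AM` arithmetic mean; `GM` geometric mean of absolute values
#' (0 when any LOVI is 0); `VC` variation coefficient sd/|mean| (NaN when
#' the mean is 0); `I50` median; `N1`/`N2` Minkowski 1- and 2-norms;
#' `MAX`/`MIN`; `V` sample variance; `RA` range.
#'
#' @param L numeric LOVI vector.
#' @param aggregator aggregator token.
#' @export
aggregate_lovis <- function(L, aggregator) {
  if (!length(L)) stop("empty LOVI vector")
  switch(aggregator,
    S   = sum(L),
    AM  = mean(L),
    GM  = if (any(L == 0)) 0 else exp(mean(log(abs(L)))),
    VC  = if (mean(L) == 0) NaN else stats::sd(L) / abs(mean(L)),
    I50 = stats::median(L),
    N1  = sum(abs(L)),
    N2  = sqrt(sum(L^2)),
    MAX = max(L),
    MIN = min(L),
    V   = stats::var(L),
    RA  = diff(range(L)),
    stop("unknown aggregator token '", aggregator, "'")
  )
}

#' Compute one global descriptor value for one molecule
#' @inheritParams compute_lovis
#' @export
compute_descriptor <- function(mol, spec, tables = atomic_property_tables(), graph = NULL) {
  if (is.character(spec)) spec <- parse_descriptor_name(spec)
  aggregate_lovis(compute_lovis(mol, spec, tables, graph), spec$aggregator)
}

#' Descriptor table for a set of molecules
#'
#' One row per molecule, one column per descriptor name. Per-cell failures
#' are recorded as `NA` with the reason collected in the `"failures"`
#' attribute (a data frame of molecule, descriptor, message) rather than
#' silently zeroed.
#'
#' @param mols list of [molecule()]s.
#' @param specs character vector of descriptor names, or list of parsed specs.
#' @param tables property table set.
#' @return numeric matrix with molecule ids as rownames and descriptor names
#'   as colnames.
#' @export
descriptor_table <- function(mols, specs, tables = atomic_property_tables()) {
  if (is.character(specs)) specs <- lapply(specs, parse_descriptor_name)
  ids <- vapply(mols, function(m) m$id, character(1))
  cn <- vapply(specs, function(s) s$name, character(1))
  out <- matrix(NA_real_, length(mols), length(specs), dimnames = list(ids, cn))
  fails <- list()
  for (i in seq_along(mols)) {
    graph <- NULL
    needs_graph <- any(vapply(specs, function(s) s$cutoff$kind == "LGP", logical(1)))
    if (needs_graph) graph <- bond_graph(mols[[i]])
    for (j in seq_along(specs)) {
      val <- tryCatch(compute_descriptor(mols[[i]], specs[[j]], tables, graph),
                      error = function(e) {
                        fails[[length(fails) + 1L]] <<-
                          data.frame(molecule = ids[i], descriptor = cn[j],
                                     message = conditionMessage(e))
                        NA_real_
                      })
      out[i, j] <- val
    }
  }
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else NULL
  out
}
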