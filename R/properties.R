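# Atomic property tables and scalar reactivity indices.
#
# The ten weighting properties are: m (atomic mass, amu), v (van der Waals
# volume, A^3), p (polarizability, A^3), e (Pauling electronegativity),
# a (element-level logP contribution), c (Gasteiger-Marsili charge, e;
# molecule-dependent, see gasteiger_charges()), psa (polar surface area
# contribution, A^2), r (molar refractivity), h (hardness, eV) and
# s (softness, 1/eV, tabulated as 1/h).

.midas_env <- new.env(parent = emptyenv())

#' Property identifiers accepted as molecular-vector weights
#' @export
PROPERTY_IDS <- c("m", "v", "p", "e", "a", "c", "psa", "r", "h", "s")

#' Load the atomic property tables shipped with the package
#'
#' Each property is a CSV with header `element,value` under
#' `inst/extdata/atomic_properties/`. Tables are read once and cached.
#' User-supplied directories with the same layout can replace the default.
#'
#' @param dir directory of `<property_id>.csv` files; default is the
#'   package's shipped table set.
#' @return named list of named numeric vectors, one per property id.
#' @export
atomic_property_tables <- function(dir = NULL) {
  if (is.null(dir)) {
    if (!is.null(.midas_env$prop_tables)) return(.midas_env$prop_tables)
    dir <- system.file("extdata", "atomic_properties", package = "midasqspr")
  }
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no property tables found in ", dir)
  tabs <- lapply(files, function(f) {
    d <- utils::read.csv(f, stringsAsFactors = FALSE)
    stats::setNames(d$value, d$element)
  })
  names(tabs) <- sub("\\.csv$", "", basename(files))
  if (is.null(.midas_env$prop_tables) &&
      identical(dir, system.file("extdata", "atomic_properties", package = "midasqspr"))) {
    .midas_env$prop_tables <- tabs
  }
  tabs
}

#' Look up a tabulated atomic property value
#'
#' Property `c` (the Gasteiger-Marsili charge) is molecule-dependent and must
#' be requested through [gasteiger_charges()]; asking the table for it is an
#' error.
#'
#' @param element element symbol.
#' @param property_id one of [PROPERTY_IDS] except `"c"`.
#' @param tables table set from [atomic_property_tables()].
#' @return scalar property value.
#' @export
property_lookup <- function(element, property_id, tables = atomic_property_tables()) {
  if (!property_id %in% PROPERTY_IDS) {
    stop("unknown property id '", property_id, "'; expected one of: ",
         paste(PROPERTY_IDS, collapse = ", "))
  }
  if (property_id == "c") {
    stop("property 'c' (Gasteiger charge) is molecule-dependent; use gasteiger_charges()")
  }
  tab <- tables[[property_id]]
  if (is.null(tab)) stop("no table loaded for property '", property_id, "'")
  v <- tab[element]
  if (is.na(v)) {
    stop("no tabulated value for element '", element, "', property '", property_id, "'")
  }
  unname(v)
}

#' Covalent radii table (Angstrom)
#' @return named numeric vector element -> covalent radius.
#' @export
covalent_radii <- function() {
  if (!is.null(.midas_env$rcov)) return(.midas_env$rcov)
  f <- system.file("extdata", "covalent_radii.csv", package = "midasqspr")
  d <- utils::read.csv(f, stringsAsFactors = FALSE)
  .midas_env$rcov <- stats::setNames(d$value, d$element)
  .midas_env$rcov
}

#' Electrophilicity index from electronegativity and hardness
#'
#' The conceptual-DFT electrophilicity omega = mu^2 / (2 eta) with chemical
#' potential mu = -chi, i.e. chi^2 / (2 eta). Both inputs in eV; the result
#' is in eV.
#'
#' @param chi Mulliken electronegativity, eV.
#' @param eta chemical hardness, eV; must be positive.
#' @return electrophilicity in eV.
#' @export
electrophilicity <- function(chi, eta) {
  if (any(eta <= 0)) stop("hardness eta must be positive")
  chi^2 / (2 * eta)
}

#' Error metrics between calculated and reference geometric parameters
#'
#' Mean unsigned error, mean signed error, and average relative error in
#' percent over M matched parameters (bond lengths, angles, ...):
#' MUE = mean |Pc - Pr|, MSE = mean (Pc - Pr),
#' %Er = 100 * mean |Pc - Pr| / |Pr| (per-parameter relative errors,
#' averaged).
#'
#' @param calc numeric vector of calculated parameter values.
#' @param ref numeric vector of reference values, same length, all nonzero.
#' @return list with `MUE`, `MSE`, `pct_Er`.
#' @export
geometry_error_metrics <- function(calc, ref) {
  if (length(calc) != length(ref)) stop("calc and ref must have the same length")
  if (length(ref) < 1L) stop("need at least one parameter")
  if (any(ref == 0)) stop("reference values must be nonzero for the relative error")
  d <- calc - ref
  list(MUE = mean(abs(d)), MSE = mean(d), pct_Er = 100 * mean(abs(d) / abs(ref)))
}
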