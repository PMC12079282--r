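#' Recognized element symbols (IUPAC periodic table)
#' @export
ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu")

#' Construct a molecule from element labels and Cartesian coordinates
#'
#' A molecule is the unit every descriptor in this package consumes: an
#' ordered, element-labeled 3D point set with a total charge. Atom order is
#' stable and defines all vector, matrix and tensor indexing downstream.
#'
#' @param elements character vector of element symbols (e.g. `"C"`, `"Ru"`).
#' @param coords numeric matrix with one row per atom and columns x, y, z,
#'   in Angstrom.
#' @param id molecule identifier string.
#' @param total_charge integer total molecular charge, in elementary charges.
#' @param formal_charges optional integer vector of per-atom formal charges;
#'   defaults to zeros.
#'
#' @return An object of class `"molecule"`: a list with elements `id`,
#'   `elements`, `coords`, `total_charge`, `formal_charges`, `n_atoms`.
#' @export
molecule <- function(elements, coords, id = "mol", total_charge = 0L,
                     formal_charges = NULL) {
  elements <- as.character(elements)
  coords <- as.matrix(coords)
  if (length(elements) < 1L) stop("a molecule needs at least one atom")
  if (!is.numeric(coords) || ncol(coords) != 3L ||
      nrow(coords) != length(elements)) {
    stop("`coords` must be a numeric n x 3 matrix matching `elements`")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  bad <- !elements %in% ELEMENT_SYMBOLS
  if (any(bad)) {
    stop("unrecognized element symbol(s): ", paste(unique(elements[bad]), collapse = ", "))
  }
  if (is.null(formal_charges)) formal_charges <- integer(length(elements))
  if (length(formal_charges) != length(elements)) {
    stop("`formal_charges` must have one entry per atom")
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(id = as.character(id), elements = elements, coords = coords,
         total_charge = as.integer(total_charge),
         formal_charges = as.integer(formal_charges),
         n_atoms = length(elements)),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule>", x$id, "-", x$n_atoms, "atoms, charge", x$total_charge, "\n")
  cat(" elements:", paste(x$elements, collapse = " "), "\n")
  invisible(x)
}

#' Read a 3D molecular structure from XYZ or SDF/MOL text
#'
#' Supports the plain two-line-header XYZ format and SDF/MOL V2000 with 3D
#' coordinates. Coordinates are always interpreted as Angstrom; atoms keep
#' file order. For SDF, formal charges are taken from the atom-block charge
#' code and any `M  CHG` lines; the total charge is their sum. For XYZ a
#' `charge=<n>` token in the comment line is honored, else the charge is 0.
#'
#' @param source path to a file, or a character vector of lines.
#' @param format `"xyz"` or `"sdf"`. Guessed from the file extension when
#'   `source` is a path and `format` is missing.
#' @param id molecule id; defaults to the structure's title line when
#'   non-empty.
#' @return A [molecule()].
#' @export
read_structure <- function(source, format = c("xyz", "sdf"), id = NULL) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    if (missing(format)) {
      ext <- tolower(tools::file_ext(source))
      format <- if (ext %in% c("sdf", "mol")) "sdf" else "xyz"
    }
    lines <- readLines(source, warn = FALSE)
  } else if (length(source) == 1L) {
    lines <- strsplit(source, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- source  # already one element per line; keep empty lines intact
  }
  format <- match.arg(format)
  switch(format, xyz = parse_xyz(lines, id), sdf = parse_sdf(lines, id))
}

parse_xyz <- function(lines, id = NULL) {
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3L) stop("XYZ input too short (line 1)")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) stop("XYZ line 1: invalid atom count")
  comment <- if (length(lines) >= 2L) lines[2L] else ""
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) {
    stop(sprintf("XYZ declares %d atoms but only %d atom lines found (line %d)",
                 n, length(body), length(lines) + 1L))
  }
  body <- body[seq_len(n)]
  toks <- strsplit(trimws(body), "\\s+")
  el <- vapply(toks, `[[`, character(1), 1L)
  xyz <- t(vapply(toks, function(tk) {
    if (length(tk) < 4L) stop("XYZ atom line with fewer than 4 fields")
    suppressWarnings(as.numeric(tk[2:4]))
  }, numeric(3)))
  if (any(is.na(xyz))) stop("XYZ: non-numeric coordinate field")
  chg <- 0L
  m <- regmatches(comment, regexec("charge=(-?[0-9]+)", comment))[[1]]
  if (length(m) == 2L) chg <- as.integer(m[2L])
  if (is.null(id)) {
    id <- trimws(sub("charge=-?[0-9]+", "", comment))
    if (!nzchar(id)) id <- "mol"
  }
  molecule(el, xyz, id = id, total_charge = chg)
}

parse_sdf <- function(lines, id = NULL) {
  if (length(lines) < 5L) stop("SDF input too short (line 1)")
  counts <- lines[4L]
  n_at <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  if (is.na(n_at)) stop("SDF line 4: cannot read atom count from counts line")
  if (n_at < 1L) stop("SDF line 4: no atoms")
  if (length(lines) < 4L + n_at) {
    stop(sprintf("SDF declares %d atoms but atom block is truncated (line %d)",
                 n_at, length(lines)))
  }
  at_lines <- lines[4L + seq_len(n_at)]
  xyz <- matrix(NA_real_, n_at, 3L)
  el <- character(n_at)
  fc <- integer(n_at)
  # old-style atom-block charge codes: 1..7 excluding 4 map to +3..-3
  chg_code <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  for (i in seq_len(n_at)) {
    ln <- at_lines[i]
    x <- suppressWarnings(as.numeric(substr(ln, 1L, 10L)))
    y <- suppressWarnings(as.numeric(substr(ln, 11L, 20L)))
    z <- suppressWarnings(as.numeric(substr(ln, 21L, 30L)))
    if (anyNA(c(x, y, z))) {
      # fall back to whitespace tokens (some writers do not pad columns)
      tk <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(tk) < 4L) stop(sprintf("SDF atom line %d malformed (line %d)", i, 4L + i))
      x <- as.numeric(tk[1L]); y <- as.numeric(tk[2L]); z <- as.numeric(tk[3L])
      el[i] <- tk[4L]
      if (length(tk) >= 6L) {
        cc <- chg_code[tk[6L]]
        if (!is.na(cc)) fc[i] <- cc
      }
    } else {
      el[i] <- trimws(substr(ln, 31L, 34L))
      cc <- suppressWarnings(as.integer(substr(ln, 37L, 39L)))
      if (!is.na(cc) && as.character(cc) %in% names(chg_code)) fc[i] <- chg_code[as.character(cc)]
    }
    xyz[i, ] <- c(x, y, z)
  }
  # M  CHG lines override atom-block codes for the atoms they name
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    fc[] <- 0L
    for (cl in chg_lines) {
      tk <- as.integer(strsplit(trimws(sub("^M  CHG", "", cl)), "\\s+")[[1]])
      npair <- tk[1L]
      for (p in seq_len(npair)) {
        fc[tk[2L * p]] <- tk[2L * p + 1L]
      }
    }
  }
  if (all(xyz[, 3L] == 0) && n_at > 3L && !any(grepl("3D", lines[2L]))) {
    dim_flag <- substr(lines[2L], 21L, 22L)
    if (identical(toupper(trimws(dim_flag)), "2D")) {
      stop("SDF declares 2D coordinates (line 2); 3D required")
    }
  }
  if (is.null(id)) {
    id <- trimws(lines[1L])
    if (!nzchar(id)) id <- "mol"
  }
  molecule(el, xyz, id = id, total_charge = sum(fc), formal_charges = fc)
}

#' Write a molecule as XYZ text
#'
#' @param mol a [molecule()].
#' @param path optional file path; when `NULL` the lines are returned.
#' @return Invisibly, the character vector of XYZ lines.
#' @export
write_xyz <- function(mol, path = NULL) {
  stopifnot(inherits(mol, "molecule"))
  comment <- mol$id
  if (mol$total_charge != 0L) comment <- paste0(comment, " charge=", mol$total_charge)
  lines <- c(
    as.character(mol$n_atoms),
    comment,
    sprintf("%-3s %17.9f %17.9f %17.9f", mol$elements,
            mol$coords[, 1], mol$coords[, 2], mol$coords[, 3])
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Canonical molecular frame: centroid origin, principal axes
#'
#' Translates the molecule to its centroid and rotates it into the principal
#' axes of the coordinate covariance (eigenvalues descending). Axis signs
#' are fixed by the third moment of the projections (falling back to the
#' fifth moment), and the third axis is the cross product of the first two,
#' so the frame is a proper rotation and is independent of the input
#' orientation and of atom order. Frame-dependent pair metrics (Minkowski
#' with p != 2, Chebyshev) are evaluated in this frame by the descriptor
#' pipeline, which makes every descriptor invariant under rigid motion of
#' the input geometry.
#'
#' @param mol a [molecule()].
#' @return the molecule with canonicalized coordinates.
#' @export
canonicalize_molecule <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  C <- sweep(mol$coords, 2L, colMeans(mol$coords))
  if (mol$n_atoms >= 2L) {
    ev <- eigen(crossprod(C) / mol$n_atoms, symmetric = TRUE)
    V <- ev$vectors  # columns ordered by decreasing eigenvalue
    P <- C %*% V
    for (d in 1:2) {
      s3 <- sum(P[, d]^3)
      s <- if (abs(s3) > 1e-10) sign(s3) else {
        s5 <- sum(P[, d]^5)
        if (abs(s5) > 1e-10) sign(s5) else 1
      }
      V[, d] <- s * V[, d]
    }
    V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
                V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
                V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
    C <- C %*% V
  }
  mol$coords <- C
  dimnames(mol$coords) <- list(NULL, c("x", "y", "z"))
  mol
}

#' Interatomic Euclidean distance matrix of a molecule, in Angstrom
#' @param mol a [molecule()].
#' @return symmetric `n_atoms x n_atoms` matrix.
#' @export
distance_matrix <- function(mol) {
  as.matrix(stats::dist(mol$coords, method = "euclidean"))
}
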