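# The published 32-catalyst dataset and synthetic data generators.
#
# The catalyst records ship verbatim as a CSV fixture: 25 training and 7
# external-validation precursors with initial rates r0 in M s^-1, the
# catalyst metal, and the experimental conditions (carried as metadata
# only; the model is condition-free). Synthetic molecules are geometric
# point sets with element labels -- not chemically valid complexes -- which
# is sufficient for exercising metrics, normalizations, cutoffs and
# invariance properties.

#' The published catalyst rate dataset (32 records)
#'
#' @return data frame with columns entry, name, r0_Ms, kcat, split
#'   (train/test), metal (Ru/Rh/Os/Ir), P_atm, T_C, M_mM, Q_mM, solvent,
#'   ref. Entry numbering preserves the printed ids (the test entries jump
#'   to 37, 55, 59, 177-180).
#' @export
table1_fixture <- function() {
  f <- system.file("extdata", "catalyst_rates.csv", package = "midasqspr")
  d <- utils::read.csv(f, stringsAsFactors = FALSE)
  d$split <- factor(d$split, levels = c("train", "test"))
  d
}

#' Response vector from the catalyst dataset
#'
#' @param records data frame from [table1_fixture()].
#' @param response_sign +1 for log10(r0) (default), -1 for -log10(r0).
#' @return numeric vector named by entry id.
#' @export
catalyst_response <- function(records = table1_fixture(), response_sign = 1) {
  stats::setNames(response_sign * log10(records$r0_Ms), records$entry)
}

#' Random element-labeled 3D point molecules
#'
#' Atoms are placed uniformly in a cubic box with rejection until all
#' pairwise distances reach `min_dist`; optionally exactly one atom per
#' molecule is drawn from the metal palette (Ru/Rh/Os/Ir), mimicking an
#' organometallic precursor's single metal center.
#'
#' @param n_mol number of molecules.
#' @param atoms_range length-2 integer range of atom counts.
#' @param palette element symbols for non-metal atoms.
#' @param metals metal palette; used when `with_metal = TRUE`.
#' @param with_metal place exactly one metal atom per molecule.
#' @param box cubic box edge, Angstrom.
#' @param min_dist minimum pairwise distance, Angstrom.
#' @param seed integer seed.
#' @param max_tries rejection-sampling cap per molecule.
#' @return list of [molecule()]s.
#' @export
make_point_molecules <- function(n_mol, atoms_range = c(6L, 10L),
                                 palette = c("C", "H", "N", "O", "P", "Cl"),
                                 metals = c("Ru", "Rh", "Os", "Ir"),
                                 with_metal = FALSE, box = 6, min_dist = 1.0,
                                 seed = 20250430L, max_tries = 2000L) {
  set.seed(seed)
  lapply(seq_len(n_mol), function(m) {
    n_at <- sample(seq.int(atoms_range[1], atoms_range[2]), 1L)
    el <- sample(palette, n_at, replace = TRUE)
    if (with_metal) el[sample.int(n_at, 1L)] <- sample(metals, 1L)
    coords <- matrix(NA_real_, n_at, 3L)
    placed <- 0L
    tries <- 0L
    while (placed < n_at) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("placement failed after ", max_tries,
             " tries: min_dist ", min_dist, " infeasible in a ", box, " A box")
      }
      pt <- stats::runif(3, 0, box)
      if (placed == 0L ||
          all(sqrt(colSums((t(coords[seq_len(placed), , drop = FALSE]) - pt)^2)) >= min_dist)) {
        placed <- placed + 1L
        coords[placed, ] <- pt
      }
    }
    molecule(el, coords, id = sprintf("synth%03d", m))
  })
}

#' Random bonded chain molecules
#'
#' A self-avoiding random walk with bond steps of 1.4-1.8 Angstrom, so that
#' every atom has at least one neighbor at covalent range. Useful for
#' exercising lag (bond-count) cutoffs on connected graphs.
#'
#' @inheritParams make_point_molecules
#' @param step_range bond-length range, Angstrom.
#' @export
make_chain_molecules <- function(n_mol, atoms_range = c(6L, 10L),
                                 palette = c("C", "N", "O", "P"),
                                 metals = c("Ru", "Rh", "Os", "Ir"),
                                 with_metal = FALSE,
                                 step_range = c(1.4, 1.8), min_dist = 1.0,
                                 seed = 20250430L) {
  set.seed(seed)
  lapply(seq_len(n_mol), function(m) {
    n_at <- sample(seq.int(atoms_range[1], atoms_range[2]), 1L)
    el <- sample(palette, n_at, replace = TRUE)
    if (with_metal) el[sample.int(n_at, 1L)] <- sample(metals, 1L)
    coords <- matrix(0, n_at, 3L)
    for (i in seq.int(2L, n_at)) {
      repeat {
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        pt <- coords[i - 1L, ] + dir * stats::runif(1, step_range[1], step_range[2])
        d_prev <- sqrt(colSums((t(coords[seq_len(i - 1L), , drop = FALSE]) - pt)^2))
        if (all(d_prev >= min_dist)) break
      }
      coords[i, ] <- pt
    }
    molecule(el, coords, id = sprintf("chain%03d", m))
  })
}

#' Synthetic descriptor-response dataset with the study's geometry
#'
#' X columns are standard normal with a constant pairwise cross-correlation
#' `collinearity` (default 0.1, giving VIF close to 1, as observed for the
#' published model); the response is `y = beta0 + X beta + eps`,
#' `eps ~ N(0, noise_sd^2)` with `noise_sd = 0.21` log units by default --
#' the published model's residual standard error.
#'
#' @param n observations (study training size: 25).
#' @param k predictors (study: 4).
#' @param beta length `k + 1` coefficient vector (intercept first). The
#'   default `c(0, rep(0.28, k))` at the default noise and collinearity
#'   gives a generating R^2 of about 0.9 (signal variance
#'   0.28^2 * (k + k(k-1) * 0.1) ~ 0.41 against noise variance 0.21^2),
#'   matching the study's fit quality.
#' @param noise_sd residual standard deviation, log units.
#' @param collinearity constant pairwise correlation of the X columns,
#'   in [0, 1).
#' @param seed integer seed.
#' @return list with `X`, `y`, `beta`, `noise_sd`.
#' @export
make_linear_qspr <- function(n = 25L, k = 4L, beta = c(0, rep(0.28, k)),
                             noise_sd = 0.21, collinearity = 0.1,
                             seed = 20250430L) {
  if (n <= k + 2L) stop("need n > k + 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (collinearity < 0 || collinearity >= 1) stop("collinearity must be in [0, 1)")
  if (length(beta) != k + 1L) stop("beta must have k + 1 entries (intercept first)")
  set.seed(seed)
  Sigma <- matrix(collinearity, k, k); diag(Sigma) <- 1
  Z <- matrix(stats::rnorm(n * k), n, k)
  X <- Z %*% chol(Sigma)
  colnames(X) <- paste0("D", seq_len(k))
  y <- beta[1] + as.numeric(X %*% beta[-1]) + stats::rnorm(n, 0, noise_sd)
  list(X = X, y = y, beta = beta, noise_sd = noise_sd)
}

#' Wide descriptor pool with planted signal columns
#'
#' Only `n_informative` flagged columns enter the generating model; the
#' rest are noise. Returns the planted indices so subset-selection tests
#' can assert recovery.
#'
#' @param n_cols pool width.
#' @param n_informative number of signal columns.
#' @param n observations.
#' @param noise_sd residual standard deviation.
#' @param beta_signal coefficient given to each informative column.
#' @param seed integer seed.
#' @return list with `X`, `y`, `true_idx`.
#' @export
ga_pool_fixture <- function(n_cols = 50L, n_informative = 4L, n = 100L,
                            noise_sd = 0.2, beta_signal = 1,
                            seed = 20250430L) {
  if (n_informative > n_cols) stop("n_informative must not exceed n_cols")
  if (n <= n_informative + 2L) stop("need n > n_informative + 2")
  set.seed(seed)
  X <- matrix(stats::rnorm(n * n_cols), n, n_cols)
  colnames(X) <- paste0("V", seq_len(n_cols))
  true_idx <- sort(sample.int(n_cols, n_informative))
  y <- as.numeric(X[, true_idx, drop = FALSE] %*% rep(beta_signal, n_informative)) +
    stats::rnorm(n, 0, noise_sd)
  list(X = X, y = y, true_idx = true_idx)
}
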