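#' Genetic-algorithm descriptor subset selection
#'
#' Fixed-size subset chromosomes evolved with tournament selection, uniform
#' crossover, per-gene mutation and single-elitism; the fitness is the
#' leave-one-out Q^2 of the OLS model on the training rows only. The study
#' ran 1000 generations with a population of 10,000 models, mutation 1% and
#' crossover 50%; the defaults here are desk-scale (100 x 200) and the full
#' setting is reachable through the parameters.
#'
#' @param X_pool descriptor pool matrix (training rows).
#' @param y training response.
#' @param model_size number of descriptors per model.
#' @param generations number of generations.
#' @param pop_size population size.
#' @param mutation_rate per-gene mutation probability (study: 0.01).
#' @param crossover_rate per-pair crossover probability (study: 0.5).
#' @param tournament_k tournament size for parent selection.
#' @param X_test,y_test optional held-out rows; adds Q2_EXT to the output.
#' @param seed integer seed.
#' @return data frame of the final population, one row per model, sorted by
#'   fitness: descriptor indices `i1..i<model_size>`, `R2`, `Q2_LOO` (and
#'   `Q2_EXT`); attribute `"best_history"` holds the best fitness per
#'   generation (non-decreasing by elitism).
#' @export
ga_select <- function(X_pool, y, model_size = 4L, generations = 100L,
                      pop_size = 200L, mutation_rate = 0.01,
                      crossover_rate = 0.5, tournament_k = 2L,
                      X_test = NULL, y_test = NULL, seed = 20250430L) {
  X_pool <- as.matrix(X_pool)
  n_cols <- ncol(X_pool)
  n <- nrow(X_pool)
  if (model_size > n_cols) stop("model_size exceeds the descriptor pool width")
  if (n <= model_size + 2L) stop("too few training rows for model_size (need n > k + 2)")
  set.seed(seed)

  fitness_of <- function(chrom) {
    tryCatch(q2_loo(X_pool[, chrom, drop = FALSE], y), error = function(e) -Inf)
  }
  random_chrom <- function() sort(sample.int(n_cols, model_size))
  repair <- function(chrom) {
    chrom <- unique(chrom)
    while (length(chrom) < model_size) {
      chrom <- unique(c(chrom, sample.int(n_cols, model_size - length(chrom))))
    }
    sort(chrom)
  }

  pop <- replicate(pop_size, random_chrom(), simplify = FALSE)
  fit <- vapply(pop, fitness_of, numeric(1))
  best_hist <- numeric(generations)

  for (g in seq_len(generations)) {
    elite_i <- which.max(fit)
    new_pop <- vector("list", pop_size)
    new_pop[[1L]] <- pop[[elite_i]]
    i <- 2L
    while (i <= pop_size) {
      pick <- function() {
        cand <- sample.int(pop_size, tournament_k)
        pop[[cand[which.max(fit[cand])]]]
      }
      p1 <- pick(); p2 <- pick()
      if (stats::runif(1) < crossover_rate) {
        mask <- stats::runif(model_size) < 0.5
        c1 <- ifelse(mask, p1, p2)
        c2 <- ifelse(mask, p2, p1)
      } else {
        c1 <- p1; c2 <- p2
      }
      mutate <- function(chrom) {
        hit <- which(stats::runif(model_size) < mutation_rate)
        if (length(hit)) chrom[hit] <- sample.int(n_cols, length(hit))
        repair(chrom)
      }
      new_pop[[i]] <- mutate(c1)
      if (i + 1L <= pop_size) new_pop[[i + 1L]] <- mutate(c2)
      i <- i + 2L
    }
    pop <- new_pop
    fit <- vapply(pop, fitness_of, numeric(1))
    best_hist[g] <- max(fit)
  }

  ord <- order(fit, decreasing = TRUE)
  pop <- pop[ord]; fit <- fit[ord]
  idx <- do.call(rbind, pop)
  colnames(idx) <- paste0("i", seq_len(model_size))
  r2 <- vapply(pop, function(ch) {
    tryCatch(ols_stats(X_pool[, ch, drop = FALSE], y)$r2, error = function(e) NA_real_)
  }, numeric(1))
  out <- data.frame(idx, R2 = r2, Q2_LOO = fit)
  if (!is.null(X_test)) {
    X_test <- as.matrix(X_test)
    out$Q2_EXT <- vapply(pop, function(ch) {
      tryCatch(q2_ext(fit_mlr(X_pool[, ch, drop = FALSE], y),
                      X_test[, ch, drop = FALSE], y_test),
               error = function(e) NA_real_)
    }, numeric(1))
  }
  attr(out, "best_history") <- best_hist
  out
}

#' Random train/test split robustness study
#'
#' Repeatedly splits the rows of a fixed descriptor matrix into training and
#' held-out parts, refits the model on each training part, and summarizes
#' R^2, Q2_LOO and Q2_EXT by medians and interquartile ranges. The study
#' ran 75,000 splits at the 25/7 geometry.
#'
#' @param X descriptor matrix (the model's fixed columns).
#' @param y response.
#' @param n_splits number of random splits.
#' @param train_n training-set size per split.
#' @param seed integer seed.
#' @return list with `summary` (data frame: metric, median, q25, q75),
#'   `raw` (n_splits x 3 matrix) and `n_skipped` (degenerate splits).
#' @export
random_split_study <- function(X, y, n_splits = 1000L, train_n = 25L,
                               seed = 20250430L) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (train_n <= k + 2L) stop("train_n must exceed k + 2")
  if (train_n >= n) stop("train_n must leave at least one held-out row")
  set.seed(seed)
  raw <- matrix(NA_real_, n_splits, 3L,
                dimnames = list(NULL, c("R2", "Q2_LOO", "Q2_EXT")))
  skipped <- 0L
  for (i in seq_len(n_splits)) {
    tr <- sample.int(n, train_n)
    te <- setdiff(seq_len(n), tr)
    if (stats::sd(y[tr]) == 0) { skipped <- skipped + 1L; next }
    res <- tryCatch({
      fit <- fit_mlr(X[tr, , drop = FALSE], y[tr])
      c(fit$R2,
        q2_loo(X[tr, , drop = FALSE], y[tr]),
        q2_ext(fit, X[te, , drop = FALSE], y[te]))
    }, error = function(e) NULL)
    if (is.null(res)) { skipped <- skipped + 1L; next }
    raw[i, ] <- res
  }
  ok <- stats::complete.cases(raw)
  summ <- do.call(rbind, lapply(colnames(raw), function(m) {
    v <- raw[ok, m]
    data.frame(metric = m, median = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)))
  }))
  list(summary = summ, raw = raw, n_skipped = skipped)
}
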