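# Applicability domain and virtual screening utilities: Williams plot
# quantities, neighborhood components analysis, local outlier factor,
# prediction with the packaged reference model, and the hydrogen-carrier
# capacity of a candidate formula.

#' Williams-plot applicability domain report
#'
#' Training leverages come from the hat diagonal of the fit; query leverages
#' are h0 = x0' (X'X)^-1 x0 with intercept-augmented rows. The leverage
#' threshold is the standard h* = 3 (k + 1) / n and the standardized
#' residual threshold is +/- 3.
#'
#' @param fit an `mlr_fit`.
#' @param X_query optional matrix of query rows (training columns).
#' @return list with `training` (data frame: leverage, std_residual,
#'   outlier, influential), `query` (data frame: leverage, influential), and
#'   thresholds `h_star`, `r_star`.
#' @export
williams_report <- function(fit, X_query = NULL) {
  stopifnot(inherits(fit, "mlr_fit"))
  n <- fit$n; k <- fit$k
  h_star <- 3 * (k + 1) / n
  r_star <- 3
  std_res <- fit$residuals / (fit$s * sqrt(1 - fit$hat))
  training <- data.frame(
    leverage = fit$hat,
    std_residual = std_res,
    outlier = abs(std_res) > r_star,
    influential = fit$hat > h_star
  )
  query <- NULL
  if (!is.null(X_query)) {
    X_query <- as.matrix(X_query)
    if (ncol(X_query) != k) stop("query columns must match the training design")
    Xa <- cbind(1, X_query)
    hq <- rowSums((Xa %*% fit$XtXinv) * Xa)
    query <- data.frame(leverage = hq, influential = hq > h_star)
  }
  list(training = training, query = query, h_star = h_star, r_star = r_star)
}

#' Tertile (quantile) activity classes from a response
#'
#' Quantile bins of the response used as class labels for the NCA
#' projection of the descriptor space.
#'
#' @param y numeric response.
#' @param n_bins number of quantile bins (default 3: low/mid/high activity).
#' @return integer factor of length `length(y)` with `n_bins` levels.
#' @export
activity_bins <- function(y, n_bins = 3L) {
  if (length(y) < n_bins) stop("need at least n_bins observations")
  if (stats::sd(y) == 0) stop("constant response: only one class")
  edges <- stats::quantile(y, probs = seq(0, 1, length.out = n_bins + 1L))
  edges[1L] <- -Inf; edges[length(edges)] <- Inf
  cut(y, breaks = unique(edges), labels = FALSE)
}

#' Neighborhood components analysis (NCA) projection
#'
#' Learns a `dim x p` linear transform A maximizing the stochastic-neighbor
#' leave-one-out classification objective: with d_ij = ||A z_i - A z_j||^2
#' and p_ij = softmax_j(-d_ij) over j != i, the objective is
#' sum_i sum_{j in class(i)} p_ij. Optimized by gradient ascent with
#' backtracking line search from an identity-block initialization, so the
#' objective is non-decreasing across accepted steps.
#'
#' @param X feature matrix (rows = observations).
#' @param labels class labels (>= 2 classes, each with >= 2 members).
#' @param dim projection dimension.
#' @param max_iter maximum accepted gradient steps.
#' @param tol stop when the objective gain falls below `tol`.
#' @param seed integer seed (API symmetry; the optimization is
#'   deterministic from the identity start).
#' @return list with `A` (the transform), `objective` (trace over accepted
#'   steps), `Z` (projected training data), and leave-one-out 1-NN
#'   accuracies `acc_before` / `acc_after`.
#' @export
nca_fit <- function(X, labels, dim = 2L, max_iter = 200L, tol = 1e-7,
                    seed = 20250430L) {
  X <- as.matrix(X)
  labels <- as.integer(factor(labels))
  n <- nrow(X); p <- ncol(X)
  if (dim > p) stop("projection dim exceeds the number of features")
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 classes")
  if (any(tab < 2L)) stop("singleton class: every class needs >= 2 members")
  # standardize columns so the identity start is scale-free
  mu <- colMeans(X); sdev <- apply(X, 2L, stats::sd)
  sdev[sdev == 0] <- 1
  Z0 <- sweep(sweep(X, 2L, mu), 2L, sdev, `/`)
  same <- outer(labels, labels, `==`); diag(same) <- FALSE

  objective_and_grad <- function(A) {
    Z <- Z0 %*% t(A)
    D2 <- as.matrix(stats::dist(Z))^2
    K <- exp(-(D2 - apply(D2 + diag(Inf, n), 1L, min)))  # row-shifted for stability
    diag(K) <- 0
    P <- K / rowSums(K)
    p_i <- rowSums(P * same)
    f <- sum(p_i)
    # gradient: 2 A sum_i [ p_i sum_j P_ij x_ij x_ij' - sum_{j~i} P_ij x_ij x_ij' ]
    W <- P * p_i - P * same
    Wsym <- W + t(W)
    L <- diag(rowSums(Wsym)) - Wsym
    G <- 2 * (A %*% t(Z0) %*% L %*% Z0)
    list(f = f, grad = G)
  }

  A <- diag(1, dim, p)
  og <- objective_and_grad(A)
  trace <- og$f
  step <- 0.1
  for (it in seq_len(max_iter)) {
    g <- og$grad
    gn <- sqrt(sum(g^2))
    if (gn < 1e-12) break
    accepted <- FALSE
    for (bt in 1:30) {
      A_new <- A + step * g / gn
      og_new <- objective_and_grad(A_new)
      if (og_new$f > og$f) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break
    if (og_new$f - og$f < tol) { A <- A_new; og <- og_new; trace <- c(trace, og$f); break }
    A <- A_new; og <- og_new
    trace <- c(trace, og$f)
    step <- step * 1.5
  }

  loo_1nn <- function(Z) {
    D <- as.matrix(stats::dist(Z)); diag(D) <- Inf
    pred <- labels[apply(D, 1L, which.min)]
    mean(pred == labels)
  }
  Z <- Z0 %*% t(A)
  list(A = A, objective = trace, Z = Z,
       acc_before = loo_1nn(Z0), acc_after = loo_1nn(Z),
       center = mu, scale = sdev)
}

#' Project new rows with a fitted NCA transform
#' @param nca result of [nca_fit()].
#' @param X new feature rows (training columns).
#' @export
nca_project <- function(nca, X) {
  X <- as.matrix(X)
  Z0 <- sweep(sweep(X, 2L, nca$center), 2L, nca$scale, `/`)
  Z0 %*% t(nca$A)
}

#' Local outlier factor (LOF) novelty scores
#'
#' Classic LOF with reachability distances: for each point, the ratio of the
#' average local reachability density of its k nearest reference neighbors
#' to its own. Scores near 1 indicate density-consistent points; scores
#' well above 1 indicate outliers. When `Z_query` is supplied, each query is
#' scored against the reference set only (the query never joins the
#' reference set).
#'
#' @param Z_train reference matrix (rows = points).
#' @param Z_query optional query matrix; default scores the reference points
#'   themselves (leave-self-out).
#' @param k_neighbors neighborhood size; must be < nrow(Z_train).
#' @return numeric LOF scores, one per scored point.
#' @export
lof_scores <- function(Z_train, Z_query = NULL, k_neighbors = 10L) {
  Z_train <- as.matrix(Z_train)
  n <- nrow(Z_train)
  if (k_neighbors >= n) stop("k_neighbors must be smaller than the reference set")
  if (k_neighbors < 1L) stop("k_neighbors must be >= 1")
  D <- as.matrix(stats::dist(Z_train)); diag(D) <- Inf

  kth <- function(v) sort(v, partial = k_neighbors)[k_neighbors]
  k_dist <- apply(D, 1L, kth)
  neigh <- lapply(seq_len(n), function(i) which(D[i, ] <= k_dist[i]))
  lrd <- vapply(seq_len(n), function(i) {
    nb <- neigh[[i]]
    reach <- pmax(k_dist[nb], D[i, nb])
    1 / mean(reach)
  }, numeric(1))

  score_point <- function(dvec) {
    kd <- kth(dvec)
    nb <- which(dvec <= kd)
    reach <- pmax(k_dist[nb], dvec[nb])
    lrd_q <- 1 / mean(reach)
    mean(lrd[nb]) / lrd_q
  }

  if (is.null(Z_query)) {
    vapply(seq_len(n), function(i) score_point(D[i, ]), numeric(1))
  } else {
    Z_query <- as.matrix(Z_query)
    vapply(seq_len(nrow(Z_query)), function(q) {
      dvec <- sqrt(colSums((t(Z_train) - Z_query[q, ])^2))
      score_point(dvec)
    }, numeric(1))
  }
}

#' Gravimetric hydrogen-carrying capacity of a carrier molecule
#'
#' 100 * n_H2 * M(H2) / (M(formula) + n_H2 * M(H2)), in percent by weight of
#' the hydrogenated carrier. Quinoline (C9H7N) with 5 H2 gives 7.2 %wt.
#'
#' @param formula named integer vector of element counts, e.g.
#'   `c(C = 9, H = 7, N = 1)`.
#' @param n_H2 number of H2 molecules stored per carrier molecule.
#' @return capacity in %wt H.
#' @export
h2_capacity <- function(formula, n_H2) {
  if (n_H2 < 0) stop("n_H2 must be >= 0")
  tabs <- atomic_property_tables()
  masses <- vapply(names(formula), function(el) property_lookup(el, "m", tabs),
                   numeric(1))
  m_mol <- sum(masses * as.numeric(formula))
  m_h2 <- 2 * property_lookup("H", "m", tabs)
  100 * n_H2 * m_h2 / (m_mol + n_H2 * m_h2)
}
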