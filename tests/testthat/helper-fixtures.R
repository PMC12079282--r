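# shared helpers: random rigid motions and brute-force reference
# implementations kept deliberately independent of the package's vectorized
# code paths

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

transform_molecule <- function(mol, R = diag(3), shift = c(0, 0, 0)) {
  molecule(mol$elements, mol$coords %*% t(R) + rep(shift, each = mol$n_atoms),
           id = mol$id, total_charge = mol$total_charge,
           formal_charges = mol$formal_charges)
}

permute_molecule <- function(mol, perm) {
  molecule(mol$elements[perm], mol$coords[perm, , drop = FALSE],
           id = mol$id, total_charge = mol$total_charge,
           formal_charges = mol$formal_charges[perm])
}

# brute-force N-tuple tensor: explicit nested loops, sum of pairwise
# Euclidean (or supplied) distances over the tuple, zero on repeated indices
brute_tuple_tensor <- function(coords, order, pfun = function(u, v) sqrt(sum((u - v)^2))) {
  n <- nrow(coords)
  T <- array(0, rep(n, order))
  idx <- as.matrix(expand.grid(rep(list(seq_len(n)), order)))
  for (r in seq_len(nrow(idx))) {
    tup <- idx[r, ]
    if (anyDuplicated(tup)) next
    s <- 0
    for (a in seq_len(order - 1)) {
      for (b in seq.int(a + 1, order)) {
        s <- s + pfun(coords[tup[a], ], coords[tup[b], ])
      }
    }
    T[matrix(tup, 1)] <- s
  }
  T
}

# explicit leave-one-out refits (the slow oracle for the PRESS identity)
brute_q2_loo <- function(X, y) {
  n <- nrow(X)
  press <- 0
  for (i in seq_len(n)) {
    d <- data.frame(y = y[-i], X[-i, , drop = FALSE])
    f <- lm(y ~ ., data = d)
    yhat <- unname(predict(f, newdata = data.frame(X[i, , drop = FALSE])))
    press <- press + (y[i] - yhat)^2
  }
  1 - press / sum((y - mean(y))^2)
}

# hand-coded PEOE iteration, written independently of the package internals
brute_peoe <- function(elements, bonds, n_iter = 6, damping = 0.5,
                       q0 = rep(0, length(elements))) {
  pars <- list(H = c(7.17, 6.24, -0.56), F = c(14.66, 13.85, 2.31),
               C = c(7.98, 9.18, 1.88), N = c(11.54, 10.82, 1.36),
               O = c(14.18, 12.92, 1.39))
  q <- q0
  for (k in seq_len(n_iter)) {
    chi <- sapply(seq_along(elements), function(i) {
      p <- pars[[elements[i]]]
      p[1] + p[2] * q[i] + p[3] * q[i]^2
    })
    dq <- rep(0, length(elements))
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      if (chi[i] == chi[j]) next
      donor <- if (chi[i] < chi[j]) i else j
      accept <- if (donor == i) j else i
      chi_plus <- sum(pars[[elements[donor]]])
      amt <- (chi[accept] - chi[donor]) / chi_plus * damping^k
      dq[donor] <- dq[donor] + amt
      dq[accept] <- dq[accept] - amt
    }
    q <- q + dq
  }
  q
}
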