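test_that("bond graph edges follow covalent radii and lags count bonds", {
  hh <- read_structure(c("2", "", "H 0 0 0", "H 0 0 0.74"), "xyz")
  g <- bond_graph(hh, tolerance = 0.3)  # 2 * 0.31 * 1.3 = 0.806 >= 0.74
  expect_true(g$adjacency[1, 2])

  far <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_false(bond_graph(far)$adjacency[1, 2])
  expect_equal(bond_graph(far)$lag[1, 2], Inf)

  chain <- molecule(c("C", "C", "C"),
                    rbind(c(0, 0, 0), c(1.5, 0, 0), c(3.0, 0, 0)))
  g3 <- bond_graph(chain)
  expect_equal(g3$lag[1, 3], 2)
  expect_true(isSymmetric(g3$lag))
  expect_equal(diag(g3$lag), rep(0, 3))
})

test_that("pair matrices reproduce the 3-4-5 metric examples", {
  m <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(pair_matrix(m, "M2")$entries[1, 2], 5)
  expect_equal(pair_matrix(m, "CH")$entries[1, 2], 4)
  expect_equal(pair_matrix(m, "M1")$entries[1, 2], 7)
  # fractional-order grammar: M15 -> p = 1.5
  expect_equal(pair_matrix(m, "M15")$entries[1, 2],
               (3^1.5 + 4^1.5)^(1 / 1.5))
  expect_error(pair_matrix(m, "ZZ"), "registry")
  expect_error(pair_matrix(m, "BH"), "no formula")
})

test_that("Chebyshev is the large-p Minkowski limit", {
  # exact sandwich: d_cheb <= d_p <= d_cheb * 3^(1/p); at p = 64 the gap is
  # below 2% of d_cheb always, and below 1e-3 once the second-largest
  # component ratio is modest
  set.seed(5)
  for (i in 1:100) {
    co <- matrix(runif(6, -4, 4), 2, 3)
    dch <- midasqspr:::chebyshev_distances(co)[1, 2]
    dmk <- midasqspr:::minkowski_distances(co, 64)[1, 2]
    expect_gte(dmk, dch - 1e-12)
    expect_lte(dmk, dch * 3^(1 / 64) + 1e-12)
    r <- sort(abs(co[1, ] - co[2, ]), decreasing = TRUE)
    if (r[2] / r[1] < 0.85) expect_lt(abs(dch - dmk), 1e-3)
  }
  # and the gap vanishes as p grows
  co <- matrix(c(0, 0, 0, 3, 2.9, 1), 2, 3, byrow = TRUE)
  gaps <- sapply(c(16, 64, 256, 1024), function(p) {
    midasqspr:::minkowski_distances(co, p)[1, 2] -
      midasqspr:::chebyshev_distances(co)[1, 2]
  })
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[4], 1e-3)
})

test_that("tuple tensors equal the sum-of-pairs on closed-form geometries", {
  tri <- molecule(c("C", "C", "C"),
                  rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)))
  T3 <- tuple_tensor(tri, 3)$entries
  expect_equal(T3[1, 2, 3], 3)
  expect_equal(T3[3, 1, 2], 3)
  expect_equal(T3[1, 1, 2], 0)  # repeated-index convention

  sq <- molecule(rep("C", 4),
                 rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
  T4 <- tuple_tensor(sq, 4)$entries
  expect_equal(T4[1, 2, 3, 4], 4 + 2 * sqrt(2))
  expect_error(tuple_tensor(tri, 4), "at least 4")
  expect_error(tuple_tensor(tri, 5), "order must be 3 or 4")
})

test_that("tuple tensors agree exactly with brute-force loops on small molecules", {
  set.seed(9)
  for (rep_i in 1:5) {
    n <- sample(4:6, 1)
    mol <- molecule(sample(c("C", "N", "O"), n, replace = TRUE),
                    matrix(runif(n * 3, 0, 5), n, 3))
    for (ord in c(3L, 4L)) {
      if (n < ord) next
      expect_equal(tuple_tensor(mol, ord)$entries,
                   brute_tuple_tensor(mol$coords, ord))
    }
  }
})

test_that("pair matrices are rigid-motion invariant and permutation equivariant", {
  set.seed(13)
  mols <- make_point_molecules(20, seed = 13)
  for (m in mols) {
    M <- pair_matrix(m, "M2")$entries
    m_rt <- transform_molecule(m, random_rotation(), rnorm(3, 0, 5))
    expect_lt(max(abs(pair_matrix(m_rt, "M2")$entries - M)), 1e-9)
    perm <- sample(m$n_atoms)
    Mp <- pair_matrix(permute_molecule(m, perm), "M2")$entries
    P <- diag(m$n_atoms)[perm, ]
    expect_lt(max(abs(Mp - P %*% M %*% t(P))), 1e-9)
  }
})

test_that("stochastic normalizations sum correctly on random molecules", {
  m0 <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(2, 0, 0)))
  M0 <- pair_matrix(m0)
  M0$entries <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(normalize_matrix(M0, "SS")$entries, matrix(c(0, 1, 1, 0), 2))

  set.seed(17)
  mols <- make_point_molecules(100, atoms_range = c(4L, 8L), seed = 17)
  for (m in mols) {
    M <- pair_matrix(m, "M2")
    expect_equal(rowSums(normalize_matrix(M, "SS")$entries),
                 rep(1, m$n_atoms), tolerance = 1e-12)
    expect_equal(sum(normalize_matrix(M, "MP")$entries), 1, tolerance = 1e-12)
    ds <- normalize_matrix(M, "DS", tol = 1e-8)$entries
    expect_lt(max(abs(rowSums(ds) - 1)), 1e-8)
    expect_lt(max(abs(colSums(ds) - 1)), 1e-8)
    # order-3 simple stochastic: every leading-index slice sums to 1
    if (m$n_atoms >= 3) {
      T3 <- normalize_matrix(tuple_tensor(m, 3), "SS")$entries
      expect_equal(rowSums(matrix(T3, nrow = m$n_atoms)),
                   rep(1, m$n_atoms), tolerance = 1e-12)
    }
  }
})

test_that("Sinkhorn balancing converges on random positive matrices", {
  set.seed(19)
  for (i in 1:10) {
    A <- matrix(runif(36, 0.1, 2), 6, 6)
    A <- A + t(A)
    M <- structure(list(entries = A, order = 2L, metric_id = "M2", n_atoms = 6L,
                        normalization = "NS", power = 1L,
                        cutoff = cutoff_scheme("KA")), class = "tuple_matrix")
    ds <- normalize_matrix(M, "DS", tol = 1e-8)$entries
    expect_lt(max(abs(rowSums(ds) - 1), abs(colSums(ds) - 1)), 1e-8)
  }
})

test_that("matrix powers and zero-row policies behave as declared", {
  m <- molecule(c("C", "C", "C"),
                rbind(c(0, 0, 0), c(1.5, 0, 0), c(3.0, 0, 0)))
  M <- pair_matrix(m)
  ss <- normalize_matrix(M, "SS")
  ss3 <- normalize_matrix(M, "SS", power = 3L)
  expect_equal(ss3$entries, ss$entries %*% ss$entries %*% ss$entries)
  expect_equal(normalize_matrix(M, "SS", power = 0L)$entries, diag(3))
  expect_error(normalize_matrix(tuple_tensor(m, 3), "SS", power = 2L), "order 2")
  # a matrix with an empty row errors under SS unless zero rows are kept
  M$entries[2, ] <- 0; M$entries[, 2] <- 0
  expect_error(normalize_matrix(M, "SS"), "zero row")
  kept <- normalize_matrix(M, "SS", zero_rows = "keep")$entries
  expect_equal(kept[2, ], rep(0, 3))
})

test_that("cutoff schemes zero the right entries and precede normalization", {
  chain <- molecule(c("C", "C", "C"),
                    rbind(c(0, 0, 0), c(1.5, 0, 0), c(3.0, 0, 0)))
  g <- bond_graph(chain)
  M <- pair_matrix(chain)
  lgp1 <- apply_cutoff(M, cutoff_scheme("LGP", lag_max = 1), graph = g)
  expect_equal(lgp1$entries[1, 3], 0)   # two bonds apart
  expect_gt(lgp1$entries[1, 2], 0)

  pairm <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(3, 0, 0)))
  lgl <- apply_cutoff(pair_matrix(pairm), cutoff_scheme("LGL", window = c(1, 2)),
                      mol = pairm)
  expect_equal(lgl$entries[1, 2], 0)

  ka <- apply_cutoff(M, cutoff_scheme("KA"))
  expect_identical(ka$entries, M$entries)

  expect_error(apply_cutoff(M, cutoff_scheme("LGP", lag_max = 2)), "bond_graph")
  expect_error(cutoff_scheme("LGL", window = c(2, 1)), "a < b")
  expect_error(cutoff_scheme("LGP"), "lag_max")

  # order-3 tensor: a tuple dies when any of its pairs is out of range
  T3 <- tuple_tensor(chain, 3)
  cut3 <- apply_cutoff(T3, cutoff_scheme("LGP", lag_max = 1), graph = g)
  expect_equal(cut3$entries[1, 2, 3], 0)  # contains the lag-2 pair (1,3)
})
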