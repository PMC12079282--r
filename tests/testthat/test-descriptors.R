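ref_names <- unname(reference_model()$descriptor_names)

test_that("the published descriptor names parse into the expected specs", {
  s2 <- parse_descriptor_name("GM_B_AB_nCi_2_M15_SS3_T_LGL[1–2]_e-s_MID")
  expect_equal(s2$aggregator, "GM")
  expect_equal(s2$form, "bilinear")
  expect_equal(s2$tuple_order, 2L)
  expect_equal(s2$metric_id, "M15")
  expect_equal(s2$normalization, "SS")
  expect_equal(s2$power, 3L)
  expect_equal(s2$scope, "total")
  expect_equal(s2$cutoff$kind, "LGL")
  expect_equal(s2$cutoff$window, c(1, 2))
  expect_equal(s2$weights, c("e", "s"))

  s3 <- parse_descriptor_name("S_B_AB_nCi_2_M3_SS4_T_LGL[2-3]_m-h_MID")
  expect_equal(s3$weights, c("m", "h"))
  expect_equal(s3$cutoff$window, c(2, 3))

  s1 <- parse_descriptor_name("I50_F_AB_nCi_2_M12_SS1_T_LGP[5]_s_MID")
  expect_equal(s1$form, "linear")
  expect_equal(s1$cutoff$kind, "LGP")
  expect_equal(s1$cutoff$lag_max, 5L)

  expect_error(parse_descriptor_name("ZZ_B_AB_nCi_2_M3_SS4_T_KA_m-h_MID"),
               "aggregator token 'ZZ' at position 1")
  expect_error(parse_descriptor_name("S_B_AB_nCi_2_M3_SS4_T_ANG[10-20]_m-h_MID"),
               "not implemented")
  # weight-count / form consistency
  expect_error(parse_descriptor_name("S_B_AB_nCi_2_M3_SS4_T_KA_m_MID"), "2 weights")
  expect_error(parse_descriptor_name("S_F_AB_nCi_2_M3_SS4_T_KA_m-h_MID"), "1 weight")
})

test_that("parse and format round-trip for every published name", {
  for (nm in ref_names) {
    sp <- parse_descriptor_name(nm)
    expect_identical(parse_descriptor_name(format_descriptor_spec(sp)), sp)
  }
})

test_that("weight vectors follow atom order and reject unknown properties", {
  h2o <- molecule(c("O", "H", "H"),
                  rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
  expect_equal(build_weight_vector(h2o, "m"), c(15.999, 1.008, 1.008))
  expect_length(build_weight_vector(h2o, "e"), 3)
  expect_error(build_weight_vector(h2o, "q"), "unknown property")
})

test_that("LOVIs match the algebraic forms and brute-force double loops", {
  pairm <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  spec <- parse_descriptor_name("S_F_AB_nCi_2_M2_NS1_T_KA_m_MID")
  spec$weights <- "m"
  # linear with unit weights: LOVIs are row sums
  L <- compute_lovis(pairm, "S_F_AB_nCi_2_M2_NS1_T_KA_m_MID")
  g <- pair_matrix(pairm)$entries
  x <- build_weight_vector(pairm, "m")
  expect_equal(as.numeric(L), as.numeric(g %*% x))

  # brute-force quadratic double loop on a random 4-atom molecule
  set.seed(31)
  mol4 <- molecule(c("C", "N", "O", "H"), matrix(runif(12, 0, 4), 4, 3))
  Lq <- compute_lovis(mol4, "S_Q_AB_nCi_2_M2_NS1_T_KA_m_MID")
  xm <- build_weight_vector(mol4, "m")
  g4 <- pair_matrix(mol4)$entries
  Lq_ref <- sapply(1:4, function(i) {
    acc <- 0
    for (j in 1:4) acc <- acc + xm[i] * g4[i, j] * xm[j]
    acc
  })
  expect_equal(as.numeric(Lq), Lq_ref)

  # bilinear cross term: x = e1, y = e2 picks out g(1,2)
  Lb <- compute_lovis(pairm, "S_B_AB_nCi_2_M2_NS1_T_KA_m-h_MID")
  xb <- build_weight_vector(pairm, "m")
  yb <- build_weight_vector(pairm, "h")
  expect_equal(sum(Lb), as.numeric(t(xb) %*% g %*% yb))
})

test_that("order-3 LOVIs match a brute-force triple loop", {
  set.seed(37)
  mol <- molecule(c("C", "N", "O", "H", "C"), matrix(runif(15, 0, 4), 5, 3))
  L <- compute_lovis(mol, "S_Q_AB_nCi_3_M2_NS1_T_KA_m_MID")
  x <- build_weight_vector(mol, "m")
  T3 <- brute_tuple_tensor(mol$coords, 3)
  L_ref <- sapply(1:5, function(i) {
    acc <- 0
    for (j in 1:5) for (k in 1:5) acc <- acc + x[i] * T3[i, j, k] * x[j] * x[k]
    acc
  })
  expect_equal(as.numeric(L), L_ref)
})

test_that("the sum of LOVIs equals the full algebraic form value", {
  mols <- make_chain_molecules(10, with_metal = TRUE, seed = 41)
  specs <- c(ref_names,
             "S_Q_AB_nCi_3_M2_SS1_T_KA_v_MID",
             "AM_F_AB_nCi_4_M1_MP1_T_KA_p_MID")
  for (m in mols) {
    for (nm in specs) {
      sp <- parse_descriptor_name(nm)
      if (m$n_atoms < sp$tuple_order) next
      L <- compute_lovis(m, sp)
      x <- build_weight_vector(m, sp$weights[1])
      y <- if (sp$form == "bilinear") build_weight_vector(m, sp$weights[2]) else x
      M <- midasqspr:::processed_matrix(m, sp, bond_graph(m))
      n <- m$n_atoms
      flat <- matrix(M$entries, nrow = n)
      wprod <- y
      if (sp$tuple_order > 2L) {
        for (d in seq_len(sp$tuple_order - 2L)) wprod <- as.vector(outer(wprod, y))
      }
      inner <- as.numeric(flat %*% wprod)
      full <- switch(sp$form,
                     linear = sum(inner),
                     quadratic = sum(x * inner),
                     bilinear = sum(x * inner))
      expect_equal(sum(L), full, tolerance = 1e-10)
    }
  }
})

test_that("aggregators compute the declared statistics", {
  expect_equal(aggregate_lovis(c(1, 2, 3), "S"), 6)
  expect_equal(aggregate_lovis(c(2, 8), "GM"), 4)
  expect_equal(aggregate_lovis(c(1, 2, 3), "I50"), 2)
  expect_equal(aggregate_lovis(c(5, 5, 5), "VC"), 0)
  expect_equal(aggregate_lovis(c(1, 2, 3), "AM"), 2)
  expect_equal(aggregate_lovis(c(-3, 4), "N1"), 7)
  expect_equal(aggregate_lovis(c(3, 4), "N2"), 5)
  expect_equal(aggregate_lovis(c(1, 5), "RA"), 4)
  expect_equal(aggregate_lovis(c(1, 5), "V"), var(c(1, 5)))
  expect_equal(aggregate_lovis(c(0, 2), "GM"), 0)    # zero kills the product
  expect_true(is.nan(aggregate_lovis(c(-1, 1), "VC")))  # zero mean flagged
  expect_error(aggregate_lovis(1, "XX"), "unknown aggregator")
})

test_that("order-2 quadratic with unit weights equals the matrix grand sum", {
  # a weight table where every element maps to 1 makes the quadratic form
  # the plain grand sum of the processed matrix
  dir <- withr::local_tempdir()
  pd <- file.path(dir, "unit"); dir.create(pd)
  tabs <- atomic_property_tables()
  utils::write.csv(data.frame(element = names(tabs$m), value = 1),
                   file.path(pd, "m.csv"), row.names = FALSE)
  unit_tabs <- atomic_property_tables(pd)
  set.seed(43)
  mols <- make_point_molecules(5, seed = 43)
  sp <- parse_descriptor_name("S_Q_AB_nCi_2_M2_NS1_T_KA_m_MID")
  for (m in mols) {
    L <- compute_lovis(m, sp, tables = unit_tabs)
    expect_equal(sum(L), sum(pair_matrix(m)$entries))
  }
})

test_that("total-scope descriptors are invariant to rotation, translation and atom order", {
  mols <- make_chain_molecules(50, with_metal = TRUE, seed = 47)
  set.seed(48)
  for (m in mols) {
    vals <- sapply(ref_names, function(nm) compute_descriptor(m, nm))
    m_rt <- transform_molecule(m, random_rotation(), rnorm(3, 0, 10))
    vals_rt <- sapply(ref_names, function(nm) compute_descriptor(m_rt, nm))
    expect_lt(max(abs(vals - vals_rt)), 1e-9)
    m_p <- permute_molecule(m, sample(m$n_atoms))
    vals_p <- sapply(ref_names, function(nm) compute_descriptor(m_p, nm))
    expect_lt(max(abs(vals - vals_p)), 1e-9)
  }
})

test_that("descriptor tables are deterministic, structured, and flag failures", {
  mols <- make_chain_molecules(3, with_metal = TRUE, seed = 53)
  tab <- descriptor_table(mols, ref_names)
  expect_equal(dim(tab), c(3L, 4L))
  expect_true(all(is.finite(tab)))
  expect_identical(tab, descriptor_table(mols, ref_names))
  # CSV round trip is exact at full precision
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(format(as.data.frame(tab), digits = 17), f)
  back <- utils::read.csv(f, row.names = 1, check.names = FALSE)
  expect_equal(as.matrix(back), unclass(tab)[, ], tolerance = 1e-15,
               ignore_attr = TRUE)
  # a molecule smaller than the tuple order yields a flagged NA, not a zero
  tiny <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)), id = "tiny")
  tab2 <- descriptor_table(list(tiny), "S_Q_AB_nCi_3_M2_NS1_T_KA_m_MID")
  expect_true(is.na(tab2[1, 1]))
  expect_match(attr(tab2, "failures")$message, "tuple order")
})

test_that("local-scope descriptors are parsed but refused at compute time", {
  sp <- parse_descriptor_name("S_F_AB_nCi_2_M2_NS1_L_KA_m_MID")
  expect_equal(sp$scope, "local")
  m <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_error(compute_lovis(m, sp), "not implemented")
})
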