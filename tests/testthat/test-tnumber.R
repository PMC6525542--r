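# Lattice walks, T-number verdicts, censuses, ASU decomposition.

test_that("adjacent pentamers on the T=1 lattice walk to (1,0)", {
  g <- ideal_graph(1, 0)
  p <- which(g$degree == 5L)
  lt <- local_t(g, p[1], p[2])
  expect_true(lt$resolved)
  expect_equal(c(lt$h, lt$k, lt$T), c(1L, 0L, 1L))
})

test_that("two hexamers along one vector between pentamers give (3,0), T=9", {
  g <- ideal_graph(3, 0)
  tr <- particle_t(g)
  expect_equal(tr$verdict, "icosahedral")
  expect_equal(tr$T, 9L)
  expect_equal(nrow(tr$pairs), 30L)
  expect_true(all(tr$pairs$h == 3L & tr$pairs$k == 0L))
})

test_that("a two-step, 60-degree turn, one-step route gives (2,1), T=7", {
  g <- ideal_graph(2, 1)
  tr <- particle_t(g)
  expect_equal(tr$verdict, "icosahedral")
  expect_equal(tr$T, 7L)
  expect_true(all(tr$pairs$h == 2L & tr$pairs$k == 1L))
})

test_that("walk and census agree over the full (h,k) grid", {
  for (hk in hk_grid()) {
    h <- hk[1]; k <- hk[2]
    tr <- particle_t(ideal_graph(h, k))
    expect_equal(tr$verdict, "icosahedral", info = sprintf("(%d,%d)", h, k))
    expect_equal(tr$T, h^2 + h * k + k^2)
    expect_equal(tr$global_T_from_count, tr$T)
    expect_equal(nrow(tr$pairs), 30L)
    expect_true(all(tr$pairs$h == h & tr$pairs$k == k))
  }
})

test_that("local_t is symmetric after canonicalization", {
  for (hk in list(c(2, 1), c(3, 1))) {
    g <- ideal_graph(hk[1], hk[2])
    p <- which(g$degree == 5L)
    for (j in c(2L, 5L, 9L)) {
      a <- local_t(g, p[1], p[j])
      b <- local_t(g, p[j], p[1])
      expect_equal(c(a$h, a$k, a$T), c(b$h, b$k, b$T))
    }
  }
})

test_that("prolate shells report mixed T with cap-local T preserved", {
  tr <- particle_t(prolate_graph(3, 2))
  expect_equal(tr$verdict, "mixed")
  expect_true(9L %in% tr$T_values)          # within-cap pairs
  expect_true(any(tr$T_values > 9L))        # across-tube pairs
  tr2 <- particle_t(prolate_graph(2, 1, r = 20))
  expect_equal(tr2$verdict, "mixed")
  expect_true(4L %in% tr2$T_values)
  expect_true(any(tr2$T_values > 4L))
})

test_that("incomplete particles get no global T", {
  s <- perturb(ideal_set(3, 0), 0, 10 / 92, seed = 4)
  tr <- particle_t(classify_capsomers(build_graph(s)))
  expect_equal(tr$verdict, "incomplete")
  expect_true(is.na(tr$global_T_from_count))
  expect_true(all(is.na(tr$T)))
  # fewer than 2 pentamers: empty pair list, still incomplete
  few <- capsomer_set(ideal_set(1, 0)$positions[1:6, ], "few")
  tr2 <- particle_t(classify_capsomers(build_graph(few)))
  expect_equal(tr2$verdict, "incomplete")
})

test_that("lattice census reproduces closed-form counts", {
  c9 <- lattice_census(9)
  expect_equal(c9$n_subunits, 540L)
  expect_equal(c9$n_capsomers, 92L)
  expect_equal(c9$n_hexamers, 80L)
  expect_equal(c9$n_pentamers, 12L)
  c1 <- lattice_census(1)
  expect_equal(c1$n_subunits, 60L)
  expect_equal(c1$n_capsomers, 12L)
  expect_equal(c1$n_hexamers, 0L)
  c3 <- lattice_census(3)
  expect_equal(c3$n_subunits, 180L)
  expect_equal(c3$n_capsomers, 32L)
  expect_equal(c3$n_hexamers, 20L)
  # subunit bookkeeping identity: 60T = 5*12 + 6*(10T-10)
  for (T in c(1, 2, 7, 9, 13, 48)) {
    cs <- lattice_census(T)
    expect_equal(cs$n_subunits, 5L * cs$n_pentamers + 6L * cs$n_hexamers)
  }
  expect_error(lattice_census(0), "positive")
})

test_that("census counts match generated lattices", {
  for (hk in list(c(1, 1), c(3, 0))) {
    g <- ideal_graph(hk[1], hk[2])
    cs <- lattice_census(hk[1]^2 + hk[1] * hk[2] + hk[2]^2)
    expect_equal(sum(g$degree == 5L), cs$n_pentamers)
    expect_equal(sum(g$degree == 6L), cs$n_hexamers)
    expect_equal(nrow(g$positions), cs$n_capsomers)
  }
})

test_that("ASU decomposition gives 1/6/2 for T=9 and sums to T", {
  asu9 <- asu_decomposition(ideal_graph(3, 0))
  expect_equal(asu9, c(fivefold = 1, pseudothreefold = 6, threefold = 2))
  expect_equal(sum(asu9), 9)
  asu3 <- asu_decomposition(ideal_graph(1, 1))
  expect_equal(asu3, c(fivefold = 1, pseudothreefold = 2, threefold = 0))
  asu1 <- asu_decomposition(ideal_graph(1, 0))
  expect_equal(unname(asu1["fivefold"]), 1)
  expect_equal(sum(asu1), 1)
  # conservation across the grid
  for (hk in hk_grid())
    expect_equal(sum(asu_decomposition(ideal_graph(hk[1], hk[2]))),
                 hk[1]^2 + hk[1] * hk[2] + hk[2]^2)
})

test_that("ASU decomposition rejects non-icosahedral particles", {
  expect_error(asu_decomposition(prolate_graph(3, 2)), "mixed")
})

test_that("T recovery under 5% noise (h<=2 smoke; full sweep in acceptance)", {
  for (hk in list(c(2, 0), c(2, 1))) {
    s0 <- ideal_set(hk[1], hk[2])
    spacing <- nn_spacing(s0)
    Texp <- hk[1]^2 + hk[1] * hk[2] + hk[2]^2
    ok <- 0L
    for (seed in 1:20) {
      tr <- particle_t(build_graph(perturb(s0, 0.05 * spacing, 0, seed = seed)))
      if (tr$verdict == "icosahedral" && tr$T == Texp) ok <- ok + 1L
    }
    expect_gte(ok / 20, 0.95)
  }
})
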