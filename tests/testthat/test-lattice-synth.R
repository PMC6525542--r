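# Synthetic lattice generators: Goldberg counts, prolate closure,
# perturbation semantics.

test_that("icosahedral generator yields 10T+2 capsomers with 12 fivefold sites", {
  for (hk in hk_grid()) {
    h <- hk[1]; k <- hk[2]
    T <- h^2 + h * k + k^2
    s <- ideal_set(h, k)
    expect_equal(n_capsomers(s), 10 * T + 2,
                 info = sprintf("(h,k)=(%d,%d)", h, k))
    g <- ideal_graph(h, k)
    expect_equal(sum(g$degree == 5L), 12L,
                 info = sprintf("(h,k)=(%d,%d)", h, k))
    expect_true(all(g$degree %in% c(5L, 6L)))
  }
})

test_that("T=1 lattice is the 12-pentamer dodecahedral shell", {
  s <- ideal_set(1, 0)
  expect_equal(n_capsomers(s), 12L)
  g <- ideal_graph(1, 0)
  expect_true(all(g$degree == 5L))
  # all capsomers on the requested sphere
  expect_equal(sqrt(rowSums(s$positions^2)), rep(24, 12), tolerance = 1e-12)
})

test_that("degenerate and invalid generator arguments are rejected", {
  expect_error(generate_icosahedral(0, 0, 24), "h = k = 0")
  expect_error(generate_icosahedral(-1, 2, 24), "non-negative")
  expect_error(generate_icosahedral(1, 0, -5), "positive")
  expect_error(generate_prolate(0, 2, 24), "positive integer")
  expect_error(generate_prolate(3, -1, 24), "non-negative")
})

test_that("facetted projection keeps fivefold vertices at the nominal radius", {
  s <- generate_icosahedral(2, 0, 24, projection = "facetted")
  rad <- sqrt(rowSums(s$positions^2))
  expect_equal(max(rad), 24, tolerance = 1e-9)    # icosahedron vertices
  expect_lt(min(rad), 24 - 1e-6)                  # face interiors sag inward
  # same topology as the spherical projection
  g <- classify_capsomers(build_graph(s))
  expect_equal(unname(class_counts(g)), unname(class_counts(ideal_graph(2, 0))))
})

test_that("prolate generator inserts q rings of 5h hexamers and stays closed", {
  cases <- list(c(3, 0), c(3, 2), c(2, 1), c(1, 3), c(4, 3))
  for (pq in cases) {
    h <- pq[1]; q <- pq[2]
    s <- generate_prolate(h, q, 24)
    expect_equal(n_capsomers(s), 10 * h^2 + 2 + 5 * h * q,
                 info = sprintf("(h,q)=(%d,%d)", h, q))
    cr <- closure_report(build_graph(s))
    expect_true(cr$complete, info = sprintf("(h,q)=(%d,%d)", h, q))
    expect_equal(cr$n_pentamers, 12L)
  }
})

test_that("prolate with no rings matches the icosahedral topology", {
  g_pro <- prolate_graph(3, 0)
  g_ico <- ideal_graph(3, 0)
  expect_equal(n_capsomers(generate_prolate(3, 0, 24)), 92L)
  expect_equal(unname(class_counts(g_pro)), unname(class_counts(g_ico)))
  expect_equal(nrow(g_pro$edges), nrow(g_ico$edges))
})

test_that("perturb with zero noise and zero drop is the identity", {
  s <- ideal_set(3, 0)
  p <- perturb(s, 0, 0, seed = 5)
  expect_identical(p$positions, s$positions)
})

test_that("perturb drops round(drop_fraction * N) capsomers without moving the rest", {
  s <- ideal_set(3, 0)
  p <- perturb(s, 0, 5 / 92, seed = 0)
  expect_equal(n_capsomers(p), 87L)
  # retained rows are a subset of the original rows, in order
  orig <- apply(s$positions, 1, paste, collapse = ",")
  kept <- apply(p$positions, 1, paste, collapse = ",")
  expect_true(all(kept %in% orig))
  expect_false(is.unsorted(match(kept, orig)))
})

test_that("perturb is bit-reproducible for a fixed seed and rejects full drops", {
  s <- ideal_set(2, 0)
  expect_identical(perturb(s, 0.4, 0.2, seed = 11)$positions,
                   perturb(s, 0.4, 0.2, seed = 11)$positions)
  expect_false(identical(perturb(s, 0.4, 0.2, seed = 11)$positions,
                         perturb(s, 0.4, 0.2, seed = 12)$positions))
  expect_error(perturb(s, 0, 0.999, seed = 1), "no capsomers")
})

test_that("perturb displacement magnitude matches the chi-3 closed form", {
  # mean radial displacement of isotropic 3-D Gaussian noise: sigma*sqrt(8/pi)
  s <- ideal_set(3, 0)
  sigma <- 0.5
  disp <- numeric(0)
  for (seed in 1:5) {
    p <- perturb(s, sigma, 0, seed = seed)
    disp <- c(disp, sqrt(rowSums((p$positions - s$positions)^2)))
  }
  expect_equal(mean(disp), sigma * sqrt(8 / pi), tolerance = 0.08)
})

test_that("perturb does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(perturb(ideal_set(1, 0), 0.1, 0, seed = 99))
  expect_identical(runif(1), a)
})
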