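# Rendering, radial profiles, centre estimation, morphology typing,
# symmetry spectra, align/average, FSC, shrinkage correction.

test_that("rendered maps are non-negative and peak at an isolated capsomer", {
  one <- capsomer_set(matrix(0, 1, 3), "one")
  m <- render_density(one, voxel_nm = 0.5, blob_sigma_nm = 1.5)
  expect_true(all(m$values >= 0))
  peak <- arrayInd(which.max(m$values), dim(m$values))
  ax <- lapply(1:3, function(i)
    m$origin[i] + (seq_len(dim(m$values)[i]) - 1) * m$voxel_nm)
  expect_equal(c(ax[[1]][peak[1]], ax[[2]][peak[2]], ax[[3]][peak[3]]),
               c(0, 0, 0), tolerance = 0.26)   # within half a voxel
})

test_that("rendering is translation-equivariant for voxel-multiple shifts", {
  s <- ideal_set(1, 1)
  m1 <- render_density(s, 1, 2)
  shift <- c(3, -2, 5)
  s2 <- capsomer_set(sweep(s$positions, 2, shift, `+`), "shifted")
  m2 <- render_density(s2, 1, 2)
  expect_equal(m2$values, m1$values, tolerance = 1e-12)
  expect_equal(m2$origin, m1$origin + shift)
})

test_that("voxels coarser than 8 per particle diameter are rejected", {
  expect_error(render_density(ideal_set(1, 0), voxel_nm = 10, blob_sigma_nm = 2),
               "voxel too coarse")
})

test_that("radial profile of an analytic 21 nm shell peaks at 21 nm", {
  m <- shell_map(21)
  rp <- radial_profile(m, c(0, 0, 0))
  expect_equal(rp$peak_radius, 21, tolerance = 1)
  expect_true(all(diff(rp$bin_centers) > 0))
})

test_that("radial profile of a rendered T=9 shell at 24 nm peaks at 24 nm", {
  m <- render_density(ideal_set(3, 0), 1, 2)
  rp <- radial_profile(m, colMeans(ideal_set(3, 0)$positions))
  expect_equal(rp$peak_radius, 24, tolerance = 1)
})

test_that("radial profile of an all-zero map is zero everywhere", {
  m <- density_map(array(0, dim = c(12, 12, 12)), 1)
  rp <- radial_profile(m, c(5.5, 5.5, 5.5))
  expect_true(all(rp$mean_density == 0))
})

test_that("radial profile is invariant under 90-degree map rotation", {
  # a symmetric cube so the voxel grid maps onto itself under the rotation
  m <- shell_map(13, box_nm = 40)
  v90 <- aperm(m$values, c(2, 1, 3))[dim(m$values)[2]:1, , ]  # z-axis 90 deg
  m90 <- density_map(v90, m$voxel_nm, m$origin)
  rp <- radial_profile(m, c(0, 0, 0))
  rp90 <- radial_profile(m90, c(0, 0, 0))
  expect_equal(rp90$mean_density, rp$mean_density, tolerance = 1e-12)
})

test_that("centre estimation recovers known shifts within a voxel", {
  m0 <- shell_map(15, center = c(0, 0, 0), box_nm = 50)
  expect_equal(estimate_center(m0), c(0, 0, 0), tolerance = 0.5)
  m1 <- shell_map(15, center = c(3, -2, 1), box_nm = 50)
  expect_equal(estimate_center(m1), c(3, -2, 1), tolerance = 1)
})

test_that("flat maps and twin-particle boxes are refused", {
  expect_error(estimate_center(density_map(array(1, dim = c(10, 10, 10)), 1)),
               "no particle")
  a <- shell_map(8, center = c(-14, 0, 0), box_nm = 56, voxel_nm = 1,
                 box_center = c(0, 0, 0))
  b <- shell_map(8, center = c(14, 0, 0), box_nm = 56, voxel_nm = 1,
                 box_center = c(0, 0, 0))
  twin <- density_map(a$values + b$values, 1, a$origin)
  expect_error(estimate_center(twin), "ambiguous")
})

test_that("morphology classifier separates thick shells from condensed cores", {
  s <- ideal_set(1, 1, r = 18)
  ctr <- colMeans(s$positions)
  p_thick <- radial_profile(render_density(s, 1.5, 1.8, interior = "thick_shell"),
                            ctr)
  p_core <- radial_profile(render_density(s, 1.5, 1.8,
                                          interior = "condensed_core"), ctr)
  rep_ <- classify_morphology(list(p_thick, p_core, p_thick, p_core))
  expect_equal(rep_$labels, c("type1_thick_ring", "type2_thin_ring",
                              "type1_thick_ring", "type2_thin_ring"))
  expect_false(rep_$degenerate)
  # equal-radius generators give matching group-mean peak radii
  expect_equal(rep_$group_profiles[[1]]$peak_radius,
               rep_$group_profiles[[2]]$peak_radius, tolerance = 1.5)
})

test_that("identical profiles trigger a degenerate-split warning", {
  p <- radial_profile(shell_map(12, box_nm = 40), c(0, 0, 0))
  expect_warning(rep_ <- classify_morphology(list(p, p, p)), "degenerate")
  expect_equal(length(unique(rep_$labels)), 1L)
})

test_that("a five-blob ring scores best at order 5", {
  m <- render_density(ring_set(5), 0.8, 1.2)
  sp <- cyclic_symmetry_spectrum(m, c(0, 0, 1), 8, center = c(0, 0, 0))
  expect_equal(sp$best_order, 5L)
  expect_gt(sp$score[5], 0.95)
  expect_true(all(sp$score >= -1 & sp$score <= 1, na.rm = TRUE))
})

test_that("three radial blob pairs score as a trimer despite six blobs", {
  m <- render_density(ring_set(3, pair = TRUE), 0.8, 1.2)
  sp <- cyclic_symmetry_spectrum(m, c(0, 0, 1), 8, center = c(0, 0, 0))
  expect_equal(sp$best_order, 3L)
  expect_gt(sp$score[3], 0.95)
  expect_lt(sp$score[6], sp$score[3])
})

test_that("a rotationally uniform torus is flagged ambiguous", {
  n <- 33; vox <- 0.8
  ax <- (seq_len(n) - (n + 1) / 2) * vox
  rho <- sqrt(outer(ax^2, ax^2, `+`))
  tor <- array(0, dim = c(n, n, n))
  for (k in seq_len(n))
    tor[, , k] <- exp(-((rho - 8)^2 + ax[k]^2) / (2 * 1.2^2))
  m <- density_map(tor, vox, origin = rep(ax[1], 3))
  sp <- cyclic_symmetry_spectrum(m, c(0, 0, 1), 8)
  expect_true(sp$ambiguous)
  expect_true(all(sp$score > 0.95))
  expect_error(cyclic_symmetry_spectrum(m, c(0, 0, 1), 1), ">= 2")
})

test_that("align_average undoes known integer shifts exactly", {
  obj <- array(0, dim = c(24, 24, 24))
  obj[10:14, 10:14, 10:14] <- c(3, 1, 4, 1, 5)
  m0 <- density_map(obj, 1)
  shifted <- lapply(list(c(2, -1, 3), c(-2, 2, 0), c(0, 3, -2)), function(s) {
    v <- array(0, dim = dim(obj))
    v[(1:24) %in% ((1:24) + 0)] <- 0  # keep dims
    # shift by embedding
    idx <- lapply(1:3, function(i) pmin(pmax(1:24 - s[i], 1), 24))
    vv <- obj[idx[[1]], idx[[2]], idx[[3]]]
    # zero the wrapped border
    for (i in 1:3) {
      sl <- if (s[i] > 0) 1:s[i] else if (s[i] < 0) (24 + s[i] + 1):24
      else integer(0)
      if (length(sl)) {
        pick <- list(1:24, 1:24, 1:24); pick[[i]] <- sl
        vv[pick[[1]], pick[[2]], pick[[3]]] <- 0
      }
    }
    density_map(vv, 1)
  })
  av <- align_average(c(list(m0), shifted))
  expect_equal(av$values, obj, tolerance = 1e-12)
})

test_that("averaging noisy copies beats any single copy", {
  base <- shell_map(10, box_nm = 32, voxel_nm = 1)
  sig_sd <- stats::sd(base$values)
  set.seed(42)
  noisy <- lapply(1:12, function(i)
    density_map(base$values +
                  array(stats::rnorm(length(base$values),
                                     sd = sig_sd / sqrt(0.5)),
                        dim = dim(base$values)),
                1, base$origin))
  av <- align_average(noisy, reference = base)
  cor_av <- stats::cor(as.vector(av$values), as.vector(base$values))
  cor_single <- vapply(noisy, function(m)
    stats::cor(as.vector(m$values), as.vector(base$values)), numeric(1))
  expect_gt(cor_av, max(cor_single))
})

test_that("single-map alignment returns the map unchanged", {
  m <- shell_map(8, box_nm = 24)
  expect_identical(align_average(list(m)), m)
  expect_error(align_average(list(m, shell_map(8, box_nm = 30))),
               "grid dimensions")
})

test_that("FSC of a map with itself is 1 in every shell", {
  m <- render_density(ideal_set(1, 1), 1.5, 2)
  fc <- fsc(m, m)
  expect_true(all(abs(fc$fsc - 1) < 1e-9))
})

test_that("FSC of independent noise maps decorrelates", {
  set.seed(7)
  a <- density_map(array(stats::rnorm(32^3), dim = c(32, 32, 32)), 1)
  b <- density_map(array(stats::rnorm(32^3), dim = c(32, 32, 32)), 1)
  fc <- fsc(a, b)
  expect_lt(max(abs(fc$fsc[5:16])), 0.25)   # big shells: tight decorrelation
  expect_equal(mean(fc$fsc[5:16]), 0, tolerance = 0.05)
})

test_that("FSC is symmetric, bounded, and follows SNR/(1+SNR) for shared signal", {
  set.seed(11)
  n <- 32
  sig <- array(stats::rnorm(n^3), dim = c(n, n, n))
  snr <- 0.5                       # power SNR per voxel
  na_ <- array(stats::rnorm(n^3, sd = sqrt(1 / snr)), dim = c(n, n, n))
  nb_ <- array(stats::rnorm(n^3, sd = sqrt(1 / snr)), dim = c(n, n, n))
  ma <- density_map(sig + na_, 1)
  mb <- density_map(sig + nb_, 1)
  f1 <- fsc(ma, mb); f2 <- fsc(mb, ma)
  expect_equal(f1$fsc, f2$fsc)
  expect_true(all(abs(f1$fsc) <= 1 + 1e-12))
  expect_equal(mean(f1$fsc[6:15]), snr / (1 + snr), tolerance = 0.05)
})

test_that("shrinkage correction is plain rescaling", {
  expect_equal(shrinkage_correct(21, 25 / 21), 25)
  expect_equal(shrinkage_correct(40, 47 / 40), 47)
  expect_equal(shrinkage_correct(13.7, 1), 13.7)
  expect_error(shrinkage_correct(10, -2), "positive")
})
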