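# Shared fixtures: lattices and graphs are cached because several test
# files reuse the same (h, k) geometries.

.fixture_cache <- new.env(parent = emptyenv())

ideal_set <- function(h, k, r = 24) {
  key <- sprintf("set_%d_%d_%g", h, k, r)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_icosahedral(h, k, r)
  .fixture_cache[[key]]
}

ideal_graph <- function(h, k, r = 24) {
  key <- sprintf("graph_%d_%d_%g", h, k, r)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- classify_capsomers(build_graph(ideal_set(h, k, r)))
  .fixture_cache[[key]]
}

prolate_graph <- function(h, q, r = 24) {
  key <- sprintf("pro_%d_%d_%g", h, q, r)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <-
      classify_capsomers(build_graph(generate_prolate(h, q, r)))
  .fixture_cache[[key]]
}

# the (h, k) grid used by the lattice property tests
hk_grid <- function(h_max = 4) {
  out <- list()
  for (h in 1:h_max) for (k in 0:h) out[[length(out) + 1L]] <- c(h, k)
  out
}

# modal nearest-neighbour spacing of a capsomer set
nn_spacing <- function(set) {
  d <- as.matrix(stats::dist(set$positions))
  diag(d) <- Inf
  stats::median(apply(d, 1, min))
}

# analytic spherical-shell map: Gaussian shell of given radius; the box is
# centred on `box_center` (default: on the shell)
shell_map <- function(radius_nm, center = c(0, 0, 0), box_nm = 60,
                      voxel_nm = 1, sigma_nm = 1.5, amplitude = 1,
                      box_center = center) {
  n <- as.integer(round(box_nm / voxel_nm)) + 1L
  origin <- box_center - (n - 1) / 2 * voxel_nm
  ax <- lapply(1:3, function(i) origin[i] + (seq_len(n) - 1) * voxel_nm)
  r <- sqrt(array(rep((ax[[1]] - center[1])^2, times = n * n) +
                    rep(rep((ax[[2]] - center[2])^2, each = n), times = n) +
                    rep((ax[[3]] - center[3])^2, each = n * n),
                  dim = c(n, n, n)))
  density_map(amplitude * exp(-(r - radius_nm)^2 / (2 * sigma_nm^2)),
              voxel_nm, origin)
}

# evaluate expr under a fixed seed without disturbing the session RNG
with_seed_local <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# ring of blobs (optionally radial blob pairs) for symmetry-spectrum tests
ring_set <- function(n, pair = FALSE, r = 8) {
  ang <- 2 * pi * (0:(n - 1)) / n
  P <- cbind(r * cos(ang), r * sin(ang), 0)
  if (pair)
    P <- rbind(cbind((r - 1.5) * cos(ang), (r - 1.5) * sin(ang), 0),
               cbind((r + 1.5) * cos(ang), (r + 1.5) * sin(ang), 0))
  capsomer_set(P, sprintf("ring%d%s", n, if (pair) "p" else ""))
}
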