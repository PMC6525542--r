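#' Density maps
#'
#' A `density_map` is a 3-D scalar voxel grid with a physical voxel size
#' (nm per voxel edge) and an origin: the position, in nm, of the centre of
#' voxel `[1, 1, 1]`.
#'
#' @param values numeric 3-D array of voxel values.
#' @param voxel_nm positive voxel edge length in nm.
#' @param origin length-3 numeric, nm position of the first voxel centre.
#'
#' @return An object of class `density_map`.
#' @export
density_map <- function(values, voxel_nm, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  if (any(dim(values) < 1L)) stop("grid dimensions must be >= 1")
  if (!is.numeric(voxel_nm) || length(voxel_nm) != 1L || voxel_nm <= 0)
    stop("`voxel_nm` must be a positive scalar")
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be a finite length-3 vector")
  structure(list(values = values,
                 voxel_nm = as.numeric(voxel_nm),
                 origin = as.numeric(origin)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_map> %d x %d x %d voxels, %.3g nm/voxel\n",
              d[1], d[2], d[3], x$voxel_nm))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) nm; range [%.3g, %.3g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

# nm coordinates of voxel centres along each axis
axis_coords <- function(map) {
  d <- dim(map$values)
  lapply(1:3, function(i) map$origin[i] + (seq_len(d[i]) - 1) * map$voxel_nm)
}

# squared distances of every voxel centre to `center` (nm), as an array
voxel_dist2 <- function(map, center) {
  ax <- axis_coords(map)
  dx2 <- (ax[[1]] - center[1])^2
  dy2 <- (ax[[2]] - center[2])^2
  dz2 <- (ax[[3]] - center[3])^2
  d <- dim(map$values)
  array(rep(dx2, times = d[2] * d[3]) +
          rep(rep(dy2, each = d[1]), times = d[3]) +
          rep(dz2, each = d[1] * d[2]), dim = d)
}

#' Render a capsomer set into a synthetic density map
#'
#' Places an isotropic Gaussian blob of unit peak height at every capsomer
#' centre, in a box auto-sized to contain all capsomers plus three blob
#' sigmas.  Optionally adds interior density emulating the two particle
#' morphologies seen in cell sections: `"thick_shell"` adds a wide inner
#' layer directly beneath the capsomer layer (immature-like particles,
#' thick rings that are empty in the middle), `"condensed_core"` adds a
#' compact central ball (mature-like particles, thin rings with condensed
#' material in the middle).
#'
#' @param set a [capsomer_set()].
#' @param voxel_nm voxel edge in nm.  Rejected if coarser than 8 voxels
#'   across the particle diameter.
#' @param blob_sigma_nm Gaussian blob standard deviation in nm.
#' @param interior one of `"none"`, `"thick_shell"`, `"condensed_core"`.
#'
#' @return A [density_map()] with non-negative values.
#' @export
render_density <- function(set, voxel_nm = 1, blob_sigma_nm = 2,
                           interior = c("none", "thick_shell",
                                        "condensed_core")) {
  stopifnot(inherits(set, "capsomer_set"))
  interior <- match.arg(interior)
  if (!is.numeric(voxel_nm) || voxel_nm <= 0) stop("`voxel_nm` must be positive")
  if (!is.numeric(blob_sigma_nm) || blob_sigma_nm <= 0)
    stop("`blob_sigma_nm` must be positive")
  P <- set$positions
  pad <- 3 * blob_sigma_nm
  lo <- apply(P, 2, min) - pad
  hi <- apply(P, 2, max) + pad
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / voxel_nm)) + 1L)
  ctr <- colMeans(P)
  diam <- 2 * mean(sqrt(rowSums(sweep(P, 2, ctr)^2)))
  if (nrow(P) > 1L && diam / voxel_nm < 8)
    stop("voxel too coarse: fewer than 8 voxels across the particle diameter")

  vals <- array(0, dim = dims)
  ax <- lapply(1:3, function(i) lo[i] + (seq_len(dims[i]) - 1) * voxel_nm)
  reach <- 3.5 * blob_sigma_nm
  for (b in seq_len(nrow(P))) {
    rng <- lapply(1:3, function(i) {
      which(abs(ax[[i]] - P[b, i]) <= reach)
    })
    if (any(lengths(rng) == 0L)) next
    dx2 <- (ax[[1]][rng[[1]]] - P[b, 1])^2
    dy2 <- (ax[[2]][rng[[2]]] - P[b, 2])^2
    dz2 <- (ax[[3]][rng[[3]]] - P[b, 3])^2
    blob <- exp(-(outer(outer(dx2, dy2, `+`), dz2, `+`)) /
                  (2 * blob_sigma_nm^2))
    vals[rng[[1]], rng[[2]], rng[[3]]] <-
      vals[rng[[1]], rng[[2]], rng[[3]]] + blob
  }

  if (interior != "none" && nrow(P) > 1L) {
    map_tmp <- density_map(vals, voxel_nm, lo)
    r <- sqrt(voxel_dist2(map_tmp, ctr))
    R <- diam / 2
    # interior amplitudes scale with the rotationally averaged shell
    # density (not the blob peak), so the capsomer layer remains the
    # radial-profile maximum for any capsomer count, radius or blob size
    shell_mean <- max(radial_profile(map_tmp, ctr)$mean_density)
    if (interior == "thick_shell") {
      # wide inner layer beneath the capsomer shell, empty centre
      w <- blob_sigma_nm / 2
      ramp_in <- pmin(1, pmax(0, (r - 0.62 * R) / w))
      ramp_out <- pmin(1, pmax(0, (0.95 * R - r) / w))
      vals <- vals + 0.5 * shell_mean * ramp_in * ramp_out
    } else {
      # compact central ball (condensed ribonucleoprotein core)
      vals <- vals + 0.8 * shell_mean * exp(-r^2 / (2 * (0.25 * R)^2))
    }
  }
  density_map(vals, voxel_nm, lo)
}
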