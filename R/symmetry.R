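# Rotate a density map about an axis through `center` (nm; default box
# centre) by `angle` radians (backward mapping with trilinear
# interpolation; voxels that map outside the box become NA).
rotate_map <- function(map, axis, angle, center = NULL) {
  v <- map$values
  d <- dim(v)
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(-angle) * K + (1 - cos(-angle)) * (K %*% K)  # backward
  ctr_vox <- if (is.null(center)) (d + 1) / 2
  else (center - map$origin) / map$voxel_nm + 1
  g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                             z = seq_len(d[3])))
  src <- sweep(g, 2, ctr_vox) %*% t(R)
  src <- sweep(src, 2, ctr_vox, `+`)
  trilinear(v, src)
}

# Trilinear interpolation of array `v` at fractional voxel positions
# `pts` (n x 3); out-of-bounds points yield NA.
trilinear <- function(v, pts) {
  d <- dim(v)
  i0 <- floor(pts)
  f <- pts - i0
  ok <- i0[, 1] >= 1 & i0[, 1] < d[1] &
    i0[, 2] >= 1 & i0[, 2] < d[2] &
    i0[, 3] >= 1 & i0[, 3] < d[3]
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(array(out, dim = d))
  i0k <- i0[ok, , drop = FALSE]
  fk <- f[ok, , drop = FALSE]
  s1 <- 1L; s2 <- d[1]; s3 <- d[1] * d[2]
  base <- (i0k[, 1] - 1L) * s1 + (i0k[, 2] - 1L) * s2 + (i0k[, 3] - 1L) * s3 + 1L
  val <- 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wgt <- (if (cx) fk[, 1] else 1 - fk[, 1]) *
      (if (cy) fk[, 2] else 1 - fk[, 2]) *
      (if (cz) fk[, 3] else 1 - fk[, 3])
    val <- val + wgt * v[base + cx * s1 + cy * s2 + cz * s3]
  }
  out[ok] <- val
  array(out, dim = d)
}

#' Cyclic-symmetry spectrum of a subvolume
#'
#' Scores candidate rotational symmetry orders of a capsomer subvolume: for
#' each order `n`, the map is rotated by `360 / n` degrees about the given
#' axis (through the box centre) and correlated with itself.  A pentamer
#' scores highest at `n = 5`; a hexamer built from three dimers scores
#' highest at `n = 3` even though six blobs are present (trimeric
#' appearance of sixfold positions).
#'
#' @param map a [density_map()] centred on the candidate symmetry axis.
#' @param axis length-3 axis direction (need not be normalized).
#' @param n_max highest order to test (>= 2).
#' @param center nm point the axis passes through (default: box centre).
#' @return An object of class `symmetry_spectrum`: `orders` (1..n_max),
#'   `score` (normalized self-correlations in `[-1, 1]`), `best_order`
#'   (argmax over n >= 2), `ambiguous` (`TRUE` when all orders score ~1,
#'   as for a rotationally uniform torus).
#' @export
cyclic_symmetry_spectrum <- function(map, axis = c(0, 0, 1), n_max = 12L,
                                     center = NULL) {
  stopifnot(inherits(map, "density_map"))
  if (!is.numeric(n_max) || n_max < 2L) stop("`n_max` must be >= 2")
  n_max <- as.integer(n_max)
  orders <- seq_len(n_max)
  v <- map$values
  score <- vapply(orders, function(n) {
    rot <- rotate_map(map, axis, 2 * pi / n, center)
    ok <- !is.na(rot)
    if (sum(ok) < 8L) return(NA_real_)
    a <- v[ok]; b <- rot[ok]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(1)
    stats::cor(a, b)
  }, numeric(1))
  best <- orders[orders >= 2L][which.max(score[orders >= 2L])]
  structure(list(orders = orders, score = score, best_order = best,
                 ambiguous = all(score[orders >= 2L] > 0.95, na.rm = TRUE)),
            class = "symmetry_spectrum")
}

#' @export
print.symmetry_spectrum <- function(x, ...) {
  cat(sprintf("<symmetry_spectrum> best order C%d%s\n", x$best_order,
              if (x$ambiguous) " (ambiguous: near-uniform about the axis)"
              else ""))
  cat("  ", paste(sprintf("C%d=%.3f", x$orders, x$score), collapse = " "),
      "\n", sep = "")
  invisible(x)
}
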