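# integer-voxel shift with zero fill
shift_array <- function(v, s) {
  d <- dim(v)
  out <- array(0, dim = d)
  src <- dst <- vector("list", 3L)
  for (i in 1:3) {
    if (s[i] >= 0) {
      dst[[i]] <- (1L + s[i]):d[i]
      src[[i]] <- 1L:(d[i] - s[i])
    } else {
      dst[[i]] <- 1L:(d[i] + s[i])
      src[[i]] <- (1L - s[i]):d[i]
    }
    if (abs(s[i]) >= d[i]) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- v[src[[1]], src[[2]], src[[3]]]
  out
}

# best integer shift of `v` onto `ref` by FFT cross-correlation (wrapped
# lags folded to the signed range)
best_shift <- function(ref, v) {
  d <- dim(ref)
  cc <- Re(stats::fft(stats::fft(ref) * Conj(stats::fft(v)),
                      inverse = TRUE))
  ix <- arrayInd(which.max(cc), d)
  s <- ix - 1L
  s <- ifelse(s > d / 2, s - d, s)
  as.integer(s)
}

#' Translationally align and average density maps
#'
#' Shifts each map by the integer-voxel translation maximizing its
#' real-space cross-correlation with the reference, then averages the
#' aligned maps.  This mirrors the translational (no rotation) in-cell
#' particle averaging used to obtain radial density profiles.
#'
#' @param maps list of [density_map()]s on identical grids.
#' @param reference `"first"` (default) or a [density_map()] on the same
#'   grid.
#' @return The averaged [density_map()].
#' @export
align_average <- function(maps, reference = "first") {
  if (inherits(maps, "density_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1L,
            all(vapply(maps, inherits, logical(1), "density_map")))
  d <- dim(maps[[1]]$values)
  vox <- maps[[1]]$voxel_nm
  for (m in maps)
    if (!identical(dim(m$values), d) || m$voxel_nm != vox)
      stop("all maps must share grid dimensions and voxel size")
  ref <- if (identical(reference, "first")) maps[[1]] else reference
  if (!inherits(ref, "density_map") || !identical(dim(ref$values), d))
    stop("`reference` must be \"first\" or a density_map on the same grid")
  if (length(maps) == 1L && identical(reference, "first")) return(maps[[1]])
  acc <- array(0, dim = d)
  for (m in maps) {
    s <- best_shift(ref$values, m$values)
    acc <- acc + shift_array(m$values, s)
  }
  density_map(acc / length(maps), vox, ref$origin)
}

#' Fourier shell correlation between two maps
#'
#' Computes the normalized cross-correlation of two maps per spherical
#' shell in frequency space (shells one frequency voxel wide) and reports
#' the resolutions at which the curve first crosses the conventional 0.5
#' and 0.143 thresholds (linear interpolation between shells).
#'
#' @param map_a,map_b [density_map()]s on identical grids.
#' @return An object of class `fsc_curve`: `shell` (index),
#'   `frequency_nm` (cycles/nm at shell centre), `fsc`, and
#'   `resolution_nm_at_0.5` / `resolution_nm_at_0.143` (NA when the curve
#'   never crosses).
#' @export
fsc <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "density_map"), inherits(map_b, "density_map"))
  d <- dim(map_a$values)
  if (!identical(d, dim(map_b$values)) || map_a$voxel_nm != map_b$voxel_nm)
    stop("maps must share grid dimensions and voxel size")
  FA <- stats::fft(map_a$values)
  FB <- stats::fft(map_b$values)
  f_ax <- lapply(1:3, function(i) {
    f <- seq_len(d[i]) - 1L
    ifelse(f > d[i] / 2, f - d[i], f) * (d[1] / d[i])  # normalize to axis 1
  })
  r2 <- array(rep(f_ax[[1]]^2, times = d[2] * d[3]) +
                rep(rep(f_ax[[2]]^2, each = d[1]), times = d[3]) +
                rep(f_ax[[3]]^2, each = d[1] * d[2]), dim = d)
  shell <- round(sqrt(r2))
  nyq <- floor(d[1] / 2)
  keep <- shell >= 1L & shell <= nyq
  sh <- factor(shell[keep], levels = 1:nyq)
  num <- vapply(split(Re(FA[keep] * Conj(FB[keep])), sh), sum, numeric(1))
  pa <- vapply(split(abs(FA[keep])^2, sh), sum, numeric(1))
  pb <- vapply(split(abs(FB[keep])^2, sh), sum, numeric(1))
  curve <- num / sqrt(pa * pb)
  curve[!is.finite(curve)] <- 0
  freq <- (1:nyq) / (d[1] * map_a$voxel_nm)  # cycles per nm

  res_at <- function(thr) {
    below <- which(curve < thr)
    if (!length(below)) return(NA_real_)
    i <- below[1]
    if (i == 1L) return(1 / freq[1])
    f_cross <- freq[i - 1] + (freq[i] - freq[i - 1]) *
      (curve[i - 1] - thr) / (curve[i - 1] - curve[i])
    1 / f_cross
  }
  structure(list(shell = 1:nyq,
                 frequency_nm = freq,
                 fsc = unname(curve),
                 resolution_nm_at_0.5 = res_at(0.5),
                 resolution_nm_at_0.143 = res_at(0.143)),
            class = "fsc_curve")
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("<fsc_curve> %d shells\n", length(x$shell)))
  cat(sprintf("  resolution %.3g nm at FSC 0.5, %.3g nm at FSC 0.143\n",
              x$resolution_nm_at_0.5, x$resolution_nm_at_0.143))
  invisible(x)
}
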