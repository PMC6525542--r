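#' Capsomer sets
#'
#' A `capsomer_set` holds the 3-D centres (in nm) of the capsomers
#' (pentameric/hexameric CA oligomers) of one particle, together with
#' provenance: where the coordinates came from (generator parameters or a
#' file path), the nominal generation radius if any, and the RNG seed if
#' any randomness was involved.
#'
#' @param positions numeric matrix with one row per capsomer and columns
#'   `x`, `y`, `z` in nm.
#' @param particle_id character scalar identifying the particle.
#' @param radius_nominal nominal generation radius in nm, or `NULL` for
#'   sets loaded from files.
#' @param source a list of generation parameters, or a file path.
#' @param seed integer seed used during generation, or `NULL`.
#'
#' @return An object of class `capsomer_set`.
#' @export
capsomer_set <- function(positions, particle_id = "particle",
                         radius_nominal = NULL, source = list(),
                         seed = NULL) {
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || ncol(positions) != 3L)
    stop("`positions` must be a numeric matrix with 3 columns (x, y, z)")
  if (nrow(positions) < 1L)
    stop("a capsomer set needs at least one capsomer")
  if (!all(is.finite(positions)))
    stop("all capsomer coordinates must be finite")
  if (nrow(positions) > 1L) {
    if (min(stats::dist(positions)) <= 0)
      stop("capsomer positions must be pairwise distinct")
  }
  colnames(positions) <- c("x", "y", "z")
  rownames(positions) <- NULL
  structure(
    list(particle_id = as.character(particle_id)[1L],
         positions = positions,
         radius_nominal = radius_nominal,
         source = source,
         seed = seed),
    class = "capsomer_set")
}

#' @export
print.capsomer_set <- function(x, ...) {
  cat(sprintf("<capsomer_set> '%s': %d capsomers\n",
              x$particle_id, nrow(x$positions)))
  ctr <- colMeans(x$positions)
  rad <- sqrt(rowSums(sweep(x$positions, 2, ctr)^2))
  cat(sprintf("  mean radius %.2f nm (range %.2f-%.2f)\n",
              mean(rad), min(rad), max(rad)))
  if (!is.null(x$radius_nominal))
    cat(sprintf("  nominal generation radius %.2f nm\n", x$radius_nominal))
  if (!is.null(x$seed)) cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Number of capsomers in a set
#' @param set a `capsomer_set`.
#' @return integer capsomer count.
#' @export
n_capsomers <- function(set) {
  stopifnot(inherits(set, "capsomer_set"))
  nrow(set$positions)
}

# geometric centre of the capsomer cloud
set_center <- function(set) colMeans(set$positions)
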