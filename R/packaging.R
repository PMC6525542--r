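#' Genome-packaging density statistics
#'
#' Capsid capacity arithmetic: given a genome length, the number of genome
#' copies packaged, the number of Gag (CA) molecules forming the shell and
#' the capsid interior volume, reports the number of genomic RNA bases per
#' Gag molecule and the interior volume available per base.  Both raw
#' values and one-significant-figure roundings (the form in which such
#' numbers are usually quoted) are returned.
#'
#' For a T = 9 retroelement capsid (540 CA, two copies of a 5.2-kb genome,
#' ~5e4 nm^3 interior) this gives ~20 bases/Gag and ~5 nm^3/base; for
#' HIV-1 (~2400 Gag, dimeric 9.8-kb genome, ~2e5 nm^3 mature core) ~8
#' bases/Gag and ~10 nm^3/base.
#'
#' @param genome_kb genome length in kilobases (positive).
#' @param genome_copies number of genome copies packaged (positive integer).
#' @param gag_count number of Gag molecules; for an icosahedral shell this
#'   is `60 * T` (see [lattice_census()]).
#' @param interior_volume_nm3 capsid interior volume in nm^3 (positive).
#'
#' @return An object of class `packaging_report` with fields `genome_kb`,
#'   `genome_copies`, `gag_count`, `interior_volume_nm3`, `bases_total`,
#'   `bases_per_gag`, `nm3_per_base` and their `_1sf` roundings.
#' @examples
#' packaging_stats(5.2, 2, lattice_census(9)$n_subunits, 5e4)
#' @export
packaging_stats <- function(genome_kb, genome_copies, gag_count,
                            interior_volume_nm3) {
  if (!is.numeric(genome_kb) || genome_kb <= 0)
    stop("`genome_kb` must be positive")
  if (!is.numeric(genome_copies) || genome_copies < 1 ||
      genome_copies != round(genome_copies))
    stop("`genome_copies` must be a positive integer")
  if (!is.numeric(gag_count) || gag_count < 1 ||
      gag_count != round(gag_count))
    stop("`gag_count` must be a positive integer")
  if (!is.numeric(interior_volume_nm3) || interior_volume_nm3 <= 0)
    stop("`interior_volume_nm3` must be positive")
  bases <- 1000 * genome_kb * genome_copies
  bpg <- bases / gag_count
  npb <- interior_volume_nm3 / bases
  structure(
    list(genome_kb = genome_kb,
         genome_copies = as.integer(genome_copies),
         gag_count = as.integer(gag_count),
         interior_volume_nm3 = interior_volume_nm3,
         bases_total = bases,
         bases_per_gag = bpg,
         nm3_per_base = npb,
         bases_per_gag_1sf = signif(bpg, 1),
         nm3_per_base_1sf = signif(npb, 1)),
    class = "packaging_report")
}

#' @export
print.packaging_report <- function(x, ...) {
  cat(sprintf(
    "<packaging_report> %g kb x %d copies = %g bases in %d Gag, %.3g nm^3\n",
    x$genome_kb, x$genome_copies, x$bases_total, x$gag_count,
    x$interior_volume_nm3))
  cat(sprintf("  %.2f bases/Gag (~%g), %.2f nm^3/base (~%g)\n",
              x$bases_per_gag, x$bases_per_gag_1sf,
              x$nm3_per_base, x$nm3_per_base_1sf))
  invisible(x)
}

#' Sphere interior volume from an inner radius
#'
#' Convenience helper returning `(4/3) * pi * r^3`.  Which radius bounds
#' the capsid interior (centre of the CA layer vs its inner surface) is a
#' modelling choice left to the caller; this helper merely does the
#' arithmetic for a user-chosen inner radius.
#'
#' @param inner_radius_nm inner radius in nm.
#' @return Volume in nm^3.
#' @export
sphere_volume_nm3 <- function(inner_radius_nm) {
  if (!is.numeric(inner_radius_nm) || any(inner_radius_nm <= 0))
    stop("`inner_radius_nm` must be positive")
  4 / 3 * pi * inner_radius_nm^3
}
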