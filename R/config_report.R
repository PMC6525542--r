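#' Run configuration
#'
#' Bundles the tunable parameters of a lattice-analysis run so a whole
#' pipeline is reproducible from one object.  Round-trips losslessly
#' through YAML via [write_run_config()] / [read_run_config()].
#'
#' @param seed integer RNG seed.
#' @param cutoff_factor adjacency cutoff multiplier (see [build_graph()]).
#' @param projection `"sphere"` or `"facetted"` icosahedral projection.
#' @param voxel_nm rendering voxel size in nm.
#' @param shrinkage_factor multiplicative length correction for embedded
#'   samples (see [shrinkage_correct()]); the default 25/21 rescales a
#'   21 nm measured radius to the ~25 nm unshrunken value.
#' @param output_dir directory for pipeline outputs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, cutoff_factor = 1.4,
                       projection = c("sphere", "facetted"),
                       voxel_nm = 1, shrinkage_factor = 25 / 21,
                       output_dir = ".") {
  projection <- match.arg(projection)
  if (seed != round(seed)) stop("`seed` must be an integer")
  if (cutoff_factor <= 1 || cutoff_factor >= 2)
    stop("`cutoff_factor` must be in (1, 2): below the second lattice shell")
  if (voxel_nm <= 0) stop("`voxel_nm` must be positive")
  if (shrinkage_factor <= 0) stop("`shrinkage_factor` must be positive")
  structure(list(seed = as.integer(seed),
                 cutoff_factor = cutoff_factor,
                 projection = projection,
                 voxel_nm = voxel_nm,
                 shrinkage_factor = shrinkage_factor,
                 output_dir = output_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 17L)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

#' Analyze one particle end to end
#'
#' The standard per-particle pipeline: neighbour graph, symmetry
#' classification, closure report, T-number report and class counts, plus
#' a provenance block (package version and configuration) so reports are
#' self-describing and byte-reproducible.
#'
#' @param set a [capsomer_set()].
#' @param config a [run_config()].
#' @return A list of class `particle_report` with elements `particle_id`,
#'   `closure`, `t_report`, `class_counts`, `n_excluded_boundary`,
#'   `provenance`.
#' @export
analyze_particle <- function(set, config = run_config()) {
  stopifnot(inherits(set, "capsomer_set"), inherits(config, "run_config"))
  g <- classify_capsomers(build_graph(set, config$cutoff_factor))
  clo <- closure_report(g)
  tr <- particle_t(g)
  cc <- class_counts(g)
  structure(
    list(particle_id = set$particle_id,
         n_capsomers = nrow(g$positions),
         closure = clo,
         t_report = tr,
         class_counts = cc,
         n_excluded_boundary = unname(cc["edge"]),
         graph = g,
         provenance = list(package = "capsidlattice",
                           version = as.character(
                             utils::packageVersion("capsidlattice")),
                           config = unclass(config))),
    class = "particle_report")
}

#' @export
print.particle_report <- function(x, ...) {
  cat(sprintf("<particle_report> '%s' (%d capsomers)\n",
              x$particle_id, x$n_capsomers))
  print(x$closure)
  print(x$t_report)
  cat("  class counts: ",
      paste(names(x$class_counts), x$class_counts, sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Aggregate statistics over many particle reports
#'
#' Dataset-level census in the style of a cryo-ET particle survey: the
#' fraction of particles that are complete closed fullerene shells, the
#' fraction with mixed T-numbers, and the tally of global T-numbers among
#' icosahedral particles.
#'
#' @param reports list of `particle_report`s from [analyze_particle()].
#' @return A list with `n_particles`, `fraction_complete`,
#'   `fraction_mixed`, `t_table`.
#' @export
aggregate_reports <- function(reports) {
  stopifnot(all(vapply(reports, inherits, logical(1), "particle_report")))
  verd <- vapply(reports, function(r) r$t_report$verdict, character(1))
  comp <- vapply(reports, function(r) r$closure$complete, logical(1))
  tglob <- vapply(reports, function(r)
    if (r$t_report$verdict == "icosahedral") r$t_report$T else NA_integer_,
    integer(1))
  list(n_particles = length(reports),
       fraction_complete = mean(comp),
       fraction_mixed = mean(verd == "mixed"),
       t_table = table(tglob, useNA = "no"))
}

#' Write a report as JSON
#'
#' Serializes any report object of this package (particle reports,
#' packaging reports, aggregates) to pretty-printed JSON at full numeric
#' precision.  Reports carry their provenance block, so a written report
#' identifies the configuration that produced it; outputs are
#' byte-identical across runs with the same configuration.
#'
#' @param x report object (lists/S3 objects of this package).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_report <- function(x, path) {
  strip <- function(o) {
    if (inherits(o, "lattice_graph")) return(NULL)  # bulky; tables cover it
    if (is.list(o)) {
      o <- lapply(o, strip)
      o[!vapply(o, is.null, logical(1))]
    } else o
  }
  jsonlite::write_json(strip(unclass_rec(x)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

unclass_rec <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_rec) else x
}
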