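#' Read and write capsomer tables
#'
#' The capsomer-table format is a plain CSV (comma separated, dot decimal,
#' UTF-8, mandatory header) with columns `particle_id`, `x`, `y`, `z`
#' (nm) and, optionally, `class` and `degree` columns written by the
#' classification step.  One file may hold several particles; rows are
#' grouped by `particle_id` in order of first appearance (grouping need
#' not be contiguous).
#'
#' Coordinates round-trip losslessly: they are written with 17 significant
#' digits, enough to reproduce any double exactly.
#'
#' @param path file path.
#' @return `read_capsomer_table` returns a list of [capsomer_set()]s (one
#'   per particle).
#' @export
read_capsomer_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = TRUE, fileEncoding = "UTF-8")
  need <- c("particle_id", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  coords <- matrix(NA_real_, nrow(df), 3L)
  for (j in 1:3) {
    col <- need[j + 1L]
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(val) | !is.finite(val))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' on line %d of %s",
                   col, bad[1] + 1L, path))  # +1: header line
    coords[, j] <- val
  }
  ids <- df$particle_id
  lapply(unique(ids), function(id) {
    capsomer_set(coords[ids == id, , drop = FALSE],
                 particle_id = id, source = path)
  })
}

#' @rdname read_capsomer_table
#' @param sets a [capsomer_set()], a list of them, or a classified
#'   `lattice_graph` (which adds `class` and `degree` columns).
#' @param center_coordinates write particle-centred coordinates (origin at
#'   each particle's centre of mass); readers accept any origin.
#' @export
write_capsomer_table <- function(sets, path, center_coordinates = TRUE) {
  rows <- capsomer_rows(sets, center_coordinates)
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  out <- rows
  for (col in c("x", "y", "z")) out[[col]] <- fmt(rows[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

capsomer_rows <- function(sets, center_coordinates) {
  if (inherits(sets, "lattice_graph")) {
    g <- sets
    P <- g$positions
    if (center_coordinates) P <- sweep(P, 2, colMeans(P))
    df <- data.frame(particle_id = g$particle_id,
                     x = P[, 1], y = P[, 2], z = P[, 3])
    df$degree <- g$degree
    if (!is.null(g$class_label)) df$class <- g$class_label
    return(df)
  }
  if (inherits(sets, "capsomer_set")) sets <- list(sets)
  stopifnot(all(vapply(sets, inherits, logical(1), "capsomer_set")))
  do.call(rbind, lapply(sets, function(s) {
    P <- s$positions
    if (center_coordinates) P <- sweep(P, 2, colMeans(P))
    data.frame(particle_id = s$particle_id,
               x = P[, 1], y = P[, 2], z = P[, 3])
  }))
}
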