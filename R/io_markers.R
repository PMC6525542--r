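#' Write a lattice map as a Chimera-style marker file
#'
#' Serializes a classified lattice graph to the XML marker-set dialect read
#' by common molecular-graphics tools (UCSF Chimera/ChimeraX "marker sets",
#' also imported by Amira): one `<marker>` per capsomer with position (nm)
#' and the lattice-map colour code -- fivefold blue, true threefold yellow,
#' pseudothreefold green, boundary/unclassifiable grey -- plus one `<link>`
#' per lattice edge.
#'
#' @param graph a classified `lattice_graph` (see [classify_capsomers()]);
#'   an unclassified graph is rejected.
#' @param path output file path.
#' @param marker_radius marker sphere radius in nm.
#' @return The path, invisibly.
#' @export
write_lattice_markers <- function(graph, path, marker_radius = 2) {
  stopifnot(inherits(graph, "lattice_graph"))
  if (is.null(graph$class_label))
    stop("graph is unclassified; run classify_capsomers() first")
  cols <- list(fivefold = c(0, 0, 1),
               threefold = c(1, 1, 0),
               pseudothreefold = c(0, 1, 0),
               edge = c(0.5, 0.5, 0.5))
  doc <- xml2::xml_new_root("marker_set", name = graph$particle_id)
  P <- graph$positions
  for (i in seq_len(nrow(P))) {
    rgb <- cols[[graph$class_label[i]]]
    xml2::xml_add_child(doc, "marker",
                        id = as.character(i),
                        x = sprintf("%.6g", P[i, 1]),
                        y = sprintf("%.6g", P[i, 2]),
                        z = sprintf("%.6g", P[i, 3]),
                        r = sprintf("%g", rgb[1]),
                        g = sprintf("%g", rgb[2]),
                        b = sprintf("%g", rgb[3]),
                        radius = sprintf("%g", marker_radius),
                        note = graph$class_label[i])
  }
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    xml2::xml_add_child(doc, "link",
                        id1 = as.character(e[r, 1]),
                        id2 = as.character(e[r, 2]),
                        r = "0.7", g = "0.7", b = "0.7",
                        radius = sprintf("%g", marker_radius / 4))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
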