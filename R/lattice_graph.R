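#' Capsomer neighbour graphs
#'
#' [build_graph()] turns a capsomer point cloud into the lattice adjacency
#' graph used throughout the analysis.  Two capsomers are neighbours iff
#' their distance is at most `cutoff_factor` times the local lattice
#' spacing, estimated per capsomer as the median of its six smallest
#' point-to-point distances (a statistic centred on the first neighbour
#' shell and robust to noise).  On an ideal hexagonal shell the first and
#' second neighbour shells sit near 1.0 and ~1.73 lattice spacings, so the
#' default factor 1.4 separates them; the spacing is measured locally
#' rather than globally because projection onto a sphere or spherocylinder
#' makes it vary systematically by ~10% across the shell.
#'
#' Under positional noise the two distance shells can overlap, so a plain
#' cutoff alone occasionally admits a second-shell pair.  Such a spurious
#' edge always crosses a shorter true edge whose endpoints are common
#' neighbours of the spurious pair; `build_graph` therefore prunes every
#' edge `(i, j)` for which two adjacent common neighbours `(a, b)` exist
#' with `d(a, b) < d(i, j)` -- the local Delaunay flip criterion.  On
#' noise-free lattices the criterion never fires (there the flanking pair
#' of a true edge is 1.73 spacings apart, farther than the edge itself).
#'
#' @param set a [capsomer_set()].
#' @param cutoff_factor positive multiplier of the local lattice spacing
#'   used as the adjacency cutoff.
#'
#' @return An object of class `lattice_graph`: positions, an edge matrix,
#'   per-node coordination (degree), and -- after [classify_capsomers()] --
#'   a per-node class label.
#' @export
build_graph <- function(set, cutoff_factor = 1.4) {
  stopifnot(inherits(set, "capsomer_set"))
  if (!is.numeric(cutoff_factor) || cutoff_factor <= 0)
    stop("`cutoff_factor` must be positive")
  P <- set$positions
  n <- nrow(P)
  if (n < 2L) stop("need at least 2 capsomers to build a graph")
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr))$d
  if (sv[2] < 1e-9 * max(sv[1], .Machine$double.eps))
    stop("degenerate geometry: capsomers are collinear or coincident")
  d <- as.matrix(stats::dist(P))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  med_nn <- stats::median(nn)
  kk <- min(6L, n - 1L)
  spacing <- apply(d, 1, function(r) stats::median(sort(r)[seq_len(kk)]))
  local_cut <- cutoff_factor * outer(spacing, spacing, pmax)
  adj <- d <= local_cut
  # prune crossing (second-shell) edges: drop (i,j) when a shorter edge
  # between two of its common neighbours geometrically crosses it (the
  # local Delaunay flip criterion; the crossing test is done in the
  # tangent plane at the edge midpoint)
  ctr2 <- colMeans(P)
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  drop <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    cn <- which(adj[i, ] & adj[j, ])
    if (length(cn) < 2L) next
    cand <- which(adj[cn, cn, drop = FALSE] & (d[cn, cn] < d[i, j]),
                  arr.ind = TRUE)
    if (!nrow(cand)) next
    # tangent-plane basis at the edge midpoint
    m <- (P[i, ] + P[j, ]) / 2
    u <- m - ctr2
    nu <- sqrt(sum(u^2))
    if (nu < 1e-12) next
    u <- u / nu
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- crossprod3(u, e1)
    proj <- function(p) c(sum((p - m) * e1), (sum((p - m) * e2)))
    ccw <- function(p, q, s)
      (q[1] - p[1]) * (s[2] - p[2]) - (q[2] - p[2]) * (s[1] - p[1])
    pi2 <- proj(P[i, ]); pj2 <- proj(P[j, ])
    for (cc in seq_len(nrow(cand))) {
      a <- cn[cand[cc, 1]]; b <- cn[cand[cc, 2]]
      pa2 <- proj(P[a, ]); pb2 <- proj(P[b, ])
      crosses <- sign(ccw(pi2, pj2, pa2)) * sign(ccw(pi2, pj2, pb2)) < 0 &&
        sign(ccw(pa2, pb2, pi2)) * sign(ccw(pa2, pb2, pj2)) < 0
      if (crosses) { drop[r] <- TRUE; break }
    }
  }
  pairs <- pairs[!drop, , drop = FALSE]
  edges <- cbind(pairs[, 1], pairs[, 2])
  colnames(edges) <- c("i", "j")
  degree <- tabulate(c(edges), nbins = n)
  structure(
    list(particle_id = set$particle_id,
         positions = P,
         edges = edges,
         degree = degree,
         class_label = NULL,
         cutoff_factor = cutoff_factor,
         median_nn = med_nn,
         source = set$source),
    class = "lattice_graph")
}

#' @export
print.lattice_graph <- function(x, ...) {
  cat(sprintf("<lattice_graph> '%s': %d capsomers, %d edges\n",
              x$particle_id, nrow(x$positions), nrow(x$edges)))
  cat("  coordination: ", paste(sprintf("%d x deg %s", table(x$degree),
                                        names(table(x$degree))),
                                collapse = ", "), "\n", sep = "")
  if (!is.null(x$class_label))
    cat("  classes: ", paste(sprintf("%d %s", table(x$class_label),
                                     names(table(x$class_label))),
                             collapse = ", "), "\n", sep = "")
  invisible(x)
}

# adjacency list (list of integer neighbour vectors)
adjacency_list <- function(graph) {
  n <- nrow(graph$positions)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  e <- graph$edges
  if (nrow(e)) {
    adj <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]),
                                           levels = seq_len(n)))
    adj <- lapply(adj, as.integer)
  }
  adj
}

as_igraph <- function(graph) {
  igraph::graph_from_edgelist(graph$edges, directed = FALSE) |>
    igraph::add_vertices(max(0L, nrow(graph$positions) -
                               max(c(0L, graph$edges))))
}

#' Classify capsomer symmetry environments
#'
#' Applies the lattice-map colour rule: fivefold-coordinated capsomers are
#' `fivefold`; sixfold-coordinated capsomers with at least one fivefold
#' neighbour are `pseudothreefold`; sixfold-coordinated capsomers whose
#' neighbours are all sixfold are true `threefold`.  Capsomers with any
#' other coordination (boundary nodes of damaged particles, or degree-7+
#' noise artifacts) are labelled `edge` and never enter the three classes.
#'
#' @param graph a `lattice_graph` from [build_graph()].
#' @return The graph with `class_label` filled in.
#' @export
classify_capsomers <- function(graph) {
  stopifnot(inherits(graph, "lattice_graph"))
  n <- nrow(graph$positions)
  deg <- graph$degree
  adj <- adjacency_list(graph)
  lab <- rep("edge", n)
  lab[deg == 5L] <- "fivefold"
  six <- which(deg == 6L)
  for (v in six) {
    lab[v] <- if (any(deg[adj[[v]]] == 5L)) "pseudothreefold" else "threefold"
  }
  graph$class_label <- lab
  graph
}

#' Fullerene closure report
#'
#' A closed fullerene shell made of pentamers and hexamers must, by Euler's
#' formula, carry a total disclination of 12: the sum over capsomers of
#' `(6 - coordination)` equals 12, realised as exactly 12 pentamers.  A
#' particle is reported `complete` iff every coordination is 5 or 6, the
#' disclination sum is exactly 12, and the graph is a single connected
#' component.
#'
#' @param graph a classified `lattice_graph`.
#' @return An object of class `closure_report` with fields `complete`,
#'   `n_pentamers`, `n_hexamers`, `disclination_sum`.
#' @export
closure_report <- function(graph) {
  stopifnot(inherits(graph, "lattice_graph"))
  if (is.null(graph$class_label))
    graph <- classify_capsomers(graph)
  deg <- graph$degree
  disc <- sum(6L - deg)
  connected <- igraph::components(as_igraph(graph))$no == 1L
  structure(
    list(complete = all(deg %in% c(5L, 6L)) && disc == 12L && connected,
         n_pentamers = sum(deg == 5L),
         n_hexamers = sum(deg == 6L),
         disclination_sum = disc,
         n_boundary = sum(!deg %in% c(5L, 6L))),
    class = "closure_report")
}

#' @export
print.closure_report <- function(x, ...) {
  cat(sprintf(
    "<closure_report> complete=%s  pentamers=%d  hexamers=%d  disclination=%d\n",
    x$complete, x$n_pentamers, x$n_hexamers, x$disclination_sum))
  if (x$n_boundary > 0)
    cat(sprintf("  %d boundary/unclassifiable capsomers\n", x$n_boundary))
  invisible(x)
}

#' Class counts excluding boundary capsomers
#'
#' Counts capsomers per symmetry class.  Boundary (`edge`) capsomers of
#' damaged particles are excluded from the three classes and reported
#' separately, so that gaps in the lattice never masquerade as symmetry
#' environments.
#'
#' @param graph a classified `lattice_graph`.
#' @return Named integer vector with entries `fivefold`,
#'   `pseudothreefold`, `threefold`, `edge`.
#' @export
class_counts <- function(graph) {
  stopifnot(inherits(graph, "lattice_graph"))
  if (is.null(graph$class_label)) graph <- classify_capsomers(graph)
  lv <- c("fivefold", "pseudothreefold", "threefold", "edge")
  tab <- table(factor(graph$class_label, levels = lv))
  out <- as.integer(tab)
  names(out) <- lv
  out
}
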