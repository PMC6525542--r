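# ---- hexagonal lattice-coordinate helpers ----------------------------------

# rotate hex-lattice coordinates by 60 degrees counterclockwise
hex_rot60 <- function(a, b) c(-b, a + b)

# Canonical (h, k) with h >= k >= 0 among the 12 images of (a, b) under
# 60-degree rotations and mirroring; T is invariant.  Returns h, k, T and
# whether the canonical form came from the mirrored orbit.
hex_canonical <- function(a, b) {
  tval <- a * a + a * b + b * b
  orb <- matrix(NA_integer_, 12L, 2L)
  v <- c(a, b)
  for (r in 1:6) {
    orb[r, ] <- v
    v <- hex_rot60(v[1], v[2])
  }
  v <- c(b, a)  # mirror
  for (r in 7:12) {
    orb[r, ] <- v
    v <- hex_rot60(v[1], v[2])
  }
  ok <- which(orb[, 1] >= orb[, 2] & orb[, 2] >= 0)
  pick <- ok[1]
  list(h = orb[pick, 1], k = orb[pick, 2], T = tval, mirrored = pick > 6L)
}

# Neighbour cycles: for every node, its neighbours ordered counterclockwise
# around the outward normal (node position minus particle centre).  The
# consistent orientation makes 60-degree frame transport well defined on
# the closed (orientable) shell.
neighbor_cycles <- function(graph) {
  P <- graph$positions
  ctr <- colMeans(P)
  adj <- adjacency_list(graph)
  n <- nrow(P)
  cyc <- vector("list", n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (length(nb) < 2L) { cyc[[v]] <- nb; next }
    u <- P[v, ] - ctr
    u <- u / sqrt(sum(u^2))
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * u) * u
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    d <- sweep(P[nb, , drop = FALSE], 2, P[v, ])
    ang <- atan2(d %*% e2, d %*% e1)
    cyc[[v]] <- nb[order(ang)]
  }
  cyc
}

# Breadth-first frame transport from pentamer `start` leaving through its
# neighbour `first_nb`.  Each visited hexamer receives integer lattice
# coordinates; its six neighbours (counterclockwise) get the six unit hex
# steps, rotated to match the already-known step to one reference
# neighbour.  Pentamers receive coordinates but never propagate (frames
# are path-dependent across their 60-degree disclinations), so every walk
# runs inside a hexamer-only corridor.  Returns every coordinate pair
# under which `target` is reached.
walk_frames <- function(adj, cyc, deg, start, first_nb, target) {
  n <- length(adj)
  ca <- rep(NA_integer_, n)
  cb <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  ca[start] <- 0L; cb[start] <- 0L; depth[start] <- 0L
  hits <- list()
  ca[first_nb] <- 1L; cb[first_nb] <- 0L; depth[first_nb] <- 1L
  if (first_nb == target) return(list(c(1L, 0L)))
  if (deg[first_nb] != 6L) return(hits)
  queue <- integer(512L); queue[1L] <- first_nb
  qhead <- 1L; qtail <- 1L
  max_depth <- Inf
  while (qhead <= qtail) {
    v <- queue[qhead]; qhead <- qhead + 1L
    if (depth[v] > max_depth) next
    nb <- cyc[[v]]
    if (length(nb) != 6L) next
    # reference: a neighbour whose known coordinate is a unit step away
    ref <- 0L
    for (m in seq_len(6L)) {
      w <- nb[m]
      if (is.na(ca[w])) next
      da <- ca[w] - ca[v]; db <- cb[w] - cb[v]
      if (da * da + da * db + db * db == 1L) { ref <- m; break }
    }
    if (ref == 0L) next
    da <- ca[nb[ref]] - ca[v]; db <- cb[nb[ref]] - cb[v]
    for (t in 0:5) {
      m <- ((ref - 1L + t) %% 6L) + 1L
      w <- nb[m]
      na_ <- ca[v] + da; nb_ <- cb[v] + db
      if (w == target) {
        hits[[length(hits) + 1L]] <- c(na_, nb_)
        if (is.infinite(max_depth)) max_depth <- depth[v] + 1L
      } else if (is.na(ca[w])) {
        ca[w] <- na_; cb[w] <- nb_; depth[w] <- depth[v] + 1L
        if (deg[w] == 6L && depth[w] <= max_depth) {
          qtail <- qtail + 1L
          if (qtail > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[qtail] <- w
        }
      }
      st <- hex_rot60(da, db); da <- st[1]; db <- st[2]
    }
  }
  hits
}

# ---- local T ---------------------------------------------------------------

#' Local T-number between two pentamers by a lattice walk
#'
#' Determines the Caspar-Klug step coordinates between two fivefold
#' positions: the shortest lattice route consists of `h` steps in one
#' direction, a 60 degree turn, and `k` steps in the new direction, giving
#' the local triangulation number `T = h^2 + h k + k^2`.  The walk
#' transports a two-axis integer frame outward from `pent_i` across
#' hexamers only (frame transport is path dependent around pentagonal
#' disclinations, so corridors through other pentamers are never used) and
#' reads off the coordinate at `pent_j`.  Among all disclination-free
#' corridors the minimal-T result is returned, and `(h, k)` is
#' canonicalised to `h >= k >= 0` (merging the two mirror hands).
#'
#' @param graph a `lattice_graph` (classification not required; degrees
#'   are).
#' @param pent_i,pent_j node indices of two fivefold (degree-5) capsomers.
#'
#' @return A list with `h`, `k`, `T`, `mirrored`, and `resolved`.  If no
#'   hexamer-only corridor connects the pair, `resolved` is `FALSE` and
#'   `h`, `k`, `T` are `NA` (an unresolvable pair, not an error).
#' @export
local_t <- function(graph, pent_i, pent_j) {
  stopifnot(inherits(graph, "lattice_graph"))
  deg <- graph$degree
  if (deg[pent_i] != 5L || deg[pent_j] != 5L)
    stop("both nodes must be fivefold (degree 5) capsomers")
  if (pent_i == pent_j) stop("`pent_i` and `pent_j` must differ")
  adj <- adjacency_list(graph)
  cyc <- neighbor_cycles(graph)
  local_t_impl(adj, cyc, deg, pent_i, pent_j)
}

local_t_impl <- function(adj, cyc, deg, pent_i, pent_j) {
  cand <- list()
  for (n0 in adj[[pent_i]]) {
    hits <- walk_frames(adj, cyc, deg, pent_i, n0, pent_j)
    cand <- c(cand, hits)
  }
  if (!length(cand))
    return(list(h = NA_integer_, k = NA_integer_, T = NA_integer_,
                mirrored = NA, resolved = FALSE))
  tv <- vapply(cand, function(x) x[1]^2 + x[1] * x[2] + x[2]^2, numeric(1))
  best <- cand[[which.min(tv)]]
  out <- hex_canonical(best[1], best[2])
  out$resolved <- TRUE
  out
}

# ---- pentamer pairing ------------------------------------------------------

# Edges of the convex hull of a small 3-D point set (brute force over face
# triples; n = 12 pentamer directions, so cost is negligible).
hull_edges <- function(P) {
  n <- nrow(P)
  stopifnot(n >= 4L)
  tri <- utils::combn(n, 3)
  scale <- max(abs(P))
  tol <- 1e-8 * scale
  edges <- matrix(integer(0), 0L, 2L)
  for (c_ in seq_len(ncol(tri))) {
    i <- tri[1, c_]; j <- tri[2, c_]; k <- tri[3, c_]
    nrm <- crossprod3(P[j, ] - P[i, ], P[k, ] - P[i, ])
    if (sqrt(sum(nrm^2)) < tol) next
    d <- (P[-c(i, j, k), , drop = FALSE] %*% nrm) - sum(nrm * P[i, ])
    if (all(d <= tol) || all(d >= -tol))
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
  }
  edges <- t(apply(edges, 1, sort))
  unique(edges)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Pentamer pairs for the local-T vectors: convex-hull triangulation of the
# pentamer direction vectors for closed shells (the geodesic "neighbouring
# fivefold positions"; 30 pairs for icosahedral particles), mutual nearest
# neighbours for incomplete ones.
pentamer_pairs <- function(graph, pents, complete) {
  P <- graph$positions
  np <- length(pents)
  if (np < 2L) return(matrix(integer(0), 0L, 2L))
  if (complete && np >= 4L) {
    ctr <- colMeans(P)
    dirs <- sweep(P[pents, , drop = FALSE], 2, ctr)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    e <- hull_edges(dirs)
    return(cbind(pents[e[, 1]], pents[e[, 2]]))
  }
  d <- as.matrix(stats::dist(P[pents, , drop = FALSE]))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  pr <- unique(t(apply(cbind(seq_len(np), nn), 1, sort)))
  mutual <- pr[nn[pr[, 2]] == pr[, 1], , drop = FALSE]
  if (!nrow(mutual)) mutual <- pr
  cbind(pents[mutual[, 1]], pents[mutual[, 2]])
}

# ---- particle verdict ------------------------------------------------------

#' Per-particle T-number report
#'
#' Runs the lattice walk over all neighbouring pentamer pairs of a particle
#' and renders a verdict: `icosahedral` (one T-number throughout,
#' consistent with the closed-shell capsomer count `N = 10 T + 2`),
#' `mixed` (a closed fullerene whose local T-numbers differ -- unevenly
#' distributed pentamers), or `incomplete` (damaged particles; whatever
#' local T values are resolvable are listed, but no global T is assigned).
#'
#' Pentamer pairs are the convex-hull triangulation edges of the 12
#' pentamer direction vectors for closed shells (30 pairs for an
#' icosahedral particle) and mutually nearest pentamers for incomplete
#' ones.
#'
#' @param graph a `lattice_graph`.
#' @return An object of class `t_report`: `pairs` (data frame with
#'   `pent_i`, `pent_j`, `h`, `k`, `T_local`, `resolved`),
#'   `global_T_from_count` (closed shells only), `T_values` (sorted unique
#'   local T), `verdict` (`"icosahedral"`, `"mixed"` or `"incomplete"`)
#'   and, for icosahedral particles, `T`.
#' @export
particle_t <- function(graph) {
  stopifnot(inherits(graph, "lattice_graph"))
  if (is.null(graph$class_label)) graph <- classify_capsomers(graph)
  clo <- closure_report(graph)
  pents <- which(graph$degree == 5L)
  n <- nrow(graph$positions)
  global_T <- if (clo$complete && (n - 2L) %% 10L == 0L)
    (n - 2L) %/% 10L else NA_integer_

  pairs <- pentamer_pairs(graph, pents, clo$complete)
  if (nrow(pairs)) {
    adj <- adjacency_list(graph)
    cyc <- neighbor_cycles(graph)
    res <- lapply(seq_len(nrow(pairs)), function(r)
      local_t_impl(adj, cyc, graph$degree, pairs[r, 1], pairs[r, 2]))
    pair_df <- data.frame(
      pent_i = pairs[, 1], pent_j = pairs[, 2],
      h = vapply(res, `[[`, integer(1), "h"),
      k = vapply(res, `[[`, integer(1), "k"),
      T_local = vapply(res, `[[`, integer(1), "T"),
      resolved = vapply(res, `[[`, logical(1), "resolved"))
  } else {
    pair_df <- data.frame(pent_i = integer(0), pent_j = integer(0),
                          h = integer(0), k = integer(0),
                          T_local = integer(0), resolved = logical(0))
  }
  t_vals <- sort(unique(pair_df$T_local[pair_df$resolved]))
  n_unresolved <- sum(!pair_df$resolved)

  verdict <- if (!clo$complete) {
    "incomplete"
  } else if (length(t_vals) == 1L && n_unresolved == 0L &&
             !is.na(global_T) && t_vals == global_T) {
    "icosahedral"
  } else {
    "mixed"
  }
  structure(
    list(particle_id = graph$particle_id,
         pairs = pair_df,
         global_T_from_count = global_T,
         T_values = t_vals,
         n_unresolved_pairs = n_unresolved,
         verdict = verdict,
         T = if (verdict == "icosahedral") t_vals else NA_integer_),
    class = "t_report")
}

#' @export
print.t_report <- function(x, ...) {
  cat(sprintf("<t_report> '%s': verdict %s", x$particle_id, x$verdict))
  if (x$verdict == "icosahedral") cat(sprintf(" (T = %d)", x$T))
  if (x$verdict == "mixed")
    cat(sprintf(" (local T: %s)", paste(x$T_values, collapse = ", ")))
  cat("\n")
  cat(sprintf("  %d pentamer pairs, %d unresolved\n",
              nrow(x$pairs), x$n_unresolved_pairs))
  if (!is.na(x$global_T_from_count))
    cat(sprintf("  capsomer-count T = %d\n", x$global_T_from_count))
  invisible(x)
}

# ---- closed-form census ----------------------------------------------------

#' Closed-form lattice census for a T-number
#'
#' For a closed Caspar-Klug shell of triangulation number `T`: `60 T`
#' subunits arranged as 12 pentamers and `10 (T - 1)` hexamers on
#' `10 T + 2` capsomers.  The census is purely arithmetic; `T` need not be
#' expressible as `h^2 + h k + k^2`.
#'
#' @param T positive integer triangulation number.
#' @return An object of class `lattice_census` with `T`, `n_subunits`,
#'   `n_capsomers`, `n_pentamers`, `n_hexamers`.
#' @examples
#' lattice_census(9)  # 540 subunits, 92 capsomers
#' @export
lattice_census <- function(T) {
  if (length(T) != 1L || !is.numeric(T) || T != round(T) || T < 1)
    stop("`T` must be a positive integer")
  T <- as.integer(T)
  structure(
    list(T = T,
         n_subunits = 60L * T,
         n_capsomers = 10L * T + 2L,
         n_pentamers = 12L,
         n_hexamers = 10L * T - 10L),
    class = "lattice_census")
}

#' @export
print.lattice_census <- function(x, ...) {
  cat(sprintf(
    "<lattice_census> T=%d: %d subunits on %d capsomers (12 pentamers + %d hexamers)\n",
    x$T, x$n_subunits, x$n_capsomers, x$n_hexamers))
  invisible(x)
}

# ---- asymmetric-unit decomposition -----------------------------------------

#' Quasi-equivalent subunit multiplicities per icosahedral asymmetric unit
#'
#' For an icosahedral particle, distributes the `60 T` subunits over the 60
#' asymmetric units by symmetry class: each pentamer contributes 5
#' subunits, each hexamer 6, so the per-ASU multiplicity of a class is
#' (subunits in the class) / 60.  The multiplicities always sum to `T`.
#' For `T = 9` this is one subunit in the fivefold, six in pseudothreefold
#' and two in true threefold positions.
#'
#' @param graph a `lattice_graph` whose [particle_t()] verdict is
#'   icosahedral (anything else is an error).
#' @return Named numeric vector `c(fivefold=, pseudothreefold=,
#'   threefold=)`.
#' @export
asu_decomposition <- function(graph) {
  stopifnot(inherits(graph, "lattice_graph"))
  if (is.null(graph$class_label)) graph <- classify_capsomers(graph)
  rep_ <- particle_t(graph)
  if (rep_$verdict != "icosahedral")
    stop("asymmetric-unit decomposition requires an icosahedral particle (verdict: ",
         rep_$verdict, ")")
  cc <- class_counts(graph)
  c(fivefold = 5 * cc[["fivefold"]] / 60,
    pseudothreefold = 6 * cc[["pseudothreefold"]] / 60,
    threefold = 6 * cc[["threefold"]] / 60)
}
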