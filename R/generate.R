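# ---- icosahedron geometry -------------------------------------------------

# Vertices of a regular icosahedron with unit circumradius, oriented with a
# fivefold axis along +z ("polar" parametrization): pole, upper 5-ring at
# z = 1/sqrt(5), lower 5-ring (rotated by 36 degrees) at z = -1/sqrt(5), pole.
icosa_vertices <- function() {
  zr <- 1 / sqrt(5)
  rr <- 2 / sqrt(5)
  ang_u <- 2 * pi * (0:4) / 5
  ang_l <- ang_u + pi / 5
  rbind(c(0, 0, 1),
        cbind(rr * cos(ang_u), rr * sin(ang_u), zr),
        cbind(rr * cos(ang_l), rr * sin(ang_l), -zr),
        c(0, 0, -1))
}

# Face list (20 x 3 vertex indices) found from the edge length: a triple of
# vertices is a face iff all three pairwise distances equal the edge.
# Faces are oriented counterclockwise seen from outside; a consistent
# orientation is essential for skew (chiral) lattices, where mirrored face
# parametrizations would tile mirror-image lattice patches that do not
# mesh across edges.
icosa_faces <- function(verts) {
  d <- as.matrix(stats::dist(verts))
  edge <- min(d[d > 1e-9])
  tri <- utils::combn(nrow(verts), 3)
  is_face <- apply(tri, 2, function(ix) {
    all(abs(c(d[ix[1], ix[2]], d[ix[1], ix[3]], d[ix[2], ix[3]]) - edge) <
          1e-6 * edge)
  })
  faces <- t(tri[, is_face, drop = FALSE])
  for (f in seq_len(nrow(faces))) {
    V <- verts[faces[f, ], ]
    nrm <- crossprod3(V[2, ] - V[1, ], V[3, ] - V[1, ])
    if (sum(nrm * colMeans(V)) < 0) faces[f, ] <- faces[f, c(1L, 3L, 2L)]
  }
  faces
}

# Integer points of the hexagonal lattice inside the Caspar-Klug triangle
# with corners (0,0), (h,k), (-k,h+k) (lattice-basis coordinates), returned
# as barycentric coordinates with respect to the three corners.
ck_triangle_bary <- function(h, k) {
  a1 <- c(1, 0)
  a2 <- c(0.5, sqrt(3) / 2)
  lat2cart <- function(a, b) cbind(a * a1[1] + b * a2[1], a * a1[2] + b * a2[2])
  C1 <- drop(lat2cart(h, k))
  C2 <- drop(lat2cart(-k, h + k))
  M <- cbind(C1, C2)                      # corner 0 at the origin
  Minv <- solve(M)
  arange <- seq.int(min(0L, -k), max(0L, h))
  brange <- seq.int(0L, h + k)
  grid <- expand.grid(a = arange, b = brange)
  P <- lat2cart(grid$a, grid$b)
  lam <- P %*% t(Minv)                    # (lambda1, lambda2)
  lam0 <- 1 - lam[, 1] - lam[, 2]
  tol <- 1e-9
  keep <- lam[, 1] >= -tol & lam[, 2] >= -tol & lam0 >= -tol
  cbind(lam0, lam[, 1], lam[, 2])[keep, , drop = FALSE]
}

# Collapse coincident points (duplicates arise on shared face edges).
dedupe_points <- function(P, tol) {
  n <- nrow(P)
  if (n < 2L) return(P)
  d <- as.matrix(stats::dist(P))
  keep <- rep(TRUE, n)
  for (i in seq_len(n - 1L)) {
    if (!keep[i]) next
    dup <- which(d[i, ] < tol)
    keep[dup[dup > i]] <- FALSE
  }
  P[keep, , drop = FALSE]
}

# ---- ideal icosahedral generator ------------------------------------------

#' Generate an ideal icosahedral (h,k) capsomer lattice
#'
#' Builds the Caspar-Klug (h,k) geodesic triangulation of the icosahedron
#' and returns its vertices -- the capsomer centres of the dual Goldberg
#' (pentamer/hexamer) shell -- projected onto a sphere of the requested
#' radius.  The lattice has `T = h^2 + h k + k^2`, `10 T + 2` capsomers, of
#' which exactly 12 (the icosahedron vertices) are fivefold coordinated.
#'
#' The shortest lattice route between two neighbouring pentamers of such a
#' shell consists of `h` steps, a 60 degree turn, and `k` further steps.
#'
#' @param h,k non-negative integers, not both zero.  `(h,k)` and `(k,h)`
#'   are mirror-image (enantiomeric) lattices; both are accepted.
#' @param radius_nm particle radius in nm (to the capsomer layer).
#' @param projection `"sphere"` (default) projects capsomers radially onto
#'   the sphere of radius `radius_nm`; `"facetted"` keeps the planar
#'   icosahedron faces, with the 12 fivefold vertices at `radius_nm`.
#'
#' @return A [capsomer_set()].
#' @examples
#' s <- generate_icosahedral(3, 0, radius_nm = 24)
#' n_capsomers(s)  # 92 = 10*9 + 2
#' @export
generate_icosahedral <- function(h, k, radius_nm,
                                 projection = c("sphere", "facetted")) {
  projection <- match.arg(projection)
  if (length(h) != 1L || length(k) != 1L || h != round(h) || k != round(k) ||
      h < 0 || k < 0)
    stop("`h` and `k` must be non-negative integers")
  if (h + k < 1) stop("h = k = 0 does not define a lattice")
  if (!is.numeric(radius_nm) || radius_nm <= 0)
    stop("`radius_nm` must be positive")
  h <- as.integer(h); k <- as.integer(k)

  verts <- icosa_vertices()
  faces <- icosa_faces(verts)
  bary <- ck_triangle_bary(h, k)
  P <- do.call(rbind, lapply(seq_len(nrow(faces)), function(f) {
    V <- verts[faces[f, ], , drop = FALSE]
    bary %*% V
  }))
  edge <- sqrt(sum((verts[1, ] - verts[2, ])^2))
  spacing <- edge / sqrt(h^2 + h * k + k^2)
  P <- dedupe_points(P, tol = 0.3 * spacing)
  P <- switch(projection,
              sphere   = P / sqrt(rowSums(P^2)) * radius_nm,
              facetted = P * radius_nm)
  capsomer_set(P,
               particle_id = sprintf("ico_h%d_k%d", h, k),
               radius_nominal = radius_nm,
               source = list(generator = "icosahedral", h = h, k = k,
                             radius_nm = radius_nm, projection = projection))
}

# ---- prolate (elongated) generator ----------------------------------------

#' Generate a prolate (elongated icosahedron) capsomer lattice
#'
#' Builds a closed tubular fullerene shell from two `(h_cap, 0)` icosahedral
#' caps about a fivefold axis, separated by `q_rings` complete rings of
#' `5 * h_cap` hexamers.  The elongation is the skew (chiral) one: the
#' equatorial band is a single `5 h_cap` by `(h_cap + q_rings)` patch of
#' hexagonal lattice wrapped on a cylinder, which is the elongation that
#' keeps every capsomer on an exact lattice point.  Positions are inflated
#' onto a spherocylinder of the given radius.
#'
#' The result always has 12 pentamers; its local T-number equals
#' `h_cap^2` within the caps and exceeds it across the tube whenever
#' `q_rings > 0`, so such particles are reported as "mixed" by
#' [particle_t()], emulating non-icosahedral elongated particles.
#'
#' @param h_cap positive integer: the caps are `(h_cap, 0)` icosahedral
#'   halves.
#' @param q_rings non-negative integer: number of inserted hexamer rings.
#' @param radius_nm tube/cap radius in nm.
#' @param inflate blending weight in `[0, 1]` between the facetted
#'   stretched icosahedron (`0`) and its full projection onto a
#'   spherocylinder (`1`).  Full projection stretches the equatorial
#'   lattice circumferentially (the band facets lie well inside the
#'   circumsphere), which for large `h_cap` distorts neighbour distances
#'   enough to confuse distance-cutoff adjacency; the default `0.5` keeps
#'   the shell visibly rounded while preserving near-uniform spacing.
#'
#' @return A [capsomer_set()] with `10 h_cap^2 + 2 + 5 h_cap q_rings`
#'   capsomers.
#' @export
generate_prolate <- function(h_cap, q_rings, radius_nm, inflate = 0.5) {
  if (length(h_cap) != 1L || h_cap != round(h_cap) || h_cap < 1)
    stop("`h_cap` must be a positive integer")
  if (length(q_rings) != 1L || q_rings != round(q_rings) || q_rings < 0)
    stop("`q_rings` must be a non-negative integer")
  if (!is.numeric(radius_nm) || radius_nm <= 0)
    stop("`radius_nm` must be positive")
  if (!is.numeric(inflate) || inflate < 0 || inflate > 1)
    stop("`inflate` must be in [0, 1]")
  h <- as.integer(h_cap); q <- as.integer(q_rings)

  verts <- icosa_vertices() * radius_nm
  edge <- radius_nm / sin(2 * pi / 5)     # icosahedron edge at this radius
  s <- edge / h                           # lattice spacing
  dz <- q * s * sqrt(3) / 2               # axial elongation
  stretch <- verts
  stretch[, 3] <- stretch[, 3] + ifelse(verts[, 3] > 0, dz / 2, -dz / 2)

  pole_t <- 1L; pole_b <- 12L
  up <- 2:6                               # upper ring, angles 72*i
  lo <- 7:11                              # lower ring, angles 72*i + 36

  # equatorial band: lattice strip of width 5h (wrapped) and height H = h+q.
  # Bottom row vertices B_i = lower-ring vertex i at a = i*h; top row vertex
  # at a = i*h is upper-ring vertex i+1 (the band faces are (L_i, L_i+1,
  # U_i+1) and (U_i+1, U_i+2, L_i+1)).
  H <- h + q
  grid <- expand.grid(a = 0:(5L * h - 1L), b = 0:H)
  ii <- grid$a %/% h                      # strip cell 0..4
  u <- (grid$a - ii * h) / h
  v <- grid$b / H
  B  <- stretch[lo, , drop = FALSE]       # B_i, i = 0..4
  TT <- stretch[up[c(2:5, 1)], , drop = FALSE]  # top-row vertex over B_i
  i1 <- (ii + 1L) %% 5L
  low <- u + v <= 1 + 1e-12
  # triangle 1 (u + v <= 1): corners B_i, B_i1, TT_i, bary (1-u-v, u, v)
  # triangle 2: corners TT_i, TT_i1, B_i1, bary (1-u, u-1+v, 1-v)
  P_band <- matrix(0, nrow(grid), 3L)
  t1 <- low
  P_band[t1, ] <- (1 - u[t1] - v[t1]) * B[ii[t1] + 1L, , drop = FALSE] +
    u[t1] * B[i1[t1] + 1L, , drop = FALSE] +
    v[t1] * TT[ii[t1] + 1L, , drop = FALSE]
  t2 <- !low
  P_band[t2, ] <- (1 - u[t2]) * TT[ii[t2] + 1L, , drop = FALSE] +
    (u[t2] - 1 + v[t2]) * TT[i1[t2] + 1L, , drop = FALSE] +
    (1 - v[t2]) * B[i1[t2] + 1L, , drop = FALSE]

  # In a hexagonal lattice successive rows are offset by half a spacing;
  # the icosahedron's inherent lower-to-upper ring offset (36 degrees)
  # supplies that for h rows only, so the q inserted rows need an extra
  # progressive twist of pi/(5h) each, and the whole top cap rotates
  # rigidly by the accumulated q*pi/(5h).
  dphi <- q * pi / (5 * h)
  rot_z <- function(M, ang) {
    ca <- cos(ang); sa <- sin(ang)
    cbind(ca * M[, 1] - sa * M[, 2], sa * M[, 1] + ca * M[, 2], M[, 3])
  }
  if (q > 0) {
    ang_b <- dphi * v                     # v = b/H: progress up the band
    ca <- cos(ang_b); sa <- sin(ang_b)
    P_band <- cbind(ca * P_band[, 1] - sa * P_band[, 2],
                    sa * P_band[, 1] + ca * P_band[, 2], P_band[, 3])
    stretch[c(pole_t, up), ] <- rot_z(stretch[c(pole_t, up), , drop = FALSE],
                                      dphi)
  }

  # polar caps: 5 equilateral (h,0) faces each (top cap already twisted)
  bary_cap <- ck_triangle_bary(h, 0L)
  cap_faces <- rbind(
    cbind(pole_t, up, up[c(2:5, 1)]),
    cbind(pole_b, lo, lo[c(2:5, 1)]))
  P_cap <- do.call(rbind, lapply(seq_len(nrow(cap_faces)), function(f) {
    bary_cap %*% stretch[cap_faces[f, ], , drop = FALSE]
  }))

  P <- dedupe_points(rbind(P_cap, P_band), tol = 0.3 * s)

  # partial inflation toward the spherocylinder: caps are spheres centred
  # at (0,0,+-dz/2), the tube a cylinder of the same radius.
  if (inflate > 0) {
    z0 <- pmin(pmax(P[, 3], -dz / 2), dz / 2)
    D <- cbind(P[, 1], P[, 2], P[, 3] - z0)
    nrm <- sqrt(rowSums(D^2))
    target <- inflate * radius_nm + (1 - inflate) * nrm
    P <- cbind(0, 0, z0) + D / nrm * target
  }

  capsomer_set(P,
               particle_id = sprintf("prolate_h%d_q%d", h, q),
               radius_nominal = radius_nm,
               source = list(generator = "prolate", h_cap = h, q_rings = q,
                             radius_nm = radius_nm, inflate = inflate))
}

# ---- perturbation ---------------------------------------------------------

#' Perturb a capsomer set with positional noise and capsomer loss
#'
#' Emulates damaged/incomplete particles and subtomogram localization
#' error: a uniformly random subset of `round(drop_fraction * N)` capsomers
#' is removed, and every retained capsomer is displaced by isotropic
#' Gaussian noise of standard deviation `sigma_nm` per axis.  Deterministic
#' for a fixed `seed`; with `sigma_nm = 0` and `drop_fraction = 0` the set
#' is returned unchanged (apart from provenance).
#'
#' @param set a [capsomer_set()].
#' @param sigma_nm non-negative per-axis noise SD in nm.
#' @param drop_fraction fraction of capsomers to remove, in `[0, 1)`.
#' @param seed integer RNG seed.
#'
#' @return A [capsomer_set()].
#' @export
perturb <- function(set, sigma_nm, drop_fraction = 0, seed = 1L) {
  stopifnot(inherits(set, "capsomer_set"))
  if (!is.numeric(sigma_nm) || sigma_nm < 0)
    stop("`sigma_nm` must be non-negative")
  if (!is.numeric(drop_fraction) || drop_fraction < 0 || drop_fraction >= 1)
    stop("`drop_fraction` must be in [0, 1)")
  n <- nrow(set$positions)
  n_drop <- round(drop_fraction * n)
  if (n - n_drop < 1L)
    stop("`drop_fraction` would leave no capsomers")
  P <- with_seed(as.integer(seed), {
    keep <- if (n_drop > 0L) sort(sample.int(n, n - n_drop)) else seq_len(n)
    P <- set$positions[keep, , drop = FALSE]
    if (sigma_nm > 0)
      P <- P + matrix(stats::rnorm(length(P), sd = sigma_nm), nrow(P), 3L)
    P
  })
  capsomer_set(P,
               particle_id = set$particle_id,
               radius_nominal = set$radius_nominal,
               source = c(set$source,
                          list(sigma_nm = sigma_nm,
                               drop_fraction = drop_fraction)),
               seed = as.integer(seed))
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
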