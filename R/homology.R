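# Alpha-complex filtration of a C-alpha point cloud.
#
# Simplices come from the Delaunay complex (computed by exact brute-force
# empty-circumsphere enumeration; snapshots have a few dozen points, so
# incremental triangulation is unnecessary). Filtration values are the ball
# RADII (Angstrom) at which each simplex enters the alpha complex: the
# circumradius for Gabriel simplices, otherwise the smallest coface value.
# This radius convention propagates into all downstream lifetimes and
# feature weights, which are therefore in Angstrom.

#' Build an alpha-complex filtration for a point cloud
#'
#' Constructs the Delaunay complex of the cloud and assigns every edge,
#' triangle and tetrahedron the smallest ball radius (Angstrom) at which it
#' belongs to the alpha complex. A deterministic seeded jitter (default 1e-9
#' Angstrom) is applied first so that cospherical point sets are in general
#' position. Near-planar clouds (including 3-point inputs) are detected and
#' handled with a two-dimensional alpha complex on their principal plane;
#' collinear input is an error.
#'
#' @param cloud R x 3 coordinate matrix, R >= 3.
#' @param jitter symbolic jitter scale, Angstrom.
#' @param jitter_seed seed for the jitter (recorded in the output).
#' @return An object of class `alpha_filtration`: points, `edges`/`tri`/`tet`
#'   vertex-index matrices (1-based, rows sorted), their filtration values
#'   `edge_val`/`tri_val`/`tet_val`, the per-triangle edge indices
#'   `tri_edges`, and metadata (`planar`, `jitter_seed`).
#' @export
build_alpha_filtration <- function(cloud, jitter = 1e-9, jitter_seed = 1L) {
  cloud <- as.matrix(cloud)
  if (ncol(cloud) != 3L) stop("`cloud` must be an R x 3 matrix")
  n <- nrow(cloud)
  if (n < 3L) stop("need at least 3 points to build a filtration")
  if (!all(is.finite(cloud))) stop("coordinates must be finite")

  pts <- cloud + with_seed(jitter_seed,
                           matrix(rnorm(3 * n, sd = jitter), n, 3))
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr, nu = 0)$d
  scale <- max(sv[1], 1e-12)
  if (sv[2] <= scale * 1e-8) {
    stop("degenerate input: points are (numerically) collinear")
  }
  planar <- n < 4L || sv[3] <= scale * 1e-6

  if (!planar) {
    del <- cpp_delaunay3(pts)
    if (nrow(del$simplices) == 0L) planar <- TRUE  # all tetrahedra flat
  }

  if (planar) {
    basis <- svd(ctr, nv = 3L)$v[, 1:2, drop = FALSE]
    Y <- ctr %*% basis
    del2 <- cpp_delaunay2(Y)
    tri <- t(apply(del2$simplices, 1, sort))
    if (nrow(del2$simplices) == 0L) stop("no valid triangles in planar cloud")
    tri_val <- sqrt(del2$r2)
    tet <- matrix(integer(0), 0, 4)
    tet_val <- numeric(0)
    work <- Y                     # Gabriel tests in the projection plane
  } else {
    tet <- t(apply(del$simplices, 1, sort))
    tet_val <- sqrt(del$r2)
    faces <- rbind(tet[, c(1, 2, 3)], tet[, c(1, 2, 4)],
                   tet[, c(1, 3, 4)], tet[, c(2, 3, 4)])
    key <- (faces[, 1] * (n + 1) + faces[, 2]) * (n + 1) + faces[, 3]
    keep <- !duplicated(key)
    tri <- faces[keep, , drop = FALSE]
    tri_val <- rep(NA_real_, nrow(tri))
    work <- pts
  }

  # triangle circumradii / Gabriel status (only needed in 3D; in 2D the
  # triangle is top-dimensional and its value is its circumradius)
  if (!planar) {
    a <- work[tri[, 1], , drop = FALSE]
    u <- work[tri[, 2], , drop = FALSE] - a
    v <- work[tri[, 3], , drop = FALSE] - a
    uu <- rowSums(u * u); vv <- rowSums(v * v); uv <- rowSums(u * v)
    dt <- uu * vv - uv * uv
    s <- vv * (uu - uv) / (2 * dt)
    t2 <- uu * (vv - uv) / (2 * dt)
    cc <- a + s * u + t2 * v
    tri_r2 <- rowSums((cc - a)^2)
    tri_gab <- gabriel_empty(work, cc, tri_r2, tri)
    # map triangles to their tetrahedron cofaces
    tri_key <- (tri[, 1] * (n + 1) + tri[, 2]) * (n + 1) + tri[, 3]
    face_key <- (faces[, 1] * (n + 1) + faces[, 2]) * (n + 1) + faces[, 3]
    face_tet <- rep(seq_len(nrow(tet)), 4)
    coface_min <- tapply(tet_val[face_tet], face_key, min)
    tri_cof <- as.numeric(coface_min[as.character(tri_key)])
    tri_val <- ifelse(tri_gab, sqrt(tri_r2), tri_cof)
    tri_val <- pmin(tri_val, tri_cof)      # enforce face monotonicity
  }

  # edges = faces of the triangles
  epairs <- rbind(tri[, c(1, 2)], tri[, c(1, 3)], tri[, c(2, 3)])
  ekey <- epairs[, 1] * (n + 1) + epairs[, 2]
  keep <- !duplicated(ekey)
  edges <- epairs[keep, , drop = FALSE]
  mid <- (work[edges[, 1], , drop = FALSE] + work[edges[, 2], , drop = FALSE]) / 2
  e_r2 <- rowSums((work[edges[, 1], , drop = FALSE] - mid)^2)
  e_gab <- gabriel_empty(work, mid, e_r2, edges)
  edge_tri <- rep(seq_len(nrow(tri)), 3)
  cof_min <- tapply(tri_val[edge_tri], ekey, min)
  e_cof <- as.numeric(cof_min[as.character(edges[, 1] * (n + 1) + edges[, 2])])
  edge_val <- ifelse(e_gab, sqrt(e_r2), e_cof)
  edge_val <- pmin(edge_val, e_cof)

  # per-triangle edge indices and the inverse incidence
  eidx <- seq_len(nrow(edges))
  names(eidx) <- edges[, 1] * (n + 1) + edges[, 2]
  tri_edges <- cbind(eidx[as.character(tri[, 1] * (n + 1) + tri[, 2])],
                     eidx[as.character(tri[, 1] * (n + 1) + tri[, 3])],
                     eidx[as.character(tri[, 2] * (n + 1) + tri[, 3])])
  dimnames(tri_edges) <- NULL
  edge_tri <- split(rep(seq_len(nrow(tri)), 3),
                    factor(as.vector(tri_edges), levels = seq_len(nrow(edges))))

  structure(list(points = pts, n = n,
                 edges = edges, edge_val = unname(edge_val),
                 tri = tri, tri_val = unname(tri_val), tri_edges = tri_edges,
                 edge_tri = unname(edge_tri),
                 tet = tet, tet_val = tet_val,
                 planar = planar, jitter_seed = jitter_seed, jitter = jitter),
            class = "alpha_filtration")
}

# Is each simplex's minimal circumscribing ball empty of all other points?
# `centres` and `r2` give the balls; `verts` the vertices to exclude.
gabriel_empty <- function(pts, centres, r2, verts) {
  m <- nrow(centres)
  out <- logical(m)
  d2 <- outer(rowSums(centres^2), rep(1, nrow(pts))) -
    2 * centres %*% t(pts) +
    outer(rep(1, m), rowSums(pts^2))
  for (i in seq_len(m)) {
    inside <- which(d2[i, ] < r2[i])
    out[i] <- length(setdiff(inside, verts[i, ])) == 0L
  }
  out
}

#' @export
print.alpha_filtration <- function(x, ...) {
  cat("<alpha_filtration>", x$n, "points;", nrow(x$edges), "edges,",
      nrow(x$tri), "triangles,", nrow(x$tet), "tetrahedra",
      if (x$planar) "(planar)" else "", "\n")
  invisible(x)
}

#' Degree-1 persistence pairs of an alpha filtration
#'
#' Standard boundary-matrix reduction over Z2 restricted to degree 1
#' (triangle columns against edge rows, in filtration order). Each finite
#' pair records the birth and death radii, the creating edge and the killing
#' triangle. Pairs with zero lifetime are dropped; essential (never-dying)
#' classes, not expected for a filtered Delaunay complex, are reported in the
#' `"essential"` attribute.
#'
#' @param filtration an [build_alpha_filtration()] result.
#' @return Object of class `ph_pairs`: a data frame with columns `birth`,
#'   `death`, `birth_edge`, `death_triangle` (indices into the filtration's
#'   edge/triangle tables), with attribute `"volumes"` holding, per pair, the
#'   triangle set accumulated during reduction (a feasible volume whose
#'   boundary is a cycle alive on `[birth, death)`).
#' @export
compute_ph1 <- function(filtration) {
  f <- filtration
  ne <- nrow(f$edges); nt <- nrow(f$tri)
  pairs0 <- data.frame(birth = numeric(0), death = numeric(0),
                       birth_edge = integer(0), death_triangle = integer(0))
  if (nt == 0L || ne == 0L) {
    attr(pairs0, "volumes") <- list()
    attr(pairs0, "essential") <- integer(0)
    class(pairs0) <- c("ph_pairs", "data.frame")
    return(pairs0)
  }
  ord_e <- order(f$edge_val, f$edges[, 1], f$edges[, 2])
  pos_e <- integer(ne); pos_e[ord_e] <- seq_len(ne)
  ord_t <- order(f$tri_val, f$tri[, 1], f$tri[, 2], f$tri[, 3])

  cols <- lapply(ord_t, function(tt) pos_e[f$tri_edges[tt, ]])
  red <- cpp_reduce_z2(cols, ne)
  paired <- which(red$pivots > 0L)
  pair_edge <- ord_e[red$pivots[paired]]
  pair_tri <- ord_t[paired]
  pair_vol <- lapply(red$v[paired], function(v) ord_t[v])

  birth <- f$edge_val[pair_edge]
  death <- f$tri_val[pair_tri]
  keep <- death - birth > 1e-10 * pmax(1, death)
  out <- data.frame(birth = birth[keep], death = death[keep],
                    birth_edge = pair_edge[keep],
                    death_triangle = pair_tri[keep])
  vols <- pair_vol[keep]
  o <- order(out$birth, out$death)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "volumes") <- vols[o]
  attr(out, "essential") <- essential_edges(f, pair_edge)
  class(out) <- c("ph_pairs", "data.frame")
  out
}

# positive edges (those creating a 1-cycle) never paired with a triangle
essential_edges <- function(f, paired_edges) {
  ord_e <- order(f$edge_val, f$edges[, 1], f$edges[, 2])
  parent <- seq_len(f$n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  positive <- integer(0)
  for (e in ord_e) {
    a <- find(f$edges[e, 1]); b <- find(f$edges[e, 2])
    if (a == b) positive <- c(positive, e) else parent[a] <- b
  }
  setdiff(positive, paired_edges)
}
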