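# Independent oracles used to validate the production implementations.
# These deliberately share no code with the package internals beyond the
# filtration data structure they are checking against.

# Naive persistence: reduce the FULL boundary matrix (vertices, edges,
# triangles, tetrahedra in one matrix, filtration order, classic left-to-
# right column algorithm with repeated column searches, no optimizations)
# and read off the degree-1 pairs (edge row / triangle column pivots).
naive_ph1_pairs <- function(filt) {
  nv <- filt$n
  ne <- nrow(filt$edges); nt <- nrow(filt$tri); nk <- nrow(filt$tet)
  # global simplex table: value, dim, vertex key for ordering
  vals <- c(rep(0, nv), filt$edge_val, filt$tri_val, filt$tet_val)
  dims <- c(rep(0L, nv), rep(1L, ne), rep(2L, nt), rep(3L, nk))
  keys <- c(seq_len(nv),
            filt$edges[, 1] * (nv + 1) + filt$edges[, 2],
            (filt$tri[, 1] * (nv + 1) + filt$tri[, 2]) * (nv + 1) + filt$tri[, 3],
            if (nk) ((filt$tet[, 1] * (nv + 1) + filt$tet[, 2]) * (nv + 1) +
                       filt$tet[, 3]) * (nv + 1) + filt$tet[, 4] else numeric(0))
  ord <- order(vals, dims, keys)
  pos <- integer(length(ord)); pos[ord] <- seq_along(ord)
  m <- length(ord)
  # dense logical boundary matrix in filtration order
  B <- matrix(FALSE, m, m)
  for (e in seq_len(ne)) {
    B[pos[filt$edges[e, 1]], pos[nv + e]] <- TRUE
    B[pos[filt$edges[e, 2]], pos[nv + e]] <- TRUE
  }
  edge_col <- function(i, j) {
    hit <- which(filt$edges[, 1] == i & filt$edges[, 2] == j)
    pos[nv + hit]
  }
  for (t in seq_len(nt)) {
    v <- filt$tri[t, ]
    for (pr in list(v[c(1, 2)], v[c(1, 3)], v[c(2, 3)])) {
      B[edge_col(pr[1], pr[2]), pos[nv + ne + t]] <- TRUE
    }
  }
  tri_col <- function(v3) {
    hit <- which(filt$tri[, 1] == v3[1] & filt$tri[, 2] == v3[2] &
                   filt$tri[, 3] == v3[3])
    pos[nv + ne + hit]
  }
  for (k in seq_len(nk)) {
    v <- filt$tet[k, ]
    for (f3 in list(v[c(1, 2, 3)], v[c(1, 2, 4)], v[c(1, 3, 4)], v[c(2, 3, 4)])) {
      B[tri_col(f3), pos[nv + ne + nt + k]] <- TRUE
    }
  }
  low <- function(col) { w <- which(col); if (length(w)) max(w) else 0L }
  for (j in seq_len(m)) {
    repeat {
      lj <- low(B[, j])
      if (lj == 0L) break
      j2 <- 0L
      for (jj in seq_len(j - 1L)) {
        if (low(B[, jj]) == lj) { j2 <- jj; break }
      }
      if (j2 == 0L) break
      B[, j] <- xor(B[, j], B[, j2])
    }
  }
  gdim <- dims[ord]; gval <- vals[ord]
  pairs <- data.frame(birth = numeric(0), death = numeric(0))
  for (j in seq_len(m)) {
    lj <- low(B[, j])
    if (lj > 0L && gdim[j] == 2L && gdim[lj] == 1L) {
      b <- gval[lj]; d <- gval[j]
      if (d - b > 1e-10 * max(1, d)) {
        pairs <- rbind(pairs, data.frame(birth = b, death = d))
      }
    }
  }
  pairs[order(pairs$birth, pairs$death), , drop = FALSE]
}

# Exhaustive volume-optimal search: enumerate all triangle subsets
# containing the death triangle by increasing size and return every optimal
# volume (as sorted triangle-index vectors) plus the optimum size.
exhaustive_voc <- function(filt, pair, max_size = 8L) {
  d <- pair$death; b <- pair$birth
  tol <- 1e-9 * max(1, d)
  cand <- which(filt$tri_val <= d + tol)
  stopifnot(length(cand) <= 22L)
  others <- setdiff(cand, pair$death_triangle)
  ne <- nrow(filt$edges)
  feasible <- function(omega) {
    tab <- tabulate(as.vector(filt$tri_edges[omega, , drop = FALSE]), nbins = ne)
    bd <- which(tab %% 2L == 1L)
    all(filt$edge_val[bd] <= b + tol)
  }
  for (sz in seq_len(min(max_size, length(others) + 1L))) {
    sols <- list()
    if (sz == 1L) {
      if (feasible(pair$death_triangle)) sols <- list(pair$death_triangle)
    } else {
      cmb <- utils::combn(others, sz - 1L)
      for (cix in seq_len(ncol(cmb))) {
        omega <- sort(c(pair$death_triangle, cmb[, cix]))
        if (feasible(omega)) sols <- c(sols, list(omega))
      }
    }
    if (length(sols)) return(list(size = sz, solutions = sols))
  }
  stop("no feasible volume up to size ", max_size)
}

# RMSD oracle: direct numeric minimization over rotations (Euler angles,
# multi-start Nelder-Mead), independent of the closed-form SVD solution.
rmsd_optim_oracle <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rot <- function(a) {
    cx <- cos(a[1]); sx <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
    Rx %*% Ry %*% Rz
  }
  obj <- function(a) sqrt(mean(rowSums((Pc %*% rot(a) - Qc)^2)))
  best <- Inf
  for (s in 1:12) {
    a0 <- c(s, 2 * s, 3 * s) %% (2 * pi)
    o <- stats::optim(a0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, o$value)
  }
  best
}

# Brute-force groupby-average oracle for flow-field cell means.
groupby_flow_oracle <- function(points, axes, edges) {
  P <- points$positions[, axes, drop = FALSE]
  Vl <- points$velocities[, axes, drop = FALSE]
  k <- length(axes)
  nb <- length(edges[[1]]) - 1L
  idx <- sapply(seq_len(k), function(a) {
    pmin(pmax(findInterval(P[, a], edges[[a]], rightmost.closed = TRUE), 1L), nb)
  })
  idx <- matrix(idx, ncol = k)
  key <- apply(idx, 1, paste, collapse = ",")
  out <- list()
  for (kk in unique(key)) {
    sel <- key == kk
    out[[kk]] <- list(count = sum(sel),
                      mean = colMeans(Vl[sel, , drop = FALSE]))
  }
  out
}

# Small deterministic random cloud
random_cloud <- function(n, seed, scale = 5) {
  set.seed(seed)
  matrix(rnorm(3 * n), n, 3) * scale
}
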