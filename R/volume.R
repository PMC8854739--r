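#' Volume-optimal representative cycle for a persistence pair
#'
#' Finds a set of triangles Omega of minimal cardinality such that (i) the
#' pair's death triangle belongs to Omega, (ii) every triangle in Omega has
#' filtration value <= death, and (iii) the Z2 boundary of Omega consists
#' only of edges with filtration value <= birth. The returned cycle is that
#' boundary: the "minimal" loop surrounding the empty space the pair
#' detects. The search is exact branch-and-bound over Z2 triangle sets,
#' warm-started with the feasible volume read off the persistence reduction;
#' ties in |Omega| are broken by the lexicographically smallest sorted edge
#' list.
#'
#' @param filtration an [build_alpha_filtration()] result.
#' @param pair one row of a [compute_ph1()] result (or a list with fields
#'   `birth`, `death`, `birth_edge`, `death_triangle`).
#' @param warm_start optional integer vector of triangle indices forming a
#'   feasible volume (as stored in the `"volumes"` attribute of `ph_pairs`).
#' @param max_nodes branch-and-bound node budget.
#' @return Object of class `ph_cycle`: list with `birth`, `death`, `cycle`
#'   (k x 2 matrix of residue-index pairs, i < j), `volume_size`, and
#'   `triangles` (the optimal volume, as filtration triangle indices).
#' @export
volume_optimal_cycle <- function(filtration, pair, warm_start = NULL,
                                 max_nodes = 200000L) {
  f <- filtration
  b <- pair$birth; d <- pair$death
  death_tri <- pair$death_triangle
  tol <- 1e-9 * max(1, d)

  admissible <- f$tri_val <= d + tol            # triangles allowed in Omega
  if (!admissible[death_tri]) stop("death triangle not among candidates")
  forbidden <- f$edge_val > b + tol             # edges not allowed in dOmega
  ne <- nrow(f$edges)

  # parity over all edges; uncovered = forbidden edges with odd coefficient
  parity0 <- integer(ne)
  e0 <- f$tri_edges[death_tri, ]
  parity0[e0] <- 1L

  best_size <- if (!is.null(warm_start)) length(warm_start) else .Machine$integer.max
  solutions <- if (!is.null(warm_start)) list(sort(warm_start)) else list()
  nodes <- 0L
  exhausted <- FALSE
  max_ties <- 64L    # cap on co-optimal solutions kept for the tie-break

  # number of admissible triangles per edge, for fail-first branching
  adm_count <- vapply(f$edge_tri, function(tt) sum(admissible[tt]), integer(1))

  rec <- function(omega, parity, banned) {
    if (exhausted) return(invisible())
    nodes <<- nodes + 1L
    if (nodes > max_nodes) { exhausted <<- TRUE; return(invisible()) }
    unc <- which(parity == 1L & forbidden)
    if (length(unc) == 0L) {
      sz <- length(omega)
      if (sz < best_size) {
        best_size <<- sz
        solutions <<- list(sort(omega))
      } else if (sz == best_size && length(solutions) < max_ties) {
        solutions <<- c(solutions, list(sort(omega)))
      }
      return(invisible())
    }
    lb <- length(omega) + ceiling(length(unc) / 3)
    if (lb > best_size ||
        (lb == best_size && length(solutions) >= max_ties)) {
      return(invisible())
    }
    e <- unc[which.min(adm_count[unc])]
    opts <- f$edge_tri[[e]]
    opts <- opts[admissible[opts]]
    opts <- opts[!(opts %in% omega) & !(opts %in% banned)]
    for (k in seq_along(opts)) {
      t <- opts[k]
      p2 <- parity
      te <- f$tri_edges[t, ]
      p2[te] <- 1L - p2[te]
      rec(c(omega, t), p2, c(banned, opts[seq_len(k - 1L)]))
    }
    invisible()
  }
  rec(death_tri, parity0, integer(0))

  if (length(solutions) == 0L) stop("no feasible volume found (infeasible pair)")
  if (exhausted) {
    warning("volume-optimal cycle search budget exceeded; ",
            "returning the best volume found (size ",
            min(lengths(solutions)), "), which may not be minimal")
  }
  sizes <- lengths(solutions)
  solutions <- unique(solutions[sizes == min(sizes)])

  boundary_of <- function(omega) {
    eids <- as.vector(f$tri_edges[omega, , drop = FALSE])
    tab <- tabulate(eids, nbins = ne)
    which(tab %% 2L == 1L)
  }
  keys <- lapply(solutions, function(s) {
    ce <- sort(boundary_of(s))
    pr <- f$edges[ce, , drop = FALSE]
    as.vector(t(pr[order(pr[, 1], pr[, 2]), , drop = FALSE]))
  })
  pick <- 1L
  if (length(keys) > 1L) {
    o <- do.call(order, as.data.frame(t(vapply(keys, function(k) {
      length(k) <- max(lengths(keys)); k[is.na(k)] <- .Machine$integer.max; k
    }, integer(max(lengths(keys)))))))
    pick <- o[1]
  }
  omega <- solutions[[pick]]
  ce <- boundary_of(omega)
  stopifnot(all(f$edge_val[ce] <= b + tol))
  cyc <- f$edges[ce, , drop = FALSE]
  cyc <- cyc[order(cyc[, 1], cyc[, 2]), , drop = FALSE]
  deg <- tabulate(as.vector(cyc), nbins = f$n)
  stopifnot(all(deg %% 2L == 0L))
  structure(list(birth = b, death = d, cycle = unname(cyc),
                 volume_size = length(omega), triangles = omega,
                 optimal = !exhausted),
            class = "ph_cycle")
}

#' @export
print.ph_cycle <- function(x, ...) {
  cat(sprintf("<ph_cycle> (b, d) = (%.4f, %.4f) A; %d edges; optimal volume %d triangles\n",
              x$birth, x$death, nrow(x$cycle), x$volume_size))
  invisible(x)
}

#' Degree-1 persistence diagram with volume-optimal cycles for one snapshot
#'
#' Composes the filtration construction, the degree-1 reduction and the
#' volume-optimal cycle extraction. Deterministic given the jitter seed.
#'
#' @param cloud R x 3 coordinate matrix.
#' @param jitter,jitter_seed passed to [build_alpha_filtration()].
#' @param snapshot_id optional identifier carried into exports.
#' @return Object of class `ph_diagram`: list with `cycles` (list of
#'   `ph_cycle`), `pairs` (data frame with birth, death, n_edges,
#'   volume_size), `n_residues`, `snapshot_id`, `jitter_seed`.
#' @export
diagram_for_snapshot <- function(cloud, jitter = 1e-9, jitter_seed = 1L,
                                 snapshot_id = NA_character_) {
  filt <- build_alpha_filtration(cloud, jitter = jitter,
                                 jitter_seed = jitter_seed)
  pairs <- compute_ph1(filt)
  vols <- attr(pairs, "volumes")
  cycles <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    cycles[[i]] <- volume_optimal_cycle(filt, pairs[i, ],
                                        warm_start = vols[[i]])
  }
  df <- data.frame(
    birth = pairs$birth, death = pairs$death,
    n_edges = vapply(cycles, function(c) nrow(c$cycle), integer(1)),
    volume_size = vapply(cycles, function(c) c$volume_size, integer(1))
  )
  structure(list(cycles = cycles, pairs = df, n_residues = nrow(cloud),
                 snapshot_id = snapshot_id, jitter_seed = jitter_seed),
            class = "ph_diagram")
}

#' @export
print.ph_diagram <- function(x, ...) {
  cat("<ph_diagram>", length(x$cycles), "degree-1 cycles on", x$n_residues,
      "residues\n")
  if (nrow(x$pairs)) print(utils::head(x$pairs, 10))
  invisible(x)
}

#' @export
as.data.frame.ph_diagram <- function(x, ...) x$pairs
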