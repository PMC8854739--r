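#' Reduced-space trajectory of NMF scores
#'
#' Bundles the per-frame coefficient scores of one trajectory (columns of
#' `H` for its snapshots) into an ordered reduced trajectory.
#'
#' @param id trajectory identifier.
#' @param scores frames x L matrix of non-negative scores (Angstrom).
#' @param frame_interval snapshot spacing, ps.
#' @return Object of class `reduced_trajectory`.
#' @export
reduced_trajectory <- function(id, scores, frame_interval = 250) {
  scores <- as.matrix(scores)
  if (any(scores < 0)) stop("NMF scores must be non-negative")
  structure(list(id = id, scores = scores, frame_interval = frame_interval),
            class = "reduced_trajectory")
}

#' Split NMF scores into per-trajectory reduced trajectories
#'
#' @param H L x M coefficient matrix (columns = snapshots).
#' @param meta data frame with one row per column of `H`, containing
#'   `trajectory_id` and `frame` (frame order within trajectory).
#' @param frame_interval snapshot spacing, ps.
#' @return list of `reduced_trajectory`, in first-appearance order.
#' @export
split_scores <- function(H, meta, frame_interval = 250) {
  if (ncol(H) != nrow(meta)) stop("metadata rows must match score columns")
  ids <- unique(meta$trajectory_id)
  lapply(ids, function(id) {
    sel <- which(meta$trajectory_id == id)
    sel <- sel[order(meta$frame[sel])]
    reduced_trajectory(id, t(H[, sel, drop = FALSE]), frame_interval)
  })
}

#' Finite-difference velocities along a reduced trajectory
#'
#' The velocity at frame t is `score(t+1) - score(t)` (Angstrom per frame
#' interval), attributed to the position `score(t)`. Velocities never span
#' trajectory boundaries.
#'
#' @param rt a `reduced_trajectory`, or a list of them (velocities are then
#'   concatenated per trajectory).
#' @return list with `positions`, `velocities` (matrices with one row per
#'   velocity sample) and `trajectory_id`.
#' @export
frame_velocities <- function(rt) {
  if (is.list(rt) && !inherits(rt, "reduced_trajectory")) {
    parts <- lapply(rt, frame_velocities)
    return(list(
      positions = do.call(rbind, lapply(parts, `[[`, "positions")),
      velocities = do.call(rbind, lapply(parts, `[[`, "velocities")),
      trajectory_id = unlist(lapply(parts, `[[`, "trajectory_id"))
    ))
  }
  s <- rt$scores
  n <- nrow(s)
  if (n < 2L) {
    warning("trajectory ", rt$id, " has a single frame; no velocities")
    return(list(positions = s[0, , drop = FALSE],
                velocities = s[0, , drop = FALSE],
                trajectory_id = character(0)))
  }
  list(positions = s[-n, , drop = FALSE],
       velocities = s[-1, , drop = FALSE] - s[-n, , drop = FALSE],
       trajectory_id = rep(rt$id, n - 1L))
}

#' Grid-binned mean-velocity flow field in reduced space
#'
#' Divides the selected score components into a regular grid spanning the
#' data range and computes each cell's sample count and arithmetic-mean
#' velocity. Cells with `count <= min_count` report their count but carry no
#' velocity estimate ("more than `min_count` samples" is read strictly).
#'
#' @param points velocity samples from [frame_velocities()].
#' @param axes score-component indices defining the grid (2 or 3 of them).
#' @param bins_per_axis number of cells per axis (>= 2).
#' @param min_count strict sample-count threshold for reporting a velocity.
#' @return Object of class `flow_field`: `axes`, `edges` (per-axis bin
#'   edges), and `cells` (data frame: per-axis cell index and centre, count,
#'   mean-velocity components `v_*`).
#' @export
bin_flow <- function(points, axes, bins_per_axis = 20L, min_count = 100L) {
  if (length(points$trajectory_id) == 0L) stop("no velocity samples")
  if (anyDuplicated(axes)) stop("`axes` must be distinct")
  stopifnot_scalar_count(bins_per_axis, "bins_per_axis", min = 2L)
  P <- points$positions[, axes, drop = FALSE]
  Vl <- points$velocities[, axes, drop = FALSE]
  k <- length(axes)
  edges <- lapply(seq_len(k), function(a) {
    rng <- range(P[, a])
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    seq(rng[1], rng[2], length.out = bins_per_axis + 1L)
  })
  idx <- vapply(seq_len(k), function(a) {
    as.integer(pmin(pmax(findInterval(P[, a], edges[[a]],
                                      rightmost.closed = TRUE), 1L),
                    bins_per_axis))
  }, integer(nrow(P)))
  idx <- matrix(idx, ncol = k)
  key <- as.vector((idx - 1L) %*% bins_per_axis^(seq_len(k) - 1L)) + 1L
  counts <- tabulate(key, nbins = bins_per_axis^k)
  occupied <- which(counts > 0L)
  vsum <- rowsum(Vl, key)
  vkeys <- as.integer(rownames(vsum))
  cells <- data.frame(cell = occupied)
  for (a in seq_len(k)) {
    ia <- ((occupied - 1L) %/% bins_per_axis^(a - 1L)) %% bins_per_axis + 1L
    cells[[paste0("i", a)]] <- ia
    cells[[paste0("centre", a)]] <-
      (edges[[a]][ia] + edges[[a]][ia + 1L]) / 2
  }
  cells$count <- counts[occupied]
  vm <- vsum[match(occupied, vkeys), , drop = FALSE] / cells$count
  for (a in seq_len(k)) {
    v <- vm[, a]
    v[cells$count <= min_count] <- NA_real_
    cells[[paste0("v", a)]] <- v
  }
  structure(list(axes = axes, edges = edges, bins_per_axis = bins_per_axis,
                 min_count = as.integer(min_count), cells = cells),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  est <- sum(!is.na(x$cells[[paste0("v", 1)]]))
  cat("<flow_field> components", paste(x$axes, collapse = ", "), ";",
      x$bins_per_axis, "bins/axis;", nrow(x$cells), "occupied cells,",
      est, "with velocity estimates (count >", x$min_count, ")\n")
  invisible(x)
}

#' Two-dimensional histogram of velocities inside a score-space region
#'
#' Selects the velocity samples whose projected position lies strictly
#' inside the given per-axis intervals and histograms their velocity
#' components. Used to expose multi-modal motion that a mean-velocity field
#' averages away.
#'
#' @param points velocity samples from [frame_velocities()].
#' @param axes two score-component indices.
#' @param region list of two intervals `c(lo, hi)` (open) on those axes.
#' @param bins number of histogram bins per velocity axis.
#' @return list with `counts` (bins x bins matrix), `vx_edges`, `vy_edges`,
#'   and `n` (selected sample count).
#' @export
velocity_histogram <- function(points, axes, region, bins = 25L) {
  if (length(axes) != 2L || length(region) != 2L) {
    stop("`axes` and `region` must each have length 2")
  }
  for (r in region) if (!(r[1] < r[2])) stop("region intervals must be non-empty")
  P <- points$positions[, axes, drop = FALSE]
  sel <- P[, 1] > region[[1]][1] & P[, 1] < region[[1]][2] &
    P[, 2] > region[[2]][1] & P[, 2] < region[[2]][2]
  Vs <- points$velocities[sel, axes, drop = FALSE]
  if (nrow(Vs) == 0L) {
    warning("no samples inside the region; empty histogram")
    return(list(counts = matrix(0L, 0, 0), vx_edges = numeric(0),
                vy_edges = numeric(0), n = 0L))
  }
  ex <- hist_edges(Vs[, 1], bins)
  ey <- hist_edges(Vs[, 2], bins)
  ix <- pmin(pmax(findInterval(Vs[, 1], ex, rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(Vs[, 2], ey, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0L, bins, bins)
  for (i in seq_along(ix)) counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1L
  list(counts = counts, vx_edges = ex, vy_edges = ey, n = nrow(Vs))
}

hist_edges <- function(x, bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  seq(rng[1], rng[2], length.out = bins + 1L)
}

#' Density histogram of positions in reduced space
#'
#' Plain occupancy counts on a regular grid (any logarithmic display
#' transform is presentation metadata, not stored data).
#'
#' @param positions matrix of reduced-space positions.
#' @param axes score-component indices.
#' @param bins bins per axis.
#' @return list with `counts` (k-dimensional array) and `edges`.
#' @export
density_histogram <- function(positions, axes, bins = 20L) {
  P <- as.matrix(positions)[, axes, drop = FALSE]
  if (nrow(P) == 0L) stop("no positions to histogram")
  k <- ncol(P)
  edges <- lapply(seq_len(k), function(a) hist_edges(P[, a], bins))
  idx <- vapply(seq_len(k), function(a) {
    as.integer(pmin(pmax(findInterval(P[, a], edges[[a]],
                                      rightmost.closed = TRUE), 1L), bins))
  }, integer(nrow(P)))
  idx <- matrix(idx, ncol = k)
  counts <- array(0L, dim = rep(bins, k))
  key <- as.vector((idx - 1L) %*% bins^(seq_len(k) - 1L)) + 1L
  tab <- tabulate(key, nbins = bins^k)
  counts[] <- tab
  list(counts = counts, edges = edges)
}

#' Trailing moving-average smoothing of reduced-trajectory scores
#'
#' Replaces each score series by its trailing `k`-frame mean (initial
#' frames use the partial window). Used before threshold-crossing
#' classification so an isolated one-frame score blip cannot register as a
#' crossing.
#'
#' @param rt a `reduced_trajectory`.
#' @param k window length in frames.
#' @return the smoothed `reduced_trajectory`.
#' @export
smooth_scores <- function(rt, k = 3L) {
  n <- nrow(rt$scores)
  s <- apply(rt$scores, 2, function(x) {
    f <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 1))
    head_n <- min(k - 1L, n)
    f[seq_len(head_n)] <- cumsum(x[seq_len(head_n)]) / seq_len(head_n)
    f
  })
  rt$scores <- matrix(s, nrow = n)
  rt
}

#' Classify folding paths by threshold-crossing order of two components
#'
#' Operationalizes the two-path picture: a trajectory is labelled `"A"` when
#' the first selected component crosses its threshold strictly before the
#' second one does, `"B"` otherwise; trajectories in which neither component
#' ever crosses are `"unresolved"`. Crossing = first frame with score above
#' the threshold. This is a derived classification rule, not a statistic
#' defined by the persistence analysis itself.
#'
#' @param rts list of `reduced_trajectory`.
#' @param components two score-component indices.
#' @param threshold scalar or length-2 score threshold (Angstrom), > 0.
#' @return data frame: `trajectory_id`, `label`, `cross_1`, `cross_2`
#'   (crossing frame indices, `NA` when never crossed).
#' @export
classify_paths <- function(rts, components, threshold) {
  if (length(components) != 2L) stop("`components` must have length 2")
  threshold <- rep_len(threshold, 2L)
  if (any(threshold <= 0)) stop("`threshold` must be positive")
  rows <- lapply(rts, function(rt) {
    s <- rt$scores
    c1 <- which(s[, components[1]] > threshold[1])[1]
    c2 <- which(s[, components[2]] > threshold[2])[1]
    t1 <- if (is.na(c1)) Inf else c1
    t2 <- if (is.na(c2)) Inf else c2
    label <- if (is.infinite(t1) && is.infinite(t2)) "unresolved"
    else if (t1 < t2) "A" else "B"
    data.frame(trajectory_id = rt$id, label = label,
               cross_1 = ifelse(is.finite(t1), t1, NA),
               cross_2 = ifelse(is.finite(t2), t2, NA),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a flow field as long-format CSV
#'
#' @param ff a `flow_field`.
#' @param path output CSV path.
#' @export
write_flow_field <- function(ff, path) {
  write.csv(ff$cells, path, row.names = FALSE)
  invisible(path)
}
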