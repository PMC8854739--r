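#' Kabsch RMSD between two point clouds
#'
#' Root-mean-square deviation after optimal rigid-body superposition
#' (rotation + translation; proper rotations only, the standard
#' structural-biology convention — reflections are excluded via the
#' determinant correction of the Kabsch SVD solution).
#'
#' @param P,Q coordinate matrices with the same residue count (>= 3 rows).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!identical(dim(P), dim(Q))) {
    stop("point clouds must have identical dimensions")
  }
  if (nrow(P) < 3L || ncol(P) != 3L) {
    stop("point clouds must be R x 3 with R >= 3")
  }
  if (!all(is.finite(P)) || !all(is.finite(Q))) {
    stop("coordinates must be finite")
  }
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$u %*% t(s$v)))
  Rm <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((Pc %*% Rm - Qc)^2)))
}

is_degenerate_frame <- function(frame, tol = 1e-12) {
  if (nrow(frame) < 2L) return(TRUE)
  all(apply(frame, 2, var) <= tol)
}

#' Remove frozen-coordinate frames
#'
#' Drops every frame in which all residues share one identical coordinate
#' triple (per-axis coordinate variance 0 within `tol`), the signature of
#' corrupted snapshots merged into distributed-computing trajectories. The
#' rule is applied to all frames, not only trailing ones.
#'
#' @param traj a `fold_trajectory`.
#' @param tol variance tolerance, Angstrom^2.
#' @return list with `trajectory` (frames preserved in order) and `removed`
#'   (count of dropped frames).
#' @export
strip_degenerate_frames <- function(traj, tol = 1e-12) {
  bad <- vapply(traj$frames, is_degenerate_frame, logical(1), tol = tol)
  if (all(bad)) stop("all frames are degenerate; nothing left of trajectory ",
                     traj$id)
  traj$frames <- traj$frames[!bad]
  traj$meta$frames_removed <- sum(bad)
  list(trajectory = traj, removed = sum(bad))
}

#' Filter a trajectory ensemble by minimum RMSD to the native state
#'
#' Implements the folded-trajectory selection: degenerate frames are removed
#' first, then each trajectory's minimum frame-wise Kabsch RMSD to the native
#' state is computed, and exactly the trajectories with minimum RMSD strictly
#' below `cutoff` are kept. Ties at the cutoff are excluded.
#'
#' @param ensemble list of `fold_trajectory`.
#' @param native native point cloud (same residue count).
#' @param cutoff RMSD cutoff, Angstrom (default 1.0).
#' @param strip_degenerate remove frozen-coordinate frames before computing
#'   the minimum.
#' @return list with `kept` (filtered ensemble) and `report` (data frame with
#'   `trajectory_id`, `min_rmsd`, `kept`, `frames_removed`).
#' @export
filter_trajectories <- function(ensemble, native, cutoff = 1.0,
                                strip_degenerate = TRUE) {
  if (!is.list(ensemble) || length(ensemble) == 0L) {
    stop("`ensemble` must be a non-empty list of trajectories")
  }
  nr <- nrow(native)
  rows <- vector("list", length(ensemble))
  cleaned <- vector("list", length(ensemble))
  for (i in seq_along(ensemble)) {
    tr <- ensemble[[i]]
    if (traj_residues(tr) != nr) {
      stop("trajectory ", tr$id, " has ", traj_residues(tr),
           " residues but native has ", nr)
    }
    removed <- 0L
    if (strip_degenerate) {
      s <- strip_degenerate_frames(tr)
      tr <- s$trajectory
      removed <- s$removed
    }
    mins <- vapply(tr$frames, kabsch_rmsd, numeric(1), Q = native)
    m <- min(mins)
    rows[[i]] <- data.frame(trajectory_id = tr$id, min_rmsd = m,
                            kept = m < cutoff, frames_removed = removed,
                            stringsAsFactors = FALSE)
    cleaned[[i]] <- tr
  }
  report <- do.call(rbind, rows)
  list(kept = cleaned[report$kept], report = report)
}

#' Write a trajectory filter report
#'
#' @param report the report data frame from [filter_trajectories()].
#' @param path output CSV path.
#' @export
write_filter_report <- function(report, path) {
  write.csv(report, path, row.names = FALSE)
  invisible(path)
}
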