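#' Dimension of the bag-of-simplices feature space
#'
#' One coordinate per unordered residue pair: `R(R-1)/2` (595 for a
#' 35-residue chain).
#'
#' @param n_residues residue count (>= 2).
#' @return integer feature dimension.
#' @export
feature_dimension <- function(n_residues) {
  stopifnot_scalar_count(n_residues, "n_residues", min = 2L)
  as.integer(n_residues * (n_residues - 1) / 2)
}

#' Lexicographic index of a residue pair
#'
#' Maps an unordered pair `(i, j)`, `i < j` (1-based), to its coordinate in
#' the bag-of-simplices vector: pairs are ordered `(1,2), (1,3), ...,
#' (1,R), (2,3), ...`.
#'
#' @param i,j residue indices (vectors allowed).
#' @param n_residues residue count.
#' @return integer vector of coordinates in `1..R(R-1)/2`.
#' @export
pair_index <- function(i, j, n_residues) {
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  if (any(i < 1L | j > n_residues | i == j)) {
    stop("residue pair out of range")
  }
  as.integer((i - 1) * n_residues - i * (i - 1) / 2 + (j - i))
}

#' Residue pair for a feature coordinate (inverse of [pair_index()])
#'
#' @param idx coordinate index vector.
#' @param n_residues residue count.
#' @return two-column integer matrix of pairs `(i, j)`, `i < j`.
#' @export
index_pair <- function(idx, n_residues) {
  R <- n_residues
  i <- findInterval(idx - 1, cumsum(c(0, (R - 1):1)), left.open = FALSE)
  off <- (i - 1) * R - i * (i - 1) / 2
  cbind(i = as.integer(i), j = as.integer(idx - off + i))
}

pair_labels <- function(n_residues) {
  p <- index_pair(seq_len(feature_dimension(n_residues)), n_residues)
  sprintf("s_%d_%d", p[, 1], p[, 2])
}

#' Bag-of-simplices feature vector for one snapshot
#'
#' Assigns each residue pair `(i, j)` the summed lifetimes `d_k - b_k` of
#' all volume-optimal cycles whose edge set contains that pair. Pairs in no
#' cycle get weight 0; the weights inherit the Angstrom radius convention of
#' the filtration. Edge membership is set-based: a duplicated edge in a
#' cycle contributes its lifetime once.
#'
#' @param cycles list of `ph_cycle` objects (or a `ph_diagram`).
#' @param n_residues residue count.
#' @return named numeric vector of length `R(R-1)/2`.
#' @export
bag_of_simplices <- function(cycles, n_residues) {
  if (inherits(cycles, "ph_diagram")) cycles <- cycles$cycles
  v <- numeric(feature_dimension(n_residues))
  for (cy in cycles) {
    if (cy$death <= cy$birth) stop("cycle with non-positive lifetime")
    e <- unique(cy$cycle)
    if (any(e < 1L) || any(e > n_residues)) {
      stop("cycle edge index out of residue range")
    }
    idx <- unique(pair_index(e[, 1], e[, 2], n_residues))
    v[idx] <- v[idx] + (cy$death - cy$birth)
  }
  names(v) <- pair_labels(n_residues)
  v
}

#' Stack feature vectors into a feature matrix
#'
#' Columns are snapshots in input order; rows are residue-pair features in
#' the lexicographic order of [pair_index()].
#'
#' @param vectors list of equal-length feature vectors.
#' @param meta optional data frame of per-snapshot metadata (one row per
#'   vector; e.g. `trajectory_id`, `frame`), attached as attribute `"meta"`.
#' @return numeric matrix N x M with non-negative entries.
#' @export
stack_features <- function(vectors, meta = NULL) {
  if (length(vectors) == 0L) stop("need at least one feature vector")
  n <- unique(lengths(vectors))
  if (length(n) != 1L) stop("feature vectors have differing dimensions")
  V <- do.call(cbind, vectors)
  if (any(V < 0)) stop("feature weights must be non-negative")
  if (!is.null(meta)) {
    if (nrow(meta) != ncol(V)) stop("metadata rows must match vector count")
    attr(V, "meta") <- meta
    colnames(V) <- if ("snapshot_id" %in% names(meta)) meta$snapshot_id else NULL
  }
  V
}

#' Write a feature matrix (with its pair labelling) to CSV
#'
#' Row names carry the `s_i_j` residue-pair labels (1-based residue
#' numbering on disk); column metadata, when present, is written to a
#' sidecar `*_meta.csv`.
#'
#' @param V feature matrix from [stack_features()].
#' @param path output CSV path.
#' @export
write_feature_matrix <- function(V, path) {
  df <- data.frame(feature = rownames(V) %||% as.character(seq_len(nrow(V))),
                   V, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  meta <- attr(V, "meta")
  if (!is.null(meta)) {
    write.csv(meta, sub("\\.csv$", "_meta.csv", path), row.names = FALSE)
  }
  invisible(path)
}
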