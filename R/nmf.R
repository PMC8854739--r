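#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius objective `||V - WH||_F` over non-negative `W`
#' (N x L) and `H` (L x M) by Lee-Seung multiplicative updates from a seeded
#' random non-negative initialization. The objective is recorded at every
#' iteration and is non-increasing; iteration stops at `max_iter` or when
#' the relative objective change drops below `tol`. The returned factors are
#' normalized so that every basis column has unit Euclidean norm (the
#' corresponding coefficient row absorbs the scale), which fixes the
#' diagonal rescaling ambiguity of NMF and gives the coefficient scores
#' units of Angstrom when `V` holds bag-of-simplices lifetimes. The residual
#' permutation ambiguity is resolved by sorting basis columns by descending
#' total coefficient mass.
#'
#' @param V non-negative numeric matrix (features x samples).
#' @param L rank, `1 <= L <= min(dim(V))`.
#' @param seed integer seed for the initialization.
#' @param max_iter maximum number of update sweeps.
#' @param tol relative objective-change stopping threshold.
#' @return Object of class `nmf_fit`: `W`, `H`, `rank`, `objective` (final
#'   `||V - WH||_F`), `objective_trace`, `iterations`, `converged`, `seed`.
#' @export
nmf_fit <- function(V, L, seed = 1L, max_iter = 2000L, tol = 1e-6) {
  V <- as.matrix(V)
  if (any(V < 0) || !all(is.finite(V))) {
    stop("`V` must be non-negative and finite")
  }
  N <- nrow(V); M <- ncol(V)
  stopifnot_scalar_count(L, "L", min = 1L)
  if (L > min(N, M)) stop("rank L exceeds min(dim(V))")
  eps <- 1e-12
  scale0 <- sqrt(mean(V) / L + eps)
  init <- with_seed(seed, list(W = matrix(runif(N * L), N, L) * scale0 + eps,
                               H = matrix(runif(L * M), L, M) * scale0 + eps))
  W <- init$W; H <- init$H
  obj <- numeric(max_iter)
  prev <- Inf
  it <- 0L
  for (k in seq_len(max_iter)) {
    H <- H * (crossprod(W, V) / (crossprod(W) %*% H + eps))
    W <- W * (V %*% t(H) / (W %*% tcrossprod(H) + eps))
    o <- sqrt(sum((V - W %*% H)^2))
    it <- k
    obj[k] <- o
    if (is.finite(prev) && abs(prev - o) < tol * max(obj[1], eps)) break
    prev <- o
  }
  obj <- obj[seq_len(it)]
  nf <- normalize_factors(W, H)
  W <- nf$W; H <- nf$H
  ord <- order(rowSums(H), decreasing = TRUE)
  structure(list(W = W[, ord, drop = FALSE], H = H[ord, , drop = FALSE],
                 rank = as.integer(L), objective = obj[it],
                 objective_trace = obj, iterations = it,
                 converged = it < max_iter, seed = as.integer(seed)),
            class = "nmf_fit")
}

#' Rescale NMF factors to unit-norm basis columns
#'
#' Scales every basis column of `W` to unit Euclidean norm and its
#' coefficient row in `H` inversely, leaving the product `WH` unchanged.
#'
#' @param W,H factor matrices.
#' @return list with rescaled `W` and `H`.
#' @export
normalize_factors <- function(W, H) {
  nrm <- sqrt(colSums(W^2))
  bad <- which(nrm == 0)
  if (length(bad)) {
    stop("basis column(s) ", paste(bad, collapse = ", "),
         " are all-zero and cannot be normalized")
  }
  list(W = sweep(W, 2, nrm, "/"), H = sweep(H, 1, nrm, "*"))
}

#' Project new samples onto a fitted NMF basis
#'
#' Non-negative least squares of each new column onto the fixed basis `W`,
#' by multiplicative updates on the coefficients only.
#'
#' @param model an `nmf_fit`.
#' @param V_new matrix with the same feature dimension as the training data.
#' @param max_iter,tol update-loop controls.
#' @param seed seed for the coefficient initialization.
#' @return list with `H` (non-negative scores, rank x M_new) and
#'   `reconstruction_error` (`||V_new - W H||_F`).
#' @export
nmf_project <- function(model, V_new, max_iter = 500L, tol = 1e-8, seed = 1L) {
  V_new <- as.matrix(V_new)
  if (nrow(V_new) != nrow(model$W)) {
    stop("feature dimension mismatch: ", nrow(V_new), " vs ", nrow(model$W))
  }
  if (any(V_new < 0)) stop("`V_new` must be non-negative")
  W <- model$W
  L <- ncol(W); M <- ncol(V_new)
  eps <- 1e-12
  H <- with_seed(seed, matrix(runif(L * M), L, M) * sqrt(mean(V_new) / L + eps) + eps)
  WtV <- crossprod(W, V_new)
  WtW <- crossprod(W)
  prev <- Inf
  for (k in seq_len(max_iter)) {
    H <- H * (WtV / (WtW %*% H + eps))
    o <- sqrt(sum((V_new - W %*% H)^2))
    if (is.finite(prev) && abs(prev - o) < tol * max(o, eps)) break
    prev <- o
  }
  H[WtV == 0] <- 0      # zero columns project to exactly zero scores
  list(H = H, reconstruction_error = sqrt(sum((V_new - W %*% H)^2)))
}

#' @export
predict.nmf_fit <- function(object, newdata, ...) {
  nmf_project(object, newdata, ...)$H
}

#' @export
coef.nmf_fit <- function(object, ...) object$H

#' @export
fitted.nmf_fit <- function(object, ...) object$W %*% object$H

#' @export
print.nmf_fit <- function(x, ...) {
  cat("<nmf_fit> rank", x$rank, ";", nrow(x$W), "features x", ncol(x$H),
      "samples\n")
  cat(sprintf("  ||V - WH||_F = %.6g after %d iterations (%s)\n",
              x$objective, x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' @export
summary.nmf_fit <- function(object, ...) {
  cat("Non-negative matrix factorization (Frobenius objective)\n")
  print(object)
  cat("  basis column norms:",
      paste(sprintf("%.3f", sqrt(colSums(object$W^2))), collapse = " "), "\n")
  cat("  coefficient mass per component:",
      paste(sprintf("%.3g", rowSums(object$H)), collapse = " "), "\n")
  invisible(object)
}

#' Best-permutation cosine similarity between two basis matrices
#'
#' Matches columns of `W1` to columns of `W2` by the permutation maximizing
#' the mean cosine similarity (exhaustive over permutations for ranks up to
#' 8, greedy beyond) and returns the matched similarities.
#'
#' @param W1,W2 basis matrices with equal dimensions.
#' @return list with `mean` cosine, per-column `cosines`, and the
#'   `permutation` mapping columns of `W2` to columns of `W1`.
#' @export
factor_cosine <- function(W1, W2) {
  if (!identical(dim(W1), dim(W2))) stop("basis matrices differ in dimension")
  L <- ncol(W1)
  n1 <- sqrt(colSums(W1^2)); n2 <- sqrt(colSums(W2^2))
  C <- crossprod(W1, W2) / outer(pmax(n1, 1e-300), pmax(n2, 1e-300))
  if (L <= 8L) {
    perms <- permutations_of(L)
    scores <- vapply(perms, function(p) mean(C[cbind(seq_len(L), p)]),
                     numeric(1))
    p <- perms[[which.max(scores)]]
  } else {
    p <- integer(L)
    used <- rep(FALSE, L)
    for (i in order(apply(C, 1, max), decreasing = TRUE)) {
      j <- which.max(ifelse(used, -Inf, C[i, ]))
      p[i] <- j; used[j] <- TRUE
    }
  }
  cosines <- C[cbind(seq_len(L), p)]
  list(mean = mean(cosines), cosines = cosines, permutation = p)
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in permutations_of(n - 1L)) {
      rest <- seq_len(n)[-i]
      out <- c(out, list(c(i, rest[p])))
    }
  }
  out
}

#' Block-structured planted factors for clustering-stability validation
#'
#' Builds `V ~ W* H*` with `L` equal, disjoint, equal-norm basis blocks
#' (clusters that are pairwise equidistant) and coefficient columns
#' dominated by one component each. Because the clusters are symmetric,
#' factorizations below the planted rank must merge an arbitrary pair and
#' become initialization-dependent, while the planted rank stays stable —
#' the regime that consensus-based rank selection is designed to detect.
#'
#' @param N,M,L problem dimensions and planted rank.
#' @param noise relative multiplicative noise scale.
#' @param seed integer seed.
#' @return list with `V`, planted `W` (unit-norm columns), `H`, `labels`.
#' @export
simulate_block_factors <- function(N, M, L, noise = 0.1, seed = 1L) {
  with_seed(seed, {
    W <- matrix(0, N, L)
    blocks <- split(seq_len(N), rep(seq_len(L), length.out = N))
    for (j in seq_len(L)) W[blocks[[j]], j] <- 1
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
    labels <- sample(rep_len(seq_len(L), M))
    H <- matrix(runif(L * M, 0, 0.1), L, M)
    H[cbind(labels, seq_len(M))] <- runif(M, 1, 2)
    V <- W %*% H
    if (noise > 0) V <- V * (1 + noise * matrix(rnorm(N * M), N, M))
    V[V < 0] <- 0
    list(V = V, W = W, H = H, labels = labels)
  })
}

#' Planted non-negative factors with multiplicative noise
#'
#' Builds a synthetic validation problem `V ~ W* H*` with known non-negative
#' factors: sparse random basis columns and coefficient columns dominated by
#' one component each (so the planted structure is both recoverable and
#' clusterable). Multiplicative Gaussian noise of relative scale `noise` is
#' applied entrywise, truncated at zero.
#'
#' @param N,M,L problem dimensions and planted rank.
#' @param noise relative noise scale (0.05 = 5 percent).
#' @param seed integer seed.
#' @param density fraction of nonzero entries per basis column.
#' @return list with `V`, planted `W` (unit-norm columns), `H`, and
#'   `labels` (dominant component per sample).
#' @export
simulate_planted_factors <- function(N, M, L, noise = 0.05, seed = 1L,
                                     density = 0.2) {
  with_seed(seed, {
    W <- matrix(0, N, L)
    k <- max(2L, round(density * N))
    for (j in seq_len(L)) {
      W[sample.int(N, k), j] <- rexp(k) + 0.2
    }
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
    labels <- sample(rep_len(seq_len(L), M))
    H <- matrix(runif(L * M, 0, 0.08), L, M)
    H[cbind(labels, seq_len(M))] <- runif(M, 1, 2)
    V <- W %*% H
    if (noise > 0) V <- V * (1 + noise * matrix(rnorm(N * M), N, M))
    V[V < 0] <- 0
    list(V = V, W = W, H = H, labels = labels)
  })
}
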