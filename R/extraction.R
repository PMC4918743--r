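# De novo signature extraction: bootstrap resampling of catalogues,
# multiplicative-update NMF under the Frobenius objective, and agglomerative
# consensus clustering of the pooled factorisation draws.

#' Bootstrap-resample a catalogue matrix
#'
#' Each sample (column) is replaced by an independent multinomial draw of its
#' own total mutation count from its empirical channel distribution, so
#' column totals are preserved exactly.
#'
#' @param matrix 96 x samples non-negative count matrix.
#' @param seed Integer RNG seed.
#' @return Matrix of the same shape and column sums.
#' @export
bootstrap_resample <- function(matrix, seed) {
  out <- with_seed(seed, {
    apply(matrix, 2, function(col) {
      n <- sum(col)
      if (n == 0) return(col * 0)
      as.numeric(stats::rmultinom(1, size = n, prob = col / n))
    })
  })
  dimnames(out) <- dimnames(matrix)
  out
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorises a non-negative catalogue matrix `V ~ W H` (channels x k times
#' k x samples) by minimising the Frobenius reconstruction error with the
#' classical multiplicative update rules, whose objective is non-increasing
#' at every iteration. Initialisation is uniform random scaled to the data;
#' results are deterministic given `seed`. On return the columns of `W` are
#' normalised to sum to 1 (probability densities over the 96 channels) with
#' the mass moved into `H`.
#'
#' @param matrix Non-negative numeric matrix (channels x samples).
#' @param k Number of signatures, `1 <= k <= min(nrow, ncol)`.
#' @param seed Integer seed for the random initialisation.
#' @param max_iter,tol Stop after `max_iter` updates or when the relative
#'   objective decrease falls below `tol`.
#' @return List with `signatures` (channels x k, columns sum to 1),
#'   `exposures` (k x samples), `objective` (the per-iteration Frobenius
#'   norm trace) and `error` (final relative reconstruction error,
#'   `||V - WH||_F / ||V||_F`).
#' @export
nmf_factorize <- function(matrix, k, seed = 1L, max_iter = 2000L, tol = 1e-8) {
  V <- as.matrix(matrix)
  if (any(V < 0)) stop("matrix must be non-negative", call. = FALSE)
  if (k < 1 || k > min(dim(V)))
    stop("k must be between 1 and min(dim(matrix))", call. = FALSE)
  eps <- .Machine$double.eps
  res <- with_seed(seed, {
    scale0 <- sqrt(mean(V) / k)
    W <- matrix(stats::runif(nrow(V) * k), nrow(V), k) * scale0
    H <- matrix(stats::runif(k * ncol(V)), k, ncol(V)) * scale0
    obj <- numeric(0)
    prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
      o <- sqrt(sum((V - W %*% H)^2))
      obj <- c(obj, o)
      if (is.finite(prev) && prev - o < tol * max(prev, 1)) break
      prev <- o
    }
    list(W = W, H = H, obj = obj)
  })
  cs <- colSums(res$W)
  cs[cs == 0] <- 1
  W <- sweep(res$W, 2, cs, "/")
  H <- sweep(res$H, 1, cs, "*")
  colnames(W) <- rownames(H) <- paste0("S", seq_len(k))
  if (!is.null(rownames(V))) rownames(W) <- rownames(V)
  if (!is.null(colnames(V))) colnames(H) <- colnames(V)
  vnorm <- sqrt(sum(V^2))
  list(signatures = W, exposures = H, objective = res$obj,
       error = if (vnorm > 0) utils::tail(res$obj, 1) / vnorm else 0)
}

# Cosine similarity between columns of A and columns of B.
.cosine_sim <- function(A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  na <- sqrt(colSums(A^2)); nb <- sqrt(colSums(B^2))
  na[na == 0] <- 1; nb[nb == 0] <- 1
  crossprod(A, B) / outer(na, nb)
}

#' Consensus signatures by agglomerative clustering
#'
#' Pools signature draws (for example from repeated NMF runs on bootstrap
#' resamples), clusters them by unsupervised agglomerative hierarchical
#' clustering under cosine distance with average linkage, cuts at `k`
#' clusters, and returns the normalised centroid of each cluster as a
#' consensus signature. Clusters whose mean within-cluster pairwise cosine
#' similarity falls below `similarity_threshold` are flagged unstable.
#'
#' @param signature_draws 96 x n matrix (or list of 96-vectors) of draws,
#'   `n >= k`.
#' @param k Number of consensus signatures.
#' @param similarity_threshold Stability flag threshold (default 0.8).
#' @return List with `signatures` (96 x k, columns sum to 1), `stable`
#'   (logical k-vector), `cluster_similarity` (mean within-cluster cosine
#'   similarity per cluster) and `assignments`.
#' @export
cluster_consensus <- function(signature_draws, k, similarity_threshold = 0.8) {
  if (is.list(signature_draws))
    signature_draws <- do.call(cbind, signature_draws)
  X <- as.matrix(signature_draws)
  n <- ncol(X)
  if (n < k) stop("need at least k signature draws", call. = FALSE)
  if (k == 1L) {
    assign <- rep(1L, n)
  } else {
    sim <- .cosine_sim(X)
    d <- stats::as.dist(pmax(1 - sim, 0))
    hc <- stats::hclust(d, method = "average")
    assign <- stats::cutree(hc, k = k)
  }
  sim <- .cosine_sim(X)
  cents <- matrix(0, nrow(X), k)
  within <- numeric(k)
  for (j in seq_len(k)) {
    members <- which(assign == j)
    cen <- rowMeans(X[, members, drop = FALSE])
    cents[, j] <- cen / sum(cen)
    s <- sim[members, members, drop = FALSE]
    within[j] <- if (length(members) > 1)
      mean(s[upper.tri(s)]) else 1
  }
  rownames(cents) <- rownames(X)
  colnames(cents) <- paste0("S", seq_len(k))
  list(signatures = cents, stable = within >= similarity_threshold,
       cluster_similarity = within, assignments = assign)
}

# Mean silhouette width of the draw clustering under cosine distance.
# Defined as 1 at k = 1 (a single process explains every draw).
.draw_silhouette <- function(X, assign) {
  k <- length(unique(assign))
  if (k == 1L) return(1)
  d <- stats::as.dist(pmax(1 - .cosine_sim(X), 0))
  sil <- cluster::silhouette(assign, d)
  mean(sil[, "sil_width"])
}

#' De novo extraction of consensus mutational signatures
#'
#' For each candidate number of signatures `k`, the cohort catalogue matrix
#' is bootstrap-resampled `n_bootstraps` times, each resample is factorised
#' by NMF, the pooled `k * n_bootstraps` signature draws are clustered into
#' `k` consensus signatures, and the reproducibility of the solution is
#' scored as the mean silhouette width of the draws under cosine distance.
#' The chosen model is the largest `k` whose reproducibility reaches
#' `stability_floor` and whose consensus signatures are all genuine:
#' mutually distinct (no two centroids with cosine similarity above
#' `max_centroid_similarity`, which guards against split clusters) and each
#' supported by draws from at least `min_bootstrap_support` of the
#' bootstraps (a "signature" reproduced by only one or two resamples is a
#' misclustered noise component, not a mutational process). This
#' operationalises selecting the minimal set of signatures that is stably
#' reproducible while still explaining the catalogues. If no `k` qualifies,
#' the most reproducible `k` is chosen with a warning.
#'
#' @param matrix 96 x samples catalogue count matrix.
#' @param k_range Candidate numbers of signatures, e.g. `1:5`.
#' @param n_bootstraps Bootstrap resamples per `k` (>= 2).
#' @param seed Integer seed; the whole procedure is reproducible
#'   bit-for-bit given `(seed, k_range, n_bootstraps)`.
#' @param stability_floor Minimum mean silhouette (default 0.8).
#' @param max_centroid_similarity Reject solutions with two consensus
#'   signatures more similar than this (default 0.85).
#' @param min_bootstrap_support Reject solutions containing a cluster drawn
#'   from fewer than this fraction of the bootstraps (default 0.5).
#' @param nmf_max_iter,nmf_tol Passed to [nmf_factorize()].
#' @return Object of class `"extraction_result"`: list with
#'   `consensus_signatures` (96 x chosen_k), `chosen_k`, `per_k_stability`,
#'   `per_k_error` (mean relative Frobenius reconstruction error),
#'   `per_k_valid` and `per_k` (full per-k details).
#' @export
extract_signatures <- function(matrix, k_range, n_bootstraps = 20L, seed = 1L,
                               stability_floor = 0.8,
                               max_centroid_similarity = 0.85,
                               min_bootstrap_support = 0.5,
                               nmf_max_iter = 2000L, nmf_tol = 1e-8) {
  if (n_bootstraps < 2) stop("n_bootstraps must be >= 2", call. = FALSE)
  V <- as.matrix(matrix)
  k_range <- sort(unique(as.integer(k_range)))
  per_k <- list()
  stab <- err <- stats::setNames(rep(NA_real_, length(k_range)),
                                 paste0("k", k_range))
  valid <- stats::setNames(rep(FALSE, length(k_range)), paste0("k", k_range))
  seeds <- derive_seeds(seed, length(k_range) * n_bootstraps * 2L)
  si <- 1L
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    draws <- vector("list", n_bootstraps)
    errs <- numeric(n_bootstraps)
    for (b in seq_len(n_bootstraps)) {
      Vb <- bootstrap_resample(V, seed = seeds[si]); si <- si + 1L
      fit <- nmf_factorize(Vb, k, seed = seeds[si], max_iter = nmf_max_iter,
                           tol = nmf_tol); si <- si + 1L
      draws[[b]] <- fit$signatures
      # score each bootstrap factorisation against the original catalogues
      errs[b] <- sqrt(sum((V - fit$signatures %*% fit$exposures)^2)) /
        sqrt(sum(V^2))
    }
    X <- do.call(cbind, draws)
    cons <- cluster_consensus(X, k)
    stab[ki] <- .draw_silhouette(X, cons$assignments)
    err[ki] <- mean(errs)
    cs <- .cosine_sim(cons$signatures)
    distinct <- k == 1L || max(cs[upper.tri(cs)]) <= max_centroid_similarity
    # every consensus cluster must recur across bootstraps
    boot_of_draw <- rep(seq_len(n_bootstraps), each = k)
    support <- vapply(seq_len(k), function(j)
      length(unique(boot_of_draw[cons$assignments == j])) / n_bootstraps,
      numeric(1))
    supported <- all(support >= min_bootstrap_support)
    valid[ki] <- distinct && supported
    per_k[[paste0("k", k)]] <- list(k = k, consensus = cons,
                                    stability = stab[ki], error = err[ki],
                                    distinct = distinct,
                                    bootstrap_support = support)
  }
  ok <- which(valid & stab >= stability_floor)
  if (length(ok) == 0) {
    warning("no k reached the stability floor; returning the most ",
            "reproducible k", call. = FALSE)
    ok <- which.max(stab)
  }
  chosen <- k_range[max(ok)]
  res <- per_k[[paste0("k", chosen)]]
  structure(list(consensus_signatures = res$consensus$signatures,
                 chosen_k = chosen,
                 per_k_stability = stab, per_k_error = err,
                 per_k_valid = valid, per_k = per_k,
                 seed = seed, n_bootstraps = n_bootstraps),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("signature extraction: chose k =", x$chosen_k, "\n")
  print(data.frame(stability = round(x$per_k_stability, 3),
                   recon_error = round(x$per_k_error, 4),
                   distinct = x$per_k_valid))
  invisible(x)
}

#' Match extracted signatures to a reference set by cosine similarity
#'
#' Greedy one-to-one assignment of extracted columns to reference columns in
#' decreasing order of cosine similarity.
#'
#' @param extracted,reference 96 x k matrices.
#' @return data.frame with `extracted`, `reference`, `cosine`.
#' @export
match_signatures <- function(extracted, reference) {
  E <- as.matrix(extracted); R <- as.matrix(reference)
  if (is.null(colnames(E))) colnames(E) <- paste0("E", seq_len(ncol(E)))
  if (is.null(colnames(R))) colnames(R) <- paste0("R", seq_len(ncol(R)))
  s <- .cosine_sim(E, R)
  k <- min(dim(s))
  out <- data.frame(extracted = character(k), reference = character(k),
                    cosine = numeric(k), stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    ij <- which(s == max(s), arr.ind = TRUE)[1, ]
    out$extracted[i] <- rownames(s)[ij[1]]
    out$reference[i] <- colnames(s)[ij[2]]
    out$cosine[i] <- s[ij[1], ij[2]]
    s[ij[1], ] <- -Inf
    s[, ij[2]] <- -Inf
  }
  out
}
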