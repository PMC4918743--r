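# Exposure refitting: given a sample's 96-channel catalogue m and a set of
# known signature densities s_1..s_q, estimate the mutation counts E_i
# contributed by each signature by minimising || m - sum_i E_i s_i ||_2
# subject to E_i >= 0, E_i <= total and sum_i E_i = total (the total number
# of somatic mutations in the sample). The cap is implied by the other two
# constraints, so the feasible set is the simplex scaled by the total.

#' Construct a signature set
#'
#' Bundles a signature matrix with per-signature feature flags and a
#' per-cancer-type registry of operative signatures. Feature flags mark
#' signatures whose activity is only credible when the sample shows the
#' corresponding feature (e.g. a signature causing indels at nucleotide
#' repeats is only fitted in samples that actually carry such indels); they
#' drive the candidate-subset selection of [select_subset()].
#'
#' @param signatures 96 x k matrix, columns summing to 1 (renormalised
#'   here), with unique column names.
#' @param feature_flags Named list mapping signature name -> character
#'   vector of flags from `c("indels_at_repeats", "indels_with_microhomology",
#'   "strand_bias", "dinucleotides", "hypermutator")`. Signatures without an
#'   entry carry no flags.
#' @param registry Named list mapping cancer type -> character vector of
#'   signature names known operative in that type.
#' @return Object of class `"signature_set"`.
#' @export
signature_set <- function(signatures, feature_flags = list(), registry = list()) {
  m <- as.matrix(signatures)
  if (nrow(m) != 96) stop("signature matrix must have 96 rows", call. = FALSE)
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop("signatures must have unique column names", call. = FALSE)
  if (any(m < 0)) stop("signature values must be non-negative", call. = FALSE)
  m <- sweep(m, 2, colSums(m), "/")
  known <- c("indels_at_repeats", "indels_with_microhomology", "strand_bias",
             "dinucleotides", "hypermutator")
  for (nm in names(feature_flags)) {
    if (!nm %in% colnames(m))
      stop("feature_flags names a non-member signature: ", nm, call. = FALSE)
    bad <- setdiff(feature_flags[[nm]], known)
    if (length(bad))
      stop("unknown feature flag(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  for (ct in names(registry)) {
    bad <- setdiff(registry[[ct]], colnames(m))
    if (length(bad))
      stop("registry for '", ct, "' names non-member signature(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(signatures = m, feature_flags = feature_flags,
                 registry = registry),
            class = "signature_set")
}

#' Per-sample features used for candidate-signature selection
#'
#' @param cancer_type Cancer type, must appear in the registry.
#' @param n_indels_at_repeats,n_indels_microhomology,n_dinucleotides
#'   Non-negative counts observed in the sample.
#' @param has_strand_bias,hypermutator Logical.
#' @return A `"sample_features"` list.
#' @export
sample_features <- function(cancer_type,
                            n_indels_at_repeats = 0L,
                            n_indels_microhomology = 0L,
                            n_dinucleotides = 0L,
                            has_strand_bias = FALSE,
                            hypermutator = FALSE) {
  stopifnot(n_indels_at_repeats >= 0, n_indels_microhomology >= 0,
            n_dinucleotides >= 0)
  structure(list(cancer_type = cancer_type,
                 n_indels_at_repeats = as.integer(n_indels_at_repeats),
                 n_indels_microhomology = as.integer(n_indels_microhomology),
                 n_dinucleotides = as.integer(n_dinucleotides),
                 has_strand_bias = isTRUE(has_strand_bias),
                 hypermutator = isTRUE(hypermutator)),
            class = "sample_features")
}

#' Select the candidate signature subset Q for one sample
#'
#' Starts from the registry entry for the sample's cancer type (the
#' signatures known operative in that type) and removes any feature-flagged
#' signature whose supporting feature the sample does not show: a signature
#' flagged for indels at repeats is dropped when the sample has only a few
#' such indels, and likewise for the other flags.
#'
#' @param features A [sample_features()] object.
#' @param catalogue Optional `"mutational_catalogue"` (not used by the
#'   default thresholds; part of the interface so threshold rules may depend
#'   on the catalogue).
#' @param registry A [signature_set()].
#' @param thresholds Named list of cutoffs; defaults
#'   `list(indels = 10, dinucleotides = 5)` (boolean flags pass through).
#' @return A `"signature_set"` restricted to the selected subset.
#' @export
select_subset <- function(features, catalogue = NULL, registry,
                          thresholds = list(indels = 10, dinucleotides = 5)) {
  stopifnot(inherits(registry, "signature_set"))
  ct <- features$cancer_type
  if (!ct %in% names(registry$registry))
    stop("unknown cancer type '", ct, "'; known types: ",
         paste(names(registry$registry), collapse = ", "), call. = FALSE)
  q <- registry$registry[[ct]]
  keep <- vapply(q, function(nm) {
    flags <- registry$feature_flags[[nm]]
    if (is.null(flags) || length(flags) == 0) return(TRUE)
    all(vapply(flags, function(fl) {
      switch(fl,
        indels_at_repeats = features$n_indels_at_repeats >= thresholds$indels,
        indels_with_microhomology =
          features$n_indels_microhomology >= thresholds$indels,
        dinucleotides = features$n_dinucleotides >= thresholds$dinucleotides,
        strand_bias = features$has_strand_bias,
        hypermutator = features$hypermutator)
    }, logical(1)))
  }, logical(1))
  q <- q[keep]
  signature_set(registry$signatures[, q, drop = FALSE],
                feature_flags = registry$feature_flags[intersect(names(registry$feature_flags), q)],
                registry = stats::setNames(list(q), ct))
}

# Euclidean projection of v onto the simplex {x >= 0, sum x = total}.
.project_simplex <- function(v, total) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u) - total
  rho <- max(which(u - css / seq_along(u) > 0))
  theta <- css[rho] / rho
  pmax(v - theta, 0)
}

# Simplex-constrained least squares: min 0.5||S e - m||^2 + 0.5 ridge ||e||^2
# s.t. e >= 0, sum e = total. FISTA projected gradient, then an active-set
# KKT polish for an (essentially) exact solution.
.solve_constrained_ls <- function(S, m, total, max_iter = 5000L,
                                  tol = 1e-12, ridge = 1e-10) {
  q <- ncol(S)
  if (q == 1L) return(total)
  G <- crossprod(S) + diag(ridge, q)
  b <- crossprod(S, m)
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  e <- rep(total / q, q)
  y <- e
  t_k <- 1
  f_prev <- Inf
  for (it in seq_len(max_iter)) {
    grad <- G %*% y - b
    e_new <- .project_simplex(as.numeric(y - grad / L), total)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    y <- e_new + ((t_k - 1) / t_new) * (e_new - e)
    e <- e_new
    t_k <- t_new
    if (it %% 50L == 0L) {
      f <- 0.5 * sum((S %*% e - m)^2) + 0.5 * ridge * sum(e^2)
      if (abs(f_prev - f) < tol * max(1, f)) break
      f_prev <- f
    }
  }
  # polish: equality-constrained LS on the active support via the KKT system
  supp <- which(e > 1e-9 * total)
  if (length(supp) >= 1) {
    Gs <- G[supp, supp, drop = FALSE]
    k <- length(supp)
    K <- rbind(cbind(Gs, rep(1, k)), c(rep(1, k), 0))
    rhs <- c(b[supp], total)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (!is.null(sol)) {
      cand <- rep(0, q)
      cand[supp] <- sol[seq_len(k)]
      if (all(cand >= -1e-9 * max(total, 1))) {
        cand <- pmax(cand, 0)
        cand <- cand * (total / sum(cand))
        f_c <- 0.5 * sum((S %*% cand - m)^2) + 0.5 * ridge * sum(cand^2)
        f_e <- 0.5 * sum((S %*% e - m)^2) + 0.5 * ridge * sum(e^2)
        if (f_c <= f_e) e <- cand
      }
    }
  }
  as.numeric(e)
}

#' Fit signature exposures for one sample
#'
#' Solves the constrained least-squares problem: minimise the Euclidean
#' distance between the sample's 96-channel catalogue and the non-negative
#' combination of the candidate signatures, subject to each exposure being
#' non-negative, no exposure exceeding the sample's mutation total, and the
#' exposures summing exactly to that total. The problem is a convex QP over
#' a scaled simplex, solved by accelerated projected gradient descent with
#' an active-set polish; a tiny ridge term breaks ties between collinear
#' signatures in favour of the minimum-norm solution.
#'
#' @param catalogue A `"mutational_catalogue"` or a named numeric 96-vector
#'   of channel counts.
#' @param Q A [signature_set()] (or 96 x q matrix) of candidate signatures;
#'   must be non-empty.
#' @return Object of class `"exposure_fit"`: list with `exposures` (named
#'   numeric, summing to `total`), `total`, `residual_norm` and
#'   `reconstruction` (the fitted 96-vector).
#' @export
fit_exposures <- function(catalogue, Q) {
  m <- if (inherits(catalogue, "mutational_catalogue"))
    catalogue$counts else catalogue
  if (length(m) != 96) stop("catalogue must have 96 channels", call. = FALSE)
  S <- if (inherits(Q, "signature_set")) Q$signatures else as.matrix(Q)
  if (ncol(S) == 0) stop("candidate signature set Q is empty", call. = FALSE)
  if (is.null(colnames(S))) colnames(S) <- paste0("S", seq_len(ncol(S)))
  total <- sum(m)
  if (total == 0) {
    e <- stats::setNames(rep(0, ncol(S)), colnames(S))
    return(structure(list(exposures = e, total = 0, residual_norm = 0,
                          reconstruction = rep(0, 96)),
                     class = "exposure_fit"))
  }
  e <- .solve_constrained_ls(S, as.numeric(m), total)
  names(e) <- colnames(S)
  recon <- as.numeric(S %*% e)
  structure(list(exposures = e, total = total,
                 residual_norm = sqrt(sum((as.numeric(m) - recon)^2)),
                 reconstruction = recon),
            class = "exposure_fit")
}

#' Call a signature present or absent in a sample
#'
#' A signature is called present when its fitted exposure reaches both an
#' absolute mutation count and a minimum fraction of the sample's total.
#' The defaults (10 mutations, 5%) are this package's convention for a
#' usable presence call, exposed for tuning.
#'
#' @param exposure An `"exposure_fit"`.
#' @param signature_name Name of the signature to test.
#' @param min_mutations,min_fraction Call thresholds.
#' @return Logical.
#' @export
call_signature_present <- function(exposure, signature_name,
                                   min_mutations = 10, min_fraction = 0.05) {
  if (!signature_name %in% names(exposure$exposures))
    stop("signature '", signature_name, "' not in the fitted set", call. = FALSE)
  e <- exposure$exposures[[signature_name]]
  if (exposure$total == 0) return(FALSE)
  e >= min_mutations && e / exposure$total >= min_fraction
}

#' Fit exposures across a cohort
#'
#' Applies [select_subset()] and [fit_exposures()] independently to each
#' sample of a catalogue matrix, using identical signature definitions
#' throughout so exposures are directly comparable across samples and
#' cancer types.
#'
#' @param matrix 96 x samples catalogue count matrix.
#' @param features Named list of [sample_features()] per sample, or a single
#'   `sample_features` applied to every sample, or NULL to fit the full
#'   signature set with no subset selection.
#' @param registry A [signature_set()].
#' @param thresholds Passed to [select_subset()].
#' @return Named list of `"exposure_fit"` objects, one per column.
#' @export
fit_cohort <- function(matrix, features = NULL, registry,
                       thresholds = list(indels = 10, dinucleotides = 5)) {
  stopifnot(inherits(registry, "signature_set"))
  samples <- colnames(matrix)
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(matrix)))
  out <- vector("list", length(samples))
  names(out) <- samples
  for (i in seq_along(samples)) {
    f_i <- if (is.null(features)) NULL
      else if (inherits(features, "sample_features")) features
      else features[[samples[i]]]
    Q <- if (is.null(f_i)) registry
      else select_subset(f_i, registry = registry, thresholds = thresholds)
    out[[i]] <- fit_exposures(matrix[, i], Q)
  }
  out
}

#' Tabulate a cohort exposure fit
#'
#' @param fits List of `"exposure_fit"` as returned by [fit_cohort()].
#' @param signatures Optional character vector fixing the column order.
#' @return data.frame: one row per sample, one column per signature plus
#'   `total` and `residual_norm`; absent signatures are 0.
#' @export
exposure_table <- function(fits, signatures = NULL) {
  if (is.null(signatures))
    signatures <- unique(unlist(lapply(fits, function(f) names(f$exposures))))
  rows <- lapply(names(fits), function(s) {
    f <- fits[[s]]
    e <- stats::setNames(rep(0, length(signatures)), signatures)
    e[names(f$exposures)] <- f$exposures
    data.frame(sample_id = s, t(e), total = f$total,
               residual_norm = f$residual_norm,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat("exposure fit: total", x$total, "mutations, residual",
      format(x$residual_norm, digits = 4), "\n")
  print(round(x$exposures, 2))
  invisible(x)
}
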