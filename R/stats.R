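# Association statistics: two-sided Fisher exact tests on 2x2 histology
# tables and Mann-Whitney U comparisons of per-sample burdens between
# signature-3-positive and -negative groups.

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Two-sided p-value under the probability-mass convention: the sum of the
#' hypergeometric probabilities of all tables with the observed margins that
#' are no more probable than the observed one. A table with a zero margin
#' carries no information and returns p = 1.
#'
#' @param a,b,c,d Cell counts: rows = factor present/absent, columns =
#'   signature 3 present/absent. Alternatively pass a 2x2 matrix as `a`.
#' @return The two-sided p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_two_tailed(6, 5, 6, 83)
fisher_exact_two_tailed <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    m <- a
  } else {
    m <- matrix(c(a, c, b, d), 2, 2)
  }
  if (any(m < 0) || any(m != round(m)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if (sum(m) == 0) stop("empty table", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1.0)
  stats::fisher.test(m)$p.value
}

#' Mann-Whitney U test
#'
#' Computes the U statistic from midrank rank sums. The two-sided p-value
#' is obtained either exactly — by enumerating all assignments of the
#' pooled observations to the two groups and counting those whose U
#' deviates from its null mean at least as much as observed — or by the
#' normal approximation with tie correction and continuity correction.
#' `mode = "auto"` uses the exact path when `length(x) + length(y) <= 16`
#' and there are no ties, the approximation otherwise.
#'
#' @param x,y Numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return List with `U` (for the first sample), `p` (two-sided) and
#'   `mode` (the mode actually used).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6), mode = "exact")
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) < 1 || length(y) < 1)
    stop("both samples must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks for ties
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (mode == "auto") mode <- if (N <= 16 && !ties) "exact" else "normal"
  if (mode == "exact") {
    p <- .mwu_exact_p(pooled, n1, U)
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1.0, mode = "normal"))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- min(1, 2 * stats::pnorm(-z))
  }
  list(U = U, p = p, mode = mode)
}

# Exact two-sided p by enumeration of all C(N, n1) group assignments of the
# pooled midranks: the fraction with |U - n1*n2/2| >= the observed deviation.
.mwu_exact_p <- function(pooled, n1, U_obs) {
  N <- length(pooled)
  n2 <- N - n1
  r <- rank(pooled)
  mu <- n1 * n2 / 2
  dev <- abs(U_obs - mu)
  idx <- utils::combn(N, n1)
  U_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(U_all - mu) >= dev - 1e-9)
}

#' Build a 2x2 contingency table from annotations and calls
#'
#' Collapses an annotation column into present/absent rows (the named
#' levels vs everything else), crosses it with the signature-3 call, and
#' excludes samples whose annotation is unknown before counting. Every
#' annotated sample (after exclusions) must have a call.
#'
#' @param annotations data.frame with `sample_id` and the stratifier
#'   column.
#' @param calls Named logical vector, sample -> signature-3 present.
#' @param stratifier List: `name` (column), `present` (character levels or
#'   `TRUE` for a logical column), `unknown` (levels to exclude; default
#'   `c("unknown", NA)`).
#' @return 2x2 integer matrix: rows `present`/`absent` of the factor,
#'   columns `sig3_present`/`sig3_absent`.
#' @export
build_contingency <- function(annotations, calls, stratifier) {
  col <- stratifier$name
  if (!col %in% names(annotations))
    stop("annotation column '", col, "' not found", call. = FALSE)
  v <- annotations[[col]]
  unknown <- if (!is.null(stratifier$unknown)) stratifier$unknown else "unknown"
  keep <- !is.na(v) & !(v %in% unknown)
  ann <- annotations[keep, , drop = FALSE]
  v <- v[keep]
  if (nrow(ann) == 0) stop("no annotated samples left after excluding ",
                           "unknowns", call. = FALSE)
  no_call <- setdiff(ann$sample_id, names(calls))
  if (length(no_call))
    stop("annotation without a signature call for sample(s): ",
         paste(no_call, collapse = ", "), call. = FALSE)
  row_present <- if (isTRUE(stratifier$present)) as.logical(v)
    else v %in% stratifier$present
  col_present <- as.logical(calls[ann$sample_id])
  m <- matrix(c(sum(row_present & col_present),
                sum(!row_present & col_present),
                sum(row_present & !col_present),
                sum(!row_present & !col_present)), 2, 2)
  dimnames(m) <- list(c("present", "absent"), c("sig3_present", "sig3_absent"))
  m
}

#' Published gastric-cohort histology tables
#'
#' The 2x2 contingency tables relating signature-3 status to gastric-cancer
#' histology in a published cohort of 100 whole-genome plus 309 TCGA
#' whole-exome gastric cancers: the compact discohesive growth pattern
#' (whole-genome cohort, 11 of 100 samples showing the pattern) and the
#' Lauren classification contrasts (409 samples with known Lauren type;
#' intestinal vs diffuse+mixed, diffuse vs intestinal+mixed). Cells are
#' `(a, b, c, d)` = (factor present & sig3 present, factor absent & sig3
#' present, factor present & sig3 absent, factor absent & sig3 absent).
#' Used as the fixed input for the exact association tests.
#'
#' @return Named list of three 2x2 integer matrices:
#'   `discohesive_growth`, `intestinal_vs_rest`, `diffuse_vs_rest`.
#' @export
gastric_histology_tables <- function() {
  mk <- function(a, b, c, d) {
    m <- matrix(c(a, b, c, d), 2, 2)
    dimnames(m) <- list(c("present", "absent"),
                        c("sig3_present", "sig3_absent"))
    m
  }
  list(
    # 12/100 WGS samples sig3-positive; 6 of 11 discohesive-pattern samples
    discohesive_growth = mk(6, 6, 5, 83),
    # Lauren: intestinal 32/239, diffuse 2/103, mixed 3/30 (sig3 +/-)
    intestinal_vs_rest = mk(32, 5, 239, 133),
    diffuse_vs_rest = mk(2, 35, 103, 269)
  )
}

#' Read sample annotations
#'
#' TSV with columns `sample`, `cohort`, `histology_lauren` (one of
#' intestinal / diffuse / mixed / unknown) and `discohesive_growth`
#' (TRUE / FALSE / unknown).
#'
#' @param path TSV file.
#' @return data.frame with `sample_id`, `cohort`, `histology_lauren`,
#'   `discohesive_growth` (logical, NA for unknown).
#' @export
read_annotations <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("sample", "cohort", "histology_lauren", "discohesive_growth")
  if (!all(need %in% names(dt)))
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  lv <- c("intestinal", "diffuse", "mixed", "unknown")
  bad <- setdiff(unique(dt$histology_lauren), lv)
  if (length(bad))
    stop("unknown Lauren level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  dg <- ifelse(dt$discohesive_growth %in% c("TRUE", "FALSE"),
               dt$discohesive_growth == "TRUE", NA)
  data.frame(sample_id = dt$sample, cohort = dt$cohort,
             histology_lauren = dt$histology_lauren,
             discohesive_growth = dg, stringsAsFactors = FALSE)
}
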