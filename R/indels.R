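# Deletions repaired by microhomology-mediated end joining leave a genomic
# scar: the removed bases share a short identical sequence with a flank at
# the breakpoint. Counting such deletions (>3 bp with breakpoint
# microhomology) per sample gives the indel-based evidence for failed
# homologous-recombination repair, complementing the signature-3 call.

#' Breakpoint microhomology length of a deletion
#'
#' Returns `max(p, q)` where `p` is the length of the longest prefix of the
#' deleted sequence that equals a prefix of the downstream flank, and `q`
#' the length of the longest suffix of the deleted sequence that equals a
#' suffix of the upstream flank — the two ways a breakpoint can carry
#' microhomology. A full-length match means the deletion removed one unit of
#' an adjacent repeat (polymerase slippage territory, not an end-joining
#' scar): the returned value is capped at `len(seq) - 1` and the
#' `"at_repeat"` attribute is set.
#'
#' @param deleted_seq The deleted bases (uppercase DNA).
#' @param upstream_flank Reference sequence immediately 5' of the deletion,
#'   at least as long as `deleted_seq`.
#' @param downstream_flank Reference sequence immediately 3' of the
#'   deletion, at least as long as `deleted_seq`.
#' @return Integer microhomology length with logical attribute `at_repeat`.
#' @export
#' @examples
#' microhomology_length("ACGT", "GGGG", "ACTTG")  # prefix "AC" matches: 2
microhomology_length <- function(deleted_seq, upstream_flank, downstream_flank) {
  L <- nchar(deleted_seq)
  if (L < 1) stop("deleted_seq must be non-empty", call. = FALSE)
  if (nchar(upstream_flank) < L || nchar(downstream_flank) < L)
    stop("flanks must be at least as long as the deleted sequence",
         call. = FALSE)
  res <- .mh_lengths(deleted_seq,
                     substr(upstream_flank,
                            nchar(upstream_flank) - L + 1L,
                            nchar(upstream_flank)),
                     substr(downstream_flank, 1L, L))
  structure(res$mh, at_repeat = res$at_repeat)
}

# Vectorised microhomology computation. up/down are trimmed to length(seq).
# Returns list(mh, at_repeat, p, q).
.mh_lengths <- function(seq, up, down) {
  n <- length(seq)
  L <- nchar(seq)
  maxL <- if (n) max(L) else 0L
  p <- integer(n)
  active <- rep(TRUE, n)
  for (j in seq_len(maxL)) {
    active <- active & j <= L &
      substr(seq, j, j) == substr(down, j, j)
    p[active] <- j
  }
  q <- integer(n)
  active <- rep(TRUE, n)
  for (j in seq_len(maxL)) {
    active <- active & j <= L &
      substr(seq, L - j + 1L, L - j + 1L) ==
        substr(up, nchar(up) - j + 1L, nchar(up) - j + 1L)
    q[active] <- j
  }
  mh <- pmax(p, q)
  at_repeat <- mh == L
  mh <- pmin(mh, L - 1L)
  list(mh = mh, at_repeat = at_repeat, p = p, q = q)
}

#' Classify indels for size and breakpoint microhomology
#'
#' Annotates every indel record with its microhomology length and repeat
#' status (deletions only; insertions are carried through unannotated) and
#' counts, per sample, the deletions qualifying as microhomology-mediated:
#' deletions longer than `min_size` bp, with microhomology of at least
#' `min_mh` bp, not lying within a tandem repeat. Flanks are read from the
#' reference; records whose locus (with flanks) falls outside the reference
#' are skipped with a warning.
#'
#' @param indels data.frame with columns `sample_id`, `chrom`, `pos`
#'   (1-based first deleted/inserted base), `kind` (`"deletion"` or
#'   `"insertion"`), `seq` (deleted/inserted bases).
#' @param reference Named character vector of contig sequences or
#'   `DNAStringSet`.
#' @param min_size Deletions must be strictly longer than this (default 3).
#' @param min_mh Minimum microhomology length (default 1).
#' @return List with `annotated` (the input plus `mh_length`, `at_repeat`,
#'   `is_mh_deletion`) and `n_mh_indels` (named integer vector per sample).
#' @export
classify_indels <- function(indels, reference, min_size = 3L, min_mh = 1L) {
  reference <- .as_reference(reference)
  dt <- data.table::as.data.table(indels)
  need <- c("sample_id", "chrom", "pos", "kind", "seq")
  if (!all(need %in% names(dt)))
    stop("indels need columns: ", paste(need, collapse = ", "), call. = FALSE)
  n <- nrow(dt)
  mh <- rep(NA_integer_, n)
  at_rep <- rep(NA, n)
  is_del <- dt$kind == "deletion"
  L <- nchar(dt$seq)
  usable <- rep(FALSE, n)
  up <- down <- rep(NA_character_, n)
  for (ch in unique(dt$chrom[is_del])) {
    if (!ch %in% names(reference)) {
      warning("contig '", ch, "' not in reference; records skipped",
              call. = FALSE)
      next
    }
    clen <- nchar(reference[[ch]])
    idx <- which(is_del & dt$chrom == ch)
    ok <- dt$pos[idx] - L[idx] >= 1L & dt$pos[idx] + 2L * L[idx] - 1L <= clen
    if (any(!ok))
      warning(sum(!ok), " deletion(s) too close to a contig edge skipped",
              call. = FALSE)
    at <- idx[ok]
    up[at] <- substring(reference[[ch]], dt$pos[at] - L[at], dt$pos[at] - 1L)
    down[at] <- substring(reference[[ch]], dt$pos[at] + L[at],
                          dt$pos[at] + 2L * L[at] - 1L)
    usable[at] <- TRUE
  }
  if (any(usable)) {
    res <- .mh_lengths(dt$seq[usable], up[usable], down[usable])
    mh[usable] <- res$mh
    at_rep[usable] <- res$at_repeat
  }
  dt[, mh_length := mh]
  dt[, at_repeat := at_rep]
  dt[, is_mh_deletion := !is.na(mh) & kind == "deletion" &
       nchar(seq) > min_size & mh >= min_mh & !at_rep]
  counts <- tapply(dt$is_mh_deletion, dt$sample_id, sum)
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(annotated = dt[], n_mh_indels = counts)
}

#' Per-sample burden table
#'
#' Joins microhomology-deletion counts, structural-variant counts and
#' signature-3 calls on sample id. Every sample appearing in the indel set
#' must have a signature-3 call; samples without an SV count get `NA` (an
#' absent measurement, not zero).
#'
#' @param classified Result of [classify_indels()] (or a named integer
#'   vector of per-sample MH-deletion counts).
#' @param sv_counts Named integer vector, sample -> structural-variant
#'   count; may be NULL.
#' @param sig3_calls Named logical vector, sample -> signature-3 present.
#' @return data.frame with `sample_id`, `n_mh_indels`,
#'   `n_structural_variants`, `sig3_present`, one row per sample in
#'   `sig3_calls`.
#' @export
burden_table <- function(classified, sv_counts = NULL, sig3_calls) {
  counts <- if (is.list(classified)) classified$n_mh_indels else classified
  missing_calls <- setdiff(names(counts), names(sig3_calls))
  if (length(missing_calls))
    stop("no signature-3 call for sample(s): ",
         paste(missing_calls, collapse = ", "), call. = FALSE)
  samples <- names(sig3_calls)
  n_mh <- stats::setNames(rep(0L, length(samples)), samples)
  n_mh[names(counts)] <- counts
  n_sv <- rep(NA_integer_, length(samples))
  if (!is.null(sv_counts)) {
    hit <- samples %in% names(sv_counts)
    n_sv[hit] <- as.integer(sv_counts[samples[hit]])
  }
  data.frame(sample_id = samples, n_mh_indels = as.integer(n_mh),
             n_structural_variants = n_sv,
             sig3_present = as.logical(sig3_calls),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read structural-variant counts
#'
#' Accepts a 2-column TSV (`sample`, `n_sv`) or a BEDPE file with the sample
#' name in the `name` (7th) column, in which case rows per sample are
#' counted.
#'
#' @param path File path.
#' @param format `"auto"`, `"tsv"` or `"bedpe"`.
#' @return Named integer vector.
#' @export
read_sv_counts <- function(path, format = c("auto", "tsv", "bedpe")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bedpe$", path, ignore.case = TRUE)) "bedpe" else "tsv"
  if (format == "bedpe") {
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    if (ncol(dt) < 7) stop("BEDPE needs at least 7 columns", call. = FALSE)
    tab <- table(dt[[7]])
    return(stats::setNames(as.integer(tab), names(tab)))
  }
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  stats::setNames(as.integer(dt[[2]]), as.character(dt[[1]]))
}
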