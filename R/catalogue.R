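#' Filter somatic variants against germline sites and a panel of normals
#'
#' A variant is removed iff (a) its `(chrom, pos, ref, alt)` appears in the
#' germline site list, or (b) the panel-of-normals evidence for the site shows
#' the alternate allele in at least two well-mapping reads in at least two
#' panel samples — the recurrent-artifact rule. Sites with no panel entry are
#' kept. Filtering is idempotent: a second pass over the kept set removes
#' nothing.
#'
#' @param variants `data.table`/data.frame with `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`.
#' @param germline_sites data.frame with `chrom`, `pos`, `ref`, `alt`
#'   (or NULL).
#' @param panel data.frame with `chrom`, `pos`, `ref`, `alt` and list-column
#'   `panel_read_counts` (or NULL); see [read_panel_evidence()].
#' @return `list(kept = , removed = )`; `removed` carries a `reason` column
#'   (`"germline"` or `"panel_of_normals"`).
#' @export
filter_variants <- function(variants, germline_sites = NULL, panel = NULL) {
  dt <- data.table::as.data.table(variants)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  reason <- rep(NA_character_, nrow(dt))
  if (!is.null(germline_sites) && nrow(germline_sites) > 0) {
    reason[key(dt) %in% key(germline_sites)] <- "germline"
  }
  if (!is.null(panel) && nrow(panel) > 0) {
    # >=2 panel samples each with >=2 alt-supporting reads
    artifact <- vapply(panel$panel_read_counts,
                       function(x) sum(x >= 2L) >= 2L, logical(1))
    bad_sites <- key(panel)[artifact]
    hit <- is.na(reason) & key(dt) %in% bad_sites
    reason[hit] <- "panel_of_normals"
  }
  removed <- cbind(dt[!is.na(reason)], reason = reason[!is.na(reason)])
  list(kept = dt[is.na(reason)], removed = removed)
}

#' Build a 96-channel mutational catalogue for one sample
#'
#' Counts every classifiable single-nucleotide variant into its
#' pyrimidine-centric substitution-in-context channel. Only SNV records
#' (`nchar(ref) == nchar(alt) == 1`) contribute; indels and multi-nucleotide
#' substitutions are ignored here (indels are handled by the indel module).
#' SNVs whose trinucleotide context cannot be read (contig edge, N in
#' context) are excluded and counted in `n_excluded`, so that
#' `sum(counts) + n_excluded == number of input SNVs`.
#'
#' @param variants Post-filter variant table for one sample (`chrom`, `pos`,
#'   `ref`, `alt`; a `sample_id` column, if present, must be constant).
#' @param reference Named character vector of contig sequences or a
#'   `DNAStringSet`.
#' @param sample_id Optional sample name (defaults to the table's).
#' @return Object of class `"mutational_catalogue"`: a list with `sample_id`,
#'   `counts` (named integer 96-vector in COSMIC channel order),
#'   `n_mutations` (= `sum(counts)`) and `n_excluded`.
#' @export
build_catalogue <- function(variants, reference, sample_id = NULL) {
  reference <- .as_reference(reference)
  dt <- data.table::as.data.table(variants)
  if (is.null(sample_id)) {
    sample_id <- if ("sample_id" %in% names(dt) && nrow(dt) > 0)
      unique(dt$sample_id) else "sample"
    if (length(sample_id) > 1)
      stop("build_catalogue expects a single sample; got ",
           length(sample_id), call. = FALSE)
    if (length(sample_id) == 0) sample_id <- "sample"
  }
  counts <- stats::setNames(integer(96), .CHANNELS)
  is_snv <- nchar(dt$ref) == 1L & nchar(dt$alt) == 1L
  snv <- dt[is_snv]
  n_excluded <- 0L
  if (nrow(snv) > 0) {
    ctx <- .contexts_at(reference, snv$chrom, snv$pos)
    # exclude edge/N contexts and contexts disagreeing with the stated ref
    usable <- !is.na(ctx$center) & ctx$center == snv$ref
    mismatch <- !is.na(ctx$center) & ctx$center != snv$ref
    if (any(mismatch))
      warning(sum(mismatch), " SNV(s) whose ref disagrees with the reference",
              " sequence were excluded", call. = FALSE)
    ch <- .classify_substitutions(snv$ref[usable], snv$alt[usable],
                                  ctx$flank5[usable], ctx$flank3[usable])
    ok <- !is.na(ch)
    tab <- table(factor(ch[ok], levels = .CHANNELS))
    counts <- counts + as.integer(tab)
    names(counts) <- .CHANNELS
    n_excluded <- nrow(snv) - sum(ok)
  }
  structure(list(sample_id = sample_id, counts = counts,
                 n_mutations = sum(counts), n_excluded = n_excluded),
            class = "mutational_catalogue")
}

# Vectorised trinucleotide-context lookup.
.contexts_at <- function(reference, chrom, pos) {
  n <- length(pos)
  f5 <- ce <- f3 <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    if (!ch %in% names(reference))
      stop("contig '", ch, "' not present in the reference", call. = FALSE)
    idx <- which(chrom == ch)
    seq <- reference[[ch]]
    len <- nchar(seq)
    p <- pos[idx]
    inside <- p > 1L & p < len
    tri <- toupper(substring(seq, p[inside] - 1L, p[inside] + 1L))
    good <- grepl("^[ACGT]{3}$", tri)
    at <- idx[inside][good]
    f5[at] <- substr(tri[good], 1, 1)
    ce[at] <- substr(tri[good], 2, 2)
    f3[at] <- substr(tri[good], 3, 3)
  }
  list(flank5 = f5, center = ce, flank3 = f3)
}

#' Build a catalogue matrix for a cohort
#'
#' @param variants Variant table for several samples (`sample_id` column
#'   required).
#' @param reference As in [build_catalogue()].
#' @param samples Optional character vector fixing the column order (samples
#'   with no variants get zero columns).
#' @return 96 x samples integer matrix, channels as rownames.
#' @export
build_catalogue_matrix <- function(variants, reference, samples = NULL) {
  dt <- data.table::as.data.table(variants)
  if (is.null(samples)) samples <- sort(unique(dt$sample_id))
  m <- matrix(0L, nrow = 96, ncol = length(samples),
              dimnames = list(.CHANNELS, samples))
  for (s in samples) {
    cat_s <- build_catalogue(dt[dt$sample_id == s], reference, sample_id = s)
    m[, s] <- cat_s$counts
  }
  m
}

#' Pyrimidine-centric trinucleotide frequencies of a sequence set
#'
#' Counts all overlapping trinucleotides and collapses reverse-complement
#' pairs onto the 32 trinucleotides whose central base is a pyrimidine
#' (C or T), matching the channel convention.
#'
#' @param reference Named character vector of contig sequences, a
#'   `DNAStringSet`, or a path to a FASTA file.
#' @return Object of class `"trinucleotide_frequencies"`: list with `freq`
#'   (named numeric 32-vector of counts) and `territory_bp` (total sequence
#'   length).
#' @export
trinucleotide_frequencies <- function(reference) {
  if (is.character(reference) && length(reference) == 1 &&
      is.null(names(reference)) && file.exists(reference)) {
    ss <- Biostrings::readDNAStringSet(reference)
  } else if (methods::is(reference, "DNAStringSet")) {
    ss <- reference
  } else {
    ss <- Biostrings::DNAStringSet(.as_reference(reference))
  }
  raw <- colSums(Biostrings::trinucleotideFrequency(ss))
  tris <- names(raw)
  center <- substr(tris, 2, 2)
  pyr <- center %in% c("C", "T")
  key <- ifelse(pyr, tris,
                as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(tris))))
  freq <- tapply(as.numeric(raw), key, sum)
  freq <- freq[order(names(freq))]
  structure(list(freq = freq, territory_bp = sum(Biostrings::width(ss))),
            class = "trinucleotide_frequencies")
}

# Trinucleotide (pyrimidine-centric) of each of the 96 channels, in order.
.channel_trinucleotides <- function() {
  # label form "A[C>A]G": flanks at positions 1 and 7, reference base at 3
  paste0(substr(.CHANNELS, 1, 1), substr(.CHANNELS, 3, 3),
         substr(.CHANNELS, 7, 7))
}

#' Renormalise a signature between trinucleotide territories
#'
#' Signatures extracted from exome catalogues reflect the exome's
#' trinucleotide composition; to compare or apply them genome-wide each
#' channel is rescaled by the genome/exome abundance ratio of its
#' trinucleotide and the vector is renormalised to sum to 1.
#'
#' @param sig Numeric 96-vector (a signature; any non-negative scaling).
#' @param exome_freq,genome_freq [trinucleotide_frequencies()] objects (or
#'   named numeric vectors over the 32 pyrimidine-centric trinucleotides).
#' @return Numeric 96-vector summing to 1.
#' @export
normalize_exome_signature <- function(sig, exome_freq, genome_freq) {
  getf <- function(f) if (inherits(f, "trinucleotide_frequencies")) f$freq else f
  ef <- getf(exome_freq); gf <- getf(genome_freq)
  if (length(sig) != 96) stop("signature must have 96 components", call. = FALSE)
  tri <- .channel_trinucleotides()
  e <- as.numeric(ef[tri]); g <- as.numeric(gf[tri])
  mass <- sig > 0
  if (any(mass & (is.na(e) | e <= 0)))
    stop("zero exome frequency for a trinucleotide carrying signature mass",
         call. = FALSE)
  ratio <- ifelse(mass, g / e, 0)
  out <- sig * ratio
  out <- out / sum(out)
  names(out) <- names(sig)
  out
}

#' Somatic mutation prevalence per megabase
#'
#' @param catalogue A `"mutational_catalogue"` or a non-negative mutation
#'   count.
#' @param territory_bp Size in bp of the sequenced territory (haploid genome
#'   or exome footprint).
#' @return Mutations per megabase.
#' @export
mutations_per_megabase <- function(catalogue, territory_bp) {
  if (territory_bp <= 0) stop("territory_bp must be > 0", call. = FALSE)
  n <- if (inherits(catalogue, "mutational_catalogue"))
    catalogue$n_mutations else as.numeric(catalogue)
  n / (territory_bp / 1e6)
}

#' @export
print.mutational_catalogue <- function(x, ...) {
  cat("mutational catalogue:", x$sample_id, "-", x$n_mutations,
      "mutations over 96 channels (", x$n_excluded, "excluded )\n")
  invisible(x)
}
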