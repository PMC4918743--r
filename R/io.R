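#' Read somatic variants from TSV or VCF
#'
#' Two input formats are supported. A 5-column tab-separated table with
#' columns `sample`, `chrom`, `pos`, `ref`, `alt` (lines starting with `#`
#' are comments); or a minimal VCF v4.x, in which case every record is
#' assigned `sample_id` (one sample per file). Multi-allelic VCF records are
#' split into one variant per alternate allele. Coordinates are 1-based and
#' fully closed, as in VCF. Records whose REF or ALT contain characters
#' outside A/C/G/T (N, ambiguity codes, symbolic alleles) or with REF == ALT
#' are rejected during parsing; the rejected rows and their reasons are kept
#' in the `"rejected"` attribute of the result and reported with a warning.
#'
#' @param path Path to the variant file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param sample_id Sample name used for VCF input (defaults to the file name
#'   without extension).
#' @return A `data.table` with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, with attribute `"rejected"` (possibly empty) describing dropped
#'   records.
#' @export
read_variants <- function(path, format = c("auto", "tsv", "vcf"),
                          sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("variant file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    if (is.null(sample_id))
      sample_id <- sub("\\.vcf(\\.gz)?$", "", basename(path), ignore.case = TRUE)
    dt <- data.table::data.table(
      sample_id = sample_id,
      chrom = fix$CHROM,
      pos = as.integer(fix$POS),
      ref = toupper(fix$REF),
      alt = toupper(fix$ALT)
    )
    # split multi-allelic records: one row per alternate allele
    dt <- dt[, list(alt = unlist(strsplit(alt, ",", fixed = TRUE))),
             by = c("sample_id", "chrom", "pos", "ref")]
    data.table::setcolorder(dt, c("sample_id", "chrom", "pos", "ref", "alt"))
  } else {
    dt <- data.table::fread(path, header = TRUE, sep = "\t",
                            colClasses = list(character = 1:2))
    need <- c("sample", "chrom", "pos", "ref", "alt")
    if (!all(need %in% names(dt)))
      stop("variant TSV must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    dt <- data.table::data.table(
      sample_id = as.character(dt$sample),
      chrom = as.character(dt$chrom),
      pos = as.integer(dt$pos),
      ref = toupper(dt$ref),
      alt = toupper(dt$alt)
    )
  }
  .validate_variants(dt)
}

.validate_variants <- function(dt) {
  seq_ok <- function(s) grepl("^[ACGT]+$", s)
  reason <- rep(NA_character_, nrow(dt))
  reason[!seq_ok(dt$ref)] <- "non-ACGT ref"
  reason[is.na(reason) & !seq_ok(dt$alt)] <- "non-ACGT alt"
  reason[is.na(reason) & dt$ref == dt$alt] <- "ref equals alt"
  bad <- !is.na(reason)
  rejected <- cbind(dt[bad], reason = reason[bad])
  if (nrow(rejected) > 0)
    warning(nrow(rejected), " variant record(s) rejected during parsing",
            call. = FALSE)
  out <- dt[!bad]
  data.table::setattr(out, "rejected", rejected)
  out
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase contig sequences. Contig names
#'   are the first whitespace-delimited token of each FASTA header and must
#'   match variant `chrom` values exactly.
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a reference to FASTA
#'
#' @param reference Named character vector of contig sequences.
#' @param path Output path.
#' @export
write_reference <- function(reference, path) {
  ss <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read / write a catalogue matrix as TSV
#'
#' The on-disk form is 96 rows (column `channel` holding the channel label)
#' and one column per sample.
#'
#' @param path TSV file.
#' @return 96 x samples integer matrix with channel rownames.
#' @export
read_catalogue_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (names(dt)[1] != "channel")
    stop("catalogue TSV must have a first column named 'channel'", call. = FALSE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt$channel
  m <- m[mutation_channels(), , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_catalogue_matrix
#' @param matrix 96 x samples matrix.
#' @export
write_catalogue_matrix <- function(matrix, path) {
  stopifnot(nrow(matrix) == 96)
  dt <- data.table::data.table(channel = rownames(matrix))
  dt <- cbind(dt, data.table::as.data.table(matrix))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read / write a signature matrix as TSV
#'
#' 96 rows in COSMIC channel order (first column `channel`), one column per
#' signature. Columns are renormalised to sum to 1 on load, so exposures are
#' invariant to a uniform rescaling of the stored vectors.
#'
#' @param path TSV file.
#' @return 96 x k numeric matrix, columns summing to 1.
#' @export
read_signature_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (names(dt)[1] != "channel")
    stop("signature TSV must have a first column named 'channel'", call. = FALSE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt$channel
  m <- m[mutation_channels(), , drop = FALSE]
  if (any(m < 0)) stop("signature values must be non-negative", call. = FALSE)
  sweep(m, 2, colSums(m), "/")
}

#' @rdname read_signature_matrix
#' @param matrix 96 x k matrix of signature probabilities.
#' @export
write_signature_matrix <- function(matrix, path) {
  stopifnot(nrow(matrix) == 96)
  dt <- data.table::data.table(channel = rownames(matrix))
  dt <- cbind(dt, data.table::as.data.table(matrix))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read germline sites and panel-of-normals evidence
#'
#' Germline sites: 4-column TSV `chrom`, `pos`, `ref`, `alt`. Panel evidence:
#' TSV with columns `chrom`, `pos`, `ref`, `alt`, `panel_read_counts`, the
#' latter a comma-separated list of alt-supporting well-mapping read counts,
#' one per panel-of-normals sample.
#'
#' @param path TSV file.
#' @return For [read_germline_sites()], a `data.table` of sites. For
#'   [read_panel_evidence()], a `data.table` with a list-column
#'   `panel_read_counts` of integer vectors.
#' @export
read_germline_sites <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "chrom"))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(dt)))
    stop("germline TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  dt[, need, with = FALSE]
}

#' @rdname read_germline_sites
#' @export
read_panel_evidence <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("chrom", "panel_read_counts")))
  need <- c("chrom", "pos", "ref", "alt", "panel_read_counts")
  if (!all(need %in% names(dt)))
    stop("panel TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  counts <- lapply(strsplit(dt$panel_read_counts, ",", fixed = TRUE),
                   function(x) as.integer(x))
  if (any(vapply(counts, function(x) any(is.na(x) | x < 0), logical(1))))
    stop("panel_read_counts must be non-negative integers", call. = FALSE)
  out <- dt[, c("chrom", "pos", "ref", "alt"), with = FALSE]
  out[, panel_read_counts := counts]
  out[]
}
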