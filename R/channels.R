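.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
# COSMIC substitution-class order; pyrimidine reference by convention
.SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 substitution channels in COSMIC order
#'
#' Every single-base substitution is reported with the mutated base as the
#' pyrimidine of its Watson-Crick pair, together with the bases immediately
#' 5' and 3' of it: 6 substitution classes x 4 x 4 flanking contexts = 96
#' channels. Ordering is the COSMIC convention: substitution classes
#' C>A, C>G, C>T, T>A, T>C, T>G; within each class the 5' then 3' flank
#' cycle through A, C, G, T lexicographically.
#'
#' @return Character vector of 96 channel labels, e.g. `"A[C>A]A"`.
#' @export
#' @examples
#' head(mutation_channels())
mutation_channels <- function() {
  labs <- character(96)
  i <- 1L
  for (sub in .SUB_CLASSES) {
    for (f5 in .BASES) {
      for (f3 in .BASES) {
        labs[i] <- paste0(f5, "[", sub, "]", f3)
        i <- i + 1L
      }
    }
  }
  labs
}

.CHANNELS <- local({
  labs <- character(96)
  i <- 1L
  for (sub in c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")) {
    for (f5 in c("A", "C", "G", "T")) {
      for (f3 in c("A", "C", "G", "T")) {
        labs[i] <- paste0(f5, "[", sub, "]", f3)
        i <- i + 1L
      }
    }
  }
  labs
})

.check_base <- function(x, field) {
  bad <- !(x %in% .BASES)
  if (any(bad)) {
    stop("non-ACGT base in field '", field, "': ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of uppercase DNA strings (A/C/G/T only).
#' @return Character vector of the same length.
#' @export
reverse_complement <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE), function(b) {
    .check_base(b, "sequence")
    paste(rev(unname(.COMPLEMENT[b])), collapse = "")
  }, character(1))
}

#' Classify a substitution into its 96-channel class
#'
#' Maps a single-base substitution with its immediate flanking bases onto one
#' of the 96 pyrimidine-centric channels. When the reference base is a purine
#' (A or G) the substitution is re-expressed on the opposite strand: reference
#' and alternate are complemented and the two flanks are complemented and
#' swapped, so that both strand representations of one event land in the same
#' channel.
#'
#' @param ref,alt Reference and alternate base (single uppercase A/C/G/T;
#'   `ref != alt`).
#' @param flank5,flank3 The bases immediately 5' and 3' of the mutated base on
#'   the reference strand.
#' @return The channel label, e.g. `"A[C>T]G"`.
#' @export
#' @examples
#' classify_substitution("C", "T", "A", "G")
#' classify_substitution("G", "A", "C", "T")  # same channel, other strand
classify_substitution <- function(ref, alt, flank5, flank3) {
  for (f in c("ref", "alt", "flank5", "flank3")) {
    v <- get(f)
    if (length(v) != 1L || !is.character(v) || nchar(v) != 1L)
      stop("'", f, "' must be a single base", call. = FALSE)
    .check_base(v, f)
  }
  if (ref == alt) stop("ref and alt must differ", call. = FALSE)
  if (ref %in% c("A", "G")) {
    tmp <- flank5
    flank5 <- unname(.COMPLEMENT[flank3])
    flank3 <- unname(.COMPLEMENT[tmp])
    ref <- unname(.COMPLEMENT[ref])
    alt <- unname(.COMPLEMENT[alt])
  }
  paste0(flank5, "[", ref, ">", alt, "]", flank3)
}

# Vectorised channel assignment used by the catalogue builder.
# Returns NA for inputs that do not classify (non-ACGT context).
.classify_substitutions <- function(ref, alt, flank5, flank3) {
  ok <- ref %in% .BASES & alt %in% .BASES &
    flank5 %in% .BASES & flank3 %in% .BASES & ref != alt
  out <- rep(NA_character_, length(ref))
  if (!any(ok)) return(out)
  r <- ref[ok]; a <- alt[ok]; f5 <- flank5[ok]; f3 <- flank3[ok]
  pur <- r %in% c("A", "G")
  if (any(pur)) {
    nf5 <- unname(.COMPLEMENT[f3[pur]])
    nf3 <- unname(.COMPLEMENT[f5[pur]])
    r[pur] <- unname(.COMPLEMENT[r[pur]])
    a[pur] <- unname(.COMPLEMENT[a[pur]])
    f5[pur] <- nf5
    f3[pur] <- nf3
  }
  out[ok] <- paste0(f5, "[", r, ">", a, "]", f3)
  out
}

#' Extract the trinucleotide context of a position
#'
#' Reads the base at `pos` together with its immediate 5' and 3' neighbours
#' from a reference sequence. Positions at a contig edge, or whose context
#' contains a non-ACGT character, cannot be classified: the function returns
#' `NA` for all three components and the caller is expected to exclude the
#' variant (mutations with ambiguous or missing mappings are discarded).
#'
#' @param reference Named character vector of uppercase contig sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param chrom Contig name (exact match).
#' @param pos 1-based position of the mutated base.
#' @return Named character vector `c(flank5=, center=, flank3=)`, all `NA` if
#'   the context is unavailable.
#' @export
#' @examples
#' extract_context(c(chr1 = "ACGTA"), "chr1", 3)
extract_context <- function(reference, chrom, pos) {
  reference <- .as_reference(reference)
  na <- c(flank5 = NA_character_, center = NA_character_, flank3 = NA_character_)
  if (!chrom %in% names(reference))
    stop("contig '", chrom, "' not present in the reference", call. = FALSE)
  seq <- reference[[chrom]]
  n <- nchar(seq)
  if (pos <= 1L || pos >= n) return(na)
  tri <- toupper(substr(seq, pos - 1L, pos + 1L))
  b <- strsplit(tri, "", fixed = TRUE)[[1]]
  if (!all(b %in% .BASES)) return(na)
  c(flank5 = b[1], center = b[2], flank3 = b[3])
}

# Accepts a named character vector or a DNAStringSet; returns named character.
.as_reference <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    out <- as.character(reference)
    names(out) <- names(reference)
    return(out)
  }
  if (is.character(reference)) {
    if (is.null(names(reference)))
      stop("reference sequences must be named by contig", call. = FALSE)
    return(reference)
  }
  stop("reference must be a named character vector or a DNAStringSet",
       call. = FALSE)
}
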