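# Shared fixtures, all generated in code.

BASES <- c("A", "C", "G", "T")

# Two signatures with disjoint channel support (exact-mixture fixtures).
disjoint_signatures <- function() {
  S <- matrix(0, 96, 2, dimnames = list(mutation_channels(), c("sA", "sB")))
  S[1:10, 1] <- 0.1
  S[21:30, 2] <- 0.1
  S
}

# All 192 raw substitution-in-context inputs.
all_raw_substitutions <- function() {
  g <- expand.grid(ref = BASES, alt = BASES, f5 = BASES, f3 = BASES,
                   stringsAsFactors = FALSE)
  g[g$ref != g$alt, ]
}

# A reference contig containing every trinucleotide at a known center,
# and the map channel -> (pos, ref, alt) on it.
context_reference <- function() {
  tris <- apply(expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE),
                1, paste, collapse = "")
  seqs <- paste0(tris, "A")                 # 1-base separator per block
  ref <- c(ctx = paste(seqs, collapse = ""))
  centers <- (seq_along(tris) - 1L) * 4L + 2L
  names(centers) <- tris
  list(reference = ref, centers = centers)
}

# Expand a 96-channel count vector into an equivalent SNV list on the
# context reference (one row per mutation).
catalogue_to_variants <- function(counts, sample_id = "sample") {
  ctx <- context_reference()
  labs <- mutation_channels()
  rows <- lapply(which(counts > 0), function(i) {
    lab <- labs[i]
    f5 <- substr(lab, 1, 1); ref <- substr(lab, 3, 3)
    alt <- substr(lab, 5, 5); f3 <- substr(lab, 7, 7)
    tri <- paste0(f5, ref, f3)
    data.frame(sample_id = sample_id, chrom = "ctx",
               pos = rep(unname(ctx$centers[tri]), counts[i]),
               ref = ref, alt = alt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0))
  out
}

cosine_vec_test <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Naive scalar microhomology oracle: direct character comparison.
mh_oracle <- function(seq, up, down) {
  L <- nchar(seq)
  p <- 0L
  for (j in seq_len(L)) {
    if (substr(seq, j, j) == substr(down, j, j)) p <- j else break
  }
  q <- 0L
  for (j in seq_len(L)) {
    a <- substr(seq, L - j + 1L, L - j + 1L)
    b <- substr(up, nchar(up) - j + 1L, nchar(up) - j + 1L)
    if (a == b) q <- j else break
  }
  list(mh = min(max(p, q), L - 1L), at_repeat = max(p, q) == L)
}

# Exact two-sided Mann-Whitney p via the Wilcoxon null distribution
# (independent of the package's enumeration path; no ties only).
mwu_dwilcox_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  u_all <- 0:(n1 * n2)
  keep <- abs(u_all - mu) >= abs(U - mu) - 1e-9
  sum(stats::dwilcox(u_all[keep], n1, n2))
}
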