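test_that("germline and panel-of-normals rules remove the right variants", {
  variants <- data.frame(
    sample_id = "s1", chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
    ref = "C", alt = "T", stringsAsFactors = FALSE)
  germ <- data.frame(chrom = "chr1", pos = 10L, ref = "C", alt = "T")
  panel <- data.table::data.table(
    chrom = "chr1", pos = c(20L, 30L), ref = "C", alt = "T")
  panel$panel_read_counts <- list(c(2L, 2L, 0L), c(5L, 1L, 1L))
  res <- filter_variants(variants, germ, panel)
  expect_equal(res$kept$pos, c(30L, 40L))   # 30: one sample at >=2 reads only
  expect_equal(res$removed$reason, c("germline", "panel_of_normals"))
})

test_that("filtering is idempotent", {
  variants <- data.frame(sample_id = "s1", chrom = "chr1",
                         pos = c(10L, 20L), ref = "C", alt = "T",
                         stringsAsFactors = FALSE)
  germ <- data.frame(chrom = "chr1", pos = 10L, ref = "C", alt = "T")
  first <- filter_variants(variants, germ, NULL)
  second <- filter_variants(first$kept, germ, NULL)
  expect_equal(nrow(second$removed), 0)
  expect_equal(second$kept, first$kept)
})

test_that("catalogue counts classifiable SNVs and conserves totals", {
  ref <- c(chr1 = "AACGTTTACGT")   # ACG at 2:4 twice (pos 3 and 9 centers C)
  variants <- data.frame(
    sample_id = "s1", chrom = "chr1",
    pos = c(3L, 9L, 3L, 1L),       # pos 1 has no 5' flank -> excluded
    ref = c("C", "C", "C", "A"), alt = c("T", "T", "T", "G"),
    stringsAsFactors = FALSE)
  cat1 <- build_catalogue(variants, ref)
  expect_s3_class(cat1, "mutational_catalogue")
  expect_equal(cat1$counts[["A[C>T]G"]], 3L)
  expect_equal(cat1$n_mutations, 3L)
  expect_equal(cat1$n_excluded, 1L)
  expect_equal(sum(cat1$counts) + cat1$n_excluded, 4L)
})

test_that("empty input yields the zero catalogue", {
  v <- data.frame(sample_id = character(0), chrom = character(0),
                  pos = integer(0), ref = character(0), alt = character(0))
  cat0 <- build_catalogue(v, c(chr1 = "ACGTA"))
  expect_equal(cat0$n_mutations, 0L)
  expect_true(all(cat0$counts == 0))
})

test_that("indels and MNVs do not enter the 96-channel catalogue", {
  ref <- c(chr1 = "AACGTTT")
  v <- data.frame(sample_id = "s1", chrom = "chr1", pos = c(3L, 3L, 3L),
                  ref = c("C", "CG", "CG"), alt = c("T", "C", "TA"),
                  stringsAsFactors = FALSE)
  cat1 <- build_catalogue(v, ref)
  expect_equal(cat1$n_mutations, 1L)
  expect_equal(cat1$n_excluded, 0L)
})

test_that("planted-variant round trip reproduces the expected catalogue exactly", {
  sim <- simulate_reference_and_variants(5000, 400, seed = 7)
  got <- build_catalogue(sim$variants, sim$reference)
  expect_equal(got$counts, sim$expected_catalogue)
  expect_equal(got$n_mutations, 400L)
  # purine-referenced plants land in pyrimidine channels by construction
  sim0 <- simulate_reference_and_variants(100, 0, seed = 1)
  expect_true(all(sim0$expected_catalogue == 0))
})

test_that("catalogue matrix round-trips through TSV", {
  sim <- simulate_reference_and_variants(2000, 100, seed = 3, sample_id = "a")
  m <- build_catalogue_matrix(sim$variants, sim$reference)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalogue_matrix(m, path)
  expect_equal(read_catalogue_matrix(path), m)
})

test_that("exome-to-genome normalization rescales by trinucleotide ratio", {
  labs <- mutation_channels()
  sig <- stats::setNames(rep(0, 96), labs)
  # two channels on different trinucleotides: ACA (A[C>A]A), ACC (A[C>A]C)
  sig[c("A[C>A]A", "A[C>A]C")] <- 0.5
  tris <- sort(unique(paste0(substr(labs, 1, 1), substr(labs, 3, 3),
                             substr(labs, 7, 7))))
  ef <- stats::setNames(rep(1, length(tris)), tris)
  gf <- ef
  gf["ACA"] <- 2                        # ratio 2 vs 1
  out <- normalize_exome_signature(sig, ef, gf)
  expect_equal(unname(out[c("A[C>A]A", "A[C>A]C")]), c(2 / 3, 1 / 3))
  expect_equal(sum(out), 1, tolerance = 1e-12)
  # identity when frequencies agree
  expect_equal(normalize_exome_signature(sig, ef, ef), sig)
  # swapping the frequency arguments inverts the transform
  back <- normalize_exome_signature(out, gf, ef)
  expect_equal(back, sig, tolerance = 1e-10)
})

test_that("normalization refuses zero exome frequency under signature mass", {
  labs <- mutation_channels()
  sig <- stats::setNames(rep(1 / 96, 96), labs)
  tris <- sort(unique(paste0(substr(labs, 1, 1), substr(labs, 3, 3),
                             substr(labs, 7, 7))))
  ef <- stats::setNames(rep(1, length(tris)), tris)
  ef["ACA"] <- 0
  gf <- stats::setNames(rep(1, length(tris)), tris)
  expect_error(normalize_exome_signature(sig, ef, gf), "zero exome")
})

test_that("trinucleotide frequencies collapse reverse complements", {
  tf <- trinucleotide_frequencies(c(chr1 = "ACAACA", chr2 = "TGTTGT"))
  # TGT is the reverse complement of ACA: all counts pool onto ACA
  expect_true(all(substr(names(tf$freq), 2, 2) %in% c("C", "T")))
  expect_equal(unname(tf$freq[["ACA"]]), 4)
  expect_equal(tf$territory_bp, 12L)
})

test_that("mutation prevalence per megabase", {
  expect_equal(mutations_per_megabase(3000, 3e9), 1.0)
  expect_equal(mutations_per_megabase(0, 3e9), 0.0)
  expect_equal(mutations_per_megabase(50, 5e7), 1.0)
  expect_error(mutations_per_megabase(10, 0), "territory_bp")
})

test_that("variant TSV and minimal VCF parse to the same records", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tchrom\tpos\tref\talt",
               "s1\tchr1\t3\tC\tT",
               "s1\tchr1\t5\tA\tG"), tsv)
  v1 <- read_variants(tsv)
  expect_equal(nrow(v1), 2)
  expect_equal(v1$ref, c("C", "A"))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t3\t.\tC\tT\t.\tPASS\t.",
               "chr1\t5\t.\tA\tG,T\t.\tPASS\t."), vcf)
  v2 <- read_variants(vcf, sample_id = "s1")
  expect_equal(nrow(v2), 3)     # multi-allelic split
  expect_equal(v2$alt, c("T", "G", "T"))
  expect_equal(v2$chrom, rep("chr1", 3))
})

test_that("records with ambiguity codes are rejected during parsing", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tchrom\tpos\tref\talt",
               "s1\tchr1\t3\tN\tT",
               "s1\tchr1\t5\tA\tA",
               "s1\tchr1\t7\tA\tG"), tsv)
  expect_warning(v <- read_variants(tsv), "rejected")
  expect_equal(nrow(v), 1)
  rej <- attr(v, "rejected")
  expect_equal(nrow(rej), 2)
  expect_setequal(rej$reason, c("non-ACGT ref", "ref equals alt"))
})
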