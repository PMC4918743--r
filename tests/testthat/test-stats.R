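test_that("Fisher exact test matches the published gastric histology tables", {
  tabs <- gastric_histology_tables()
  expect_equal(round(fisher_exact_two_tailed(tabs$discohesive_growth), 4),
               0.0003)
  expect_equal(round(fisher_exact_two_tailed(tabs$intestinal_vs_rest), 4),
               0.0058)
  expect_equal(round(fisher_exact_two_tailed(tabs$diffuse_vs_rest), 4),
               0.0015)
})

test_that("Fisher test symmetries and degenerate margins", {
  p <- fisher_exact_two_tailed(6, 5, 6, 83)
  # simultaneous row and column swap leaves p unchanged
  expect_equal(fisher_exact_two_tailed(83, 6, 5, 6), p)
  # swapping the rows leaves p unchanged (table symmetry)
  expect_equal(fisher_exact_two_tailed(6, 83, 6, 5), p)
  expect_equal(fisher_exact_two_tailed(0, 10, 0, 10), 1.0)
  expect_error(fisher_exact_two_tailed(0, 0, 0, 0), "empty")
  expect_error(fisher_exact_two_tailed(-1, 2, 3, 4), "non-negative")
})

test_that("the textbook exact Mann-Whitney case gives p = 0.1", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(res$p, 0.1)
  expect_equal(res$U, 0)
})

test_that("identical samples give p = 1 under the exact convention", {
  res <- mann_whitney_u(c(2, 5, 9), c(2, 5, 9), mode = "exact")
  expect_equal(res$p, 1.0)
})

test_that("exact Mann-Whitney equals the null-distribution oracle", {
  set.seed(13)
  for (n1 in 1:5) {
    for (n2 in n1:(10 - n1)) {
      x <- sample(1:100, n1)
      y <- sample(setdiff(1:100, x), n2)
      got <- mann_whitney_u(x, y, mode = "exact")$p
      expect_equal(got, mwu_dwilcox_oracle(x, y), tolerance = 1e-12,
                   info = paste(n1, n2))
    }
  }
})

test_that("normal approximation tracks the exact p for moderate samples", {
  set.seed(17)
  x <- sample(1:1000, 8)
  y <- sample(setdiff(1:1000, x), 8)
  pe <- mann_whitney_u(x, y, mode = "exact")$p
  pn <- mann_whitney_u(x, y, mode = "normal")$p
  expect_lt(abs(pe - pn), 0.02)
  # and agrees with the standard implementation, tie-corrected
  xt <- c(1, 2, 2, 5, 7, 7, 9)
  yt <- c(2, 3, 3, 7, 8, 10, 11, 11)
  got <- mann_whitney_u(xt, yt, mode = "normal")$p
  want <- suppressWarnings(stats::wilcox.test(xt, yt, correct = TRUE)$p.value)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("auto mode picks exact only for small tie-free samples", {
  expect_equal(mann_whitney_u(1:3, 4:6)$mode, "exact")
  expect_equal(mann_whitney_u(c(1, 2, 2), 4:6)$mode, "normal")
  expect_equal(mann_whitney_u(1:9, 10:18)$mode, "normal")
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("contingency construction reproduces the published Lauren counts", {
  # reconstruct the 409 annotated samples from the printed per-level counts
  lv <- c(rep("intestinal", 271), rep("diffuse", 105), rep("mixed", 33),
          rep("unknown", 20))
  sig3 <- c(rep(TRUE, 32), rep(FALSE, 239),   # intestinal 32/239
            rep(TRUE, 2), rep(FALSE, 103),    # diffuse 2/103
            rep(TRUE, 3), rep(FALSE, 30),     # mixed 3/30
            rep(FALSE, 20))
  ann <- data.frame(sample_id = paste0("g", seq_along(lv)),
                    histology_lauren = lv, stringsAsFactors = FALSE)
  calls <- stats::setNames(sig3, ann$sample_id)
  tab <- build_contingency(ann, calls,
                           list(name = "histology_lauren",
                                present = "intestinal",
                                unknown = "unknown"))
  expect_equal(unname(as.vector(tab)), c(32, 5, 239, 133))
  expect_equal(round(fisher_exact_two_tailed(tab), 4), 0.0058)
  tab2 <- build_contingency(ann, calls,
                            list(name = "histology_lauren",
                                 present = "diffuse", unknown = "unknown"))
  expect_equal(unname(as.vector(tab2)), c(2, 35, 103, 269))
  expect_equal(round(fisher_exact_two_tailed(tab2), 4), 0.0015)
})

test_that("contingency construction validates its inputs", {
  ann <- data.frame(sample_id = c("a", "b"),
                    histology_lauren = c("unknown", "unknown"),
                    stringsAsFactors = FALSE)
  calls <- c(a = TRUE, b = FALSE)
  expect_error(build_contingency(ann, calls,
                                 list(name = "histology_lauren",
                                      present = "intestinal",
                                      unknown = "unknown")),
               "unknown")
  ann2 <- data.frame(sample_id = c("a", "z"),
                     histology_lauren = c("diffuse", "intestinal"),
                     stringsAsFactors = FALSE)
  expect_error(build_contingency(ann2, calls,
                                 list(name = "histology_lauren",
                                      present = "intestinal")),
               "z")
  # single-level stratifier: degenerate margin, downstream p = 1
  ann3 <- data.frame(sample_id = c("a", "b"),
                     histology_lauren = c("diffuse", "diffuse"),
                     stringsAsFactors = FALSE)
  tab <- build_contingency(ann3, calls,
                           list(name = "histology_lauren",
                                present = "diffuse"))
  expect_equal(fisher_exact_two_tailed(tab), 1.0)
})

test_that("p-value formatting matches the report conventions", {
  expect_equal(format_pvalue(c(0.005796, 0.0003, 1.07e-5)),
               c("0.0058", "3.00e-04", "1.07e-05"))
})

test_that("a planted annotation association is detectable by Fisher's test", {
  calls <- stats::setNames(rep(c(TRUE, FALSE), c(12, 88)), paste0("s", 1:100))
  hits <- 0
  for (seed in 1:30) {
    ann <- simulate_annotations(calls, base_rate = 0.07,
                                association_odds = 15, seed = seed)
    tab <- build_contingency(ann, calls,
                             list(name = "discohesive_growth",
                                  present = TRUE))
    if (fisher_exact_two_tailed(tab) < 0.01) hits <- hits + 1
  }
  expect_gte(hits / 30, 0.9)
})

test_that("a null annotation shows no association", {
  calls <- stats::setNames(rep(c(TRUE, FALSE), c(12, 88)), paste0("s", 1:100))
  ps <- vapply(1:60, function(seed) {
    ann <- simulate_annotations(calls, base_rate = 0.3,
                                association_odds = 1, seed = 1000 + seed)
    fisher_exact_two_tailed(
      build_contingency(ann, calls, list(name = "discohesive_growth",
                                         present = TRUE)))
  }, numeric(1))
  expect_gte(median(ps), 0.2)
})
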