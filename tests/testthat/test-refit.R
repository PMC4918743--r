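test_that("an exact two-signature mixture is recovered with zero residual", {
  S <- disjoint_signatures()
  m <- 100 * S[, 1] + 50 * S[, 2]
  fit <- fit_exposures(m, S)
  expect_equal(unname(fit$exposures), c(100, 50), tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-6)
  expect_equal(sum(fit$exposures), fit$total)
})

test_that("a single candidate signature absorbs the whole total", {
  S <- disjoint_signatures()
  m <- 100 * S[, 1] + 50 * S[, 2]
  fit <- fit_exposures(m, S[, 1, drop = FALSE])
  expect_equal(unname(fit$exposures), 150)
  expect_gt(fit$residual_norm, 0)
})

test_that("degenerate inputs are handled", {
  S <- disjoint_signatures()
  zero <- stats::setNames(rep(0, 96), rownames(S))
  fit <- fit_exposures(zero, S)
  expect_equal(unname(fit$exposures), c(0, 0))
  expect_equal(fit$residual_norm, 0)
  expect_error(fit_exposures(zero[1:10], S), "96")
  expect_error(fit_exposures(zero, S[, 0]), "empty")
})

test_that("constraints hold on noisy fits", {
  sigs <- simulate_signatures(4, seed = 2)
  cfg <- simulation_config(n_samples = 10, k_signatures = 4,
                           burden_meanlog = log(500), burden_sdlog = 1,
                           sparsity = 0.4, seed = 3)
  sim <- simulate_cohort(cfg, sigs)
  reg <- signature_set(sigs, registry = list(cohort = colnames(sigs)))
  fits <- fit_cohort(sim$catalogues, registry = reg)
  for (f in fits) {
    expect_true(all(f$exposures >= 0))
    expect_true(all(f$exposures <= f$total + 1e-6))
    expect_equal(sum(f$exposures), f$total, tolerance = 1e-6)
  }
})

test_that("the solver is no worse than integer-grid enumeration", {
  # small-total instances solvable by brute force
  for (i in 1:15) {
    k <- 2 + i %% 2
    sigs <- simulate_signatures(k, seed = 400 + i)
    total <- 20 + (i * 7) %% 41
    cfg <- simulation_config(n_samples = 1, k_signatures = k,
                             burden_meanlog = log(total), burden_sdlog = 0,
                             sparsity = 0, sig3_prevalence = 1,
                             seed = 500 + i)
    m <- as.numeric(simulate_cohort(cfg, sigs)$catalogues[, 1])
    total <- sum(m)
    fit <- fit_exposures(m, sigs)
    if (k == 2) {
      grid <- rbind(0:total, total - (0:total))
    } else {
      g <- expand.grid(e1 = 0:total, e2 = 0:total)
      g <- g[g$e1 + g$e2 <= total, ]
      grid <- rbind(g$e1, g$e2, total - g$e1 - g$e2)
    }
    obj <- colSums((m - sigs %*% grid)^2)
    expect_lte(fit$residual_norm^2, min(obj) + 1e-6)
  }
})

test_that("exposures are invariant to uniform rescaling of the signatures", {
  S <- simulate_signatures(3, seed = 9)
  m <- as.numeric(S %*% c(40, 25, 10))
  f1 <- fit_exposures(m, signature_set(7.5 * S, registry = list()))
  f2 <- fit_exposures(m, S)
  expect_equal(f1$exposures, f2$exposures, tolerance = 1e-6)
})

test_that("recovery error shrinks as the mutation burden grows", {
  sigs <- simulate_signatures(3, seed = 14)
  err_at <- function(total) {
    cfg <- simulation_config(n_samples = 15, k_signatures = 3,
                             burden_meanlog = log(total), burden_sdlog = 0,
                             sparsity = 0, sig3_prevalence = 1, seed = 77)
    sim <- simulate_cohort(cfg, sigs)
    reg <- signature_set(sigs, registry = list(cohort = colnames(sigs)))
    fits <- fit_cohort(sim$catalogues, registry = reg)
    mean(vapply(seq_along(fits), function(i)
      mean(abs(fits[[i]]$exposures - sim$truth$exposures[, i])) /
        fits[[i]]$total, numeric(1)))
  }
  errs <- c(err_at(1000), err_at(10000), err_at(100000))
  expect_true(all(diff(errs) < 0))
})

test_that("subset selection follows the operative-signature registry", {
  S <- simulate_signatures(5, seed = 6)
  colnames(S) <- c("signature 1", "signature 3", "signature 5",
                   "signature 6", "signature 18")
  reg <- signature_set(
    S,
    feature_flags = list("signature 6" = "indels_at_repeats"),
    registry = list(
      neuroblastoma = c("signature 1", "signature 5", "signature 18"),
      colorectal = c("signature 1", "signature 6")))
  # neuroblastoma: the three registered signatures, no flags involved
  q <- select_subset(sample_features("neuroblastoma"), registry = reg)
  expect_setequal(colnames(q$signatures),
                  c("signature 1", "signature 5", "signature 18"))
  # repeat-indel-flagged signature drops out without supporting indels
  q2 <- select_subset(sample_features("colorectal", n_indels_at_repeats = 0),
                      registry = reg)
  expect_equal(colnames(q2$signatures), "signature 1")
  q3 <- select_subset(sample_features("colorectal", n_indels_at_repeats = 25),
                      registry = reg)
  expect_setequal(colnames(q3$signatures), c("signature 1", "signature 6"))
  expect_error(select_subset(sample_features("melanoma"), registry = reg),
               "neuroblastoma")
})

test_that("presence calls respect both thresholds", {
  S <- disjoint_signatures()
  m <- 100 * S[, 1] + 50 * S[, 2]
  fit <- fit_exposures(m, S)
  expect_true(call_signature_present(fit, "sA"))
  expect_false(call_signature_present(fit, "sA", min_mutations = 200))
  expect_false(call_signature_present(fit, "sB", min_fraction = 0.5))
  expect_error(call_signature_present(fit, "nope"), "nope")
  m0 <- fit_exposures(0 * m, S)
  expect_false(call_signature_present(m0, "sA"))
})

test_that("cohort fitting is sample-order equivariant", {
  sigs <- simulate_signatures(3, seed = 8)
  cfg <- simulation_config(n_samples = 6, k_signatures = 3, seed = 4)
  sim <- simulate_cohort(cfg, sigs)
  reg <- signature_set(sigs, registry = list(cohort = colnames(sigs)))
  f1 <- fit_cohort(sim$catalogues, registry = reg)
  perm <- c(4, 2, 6, 1, 3, 5)
  f2 <- fit_cohort(sim$catalogues[, perm], registry = reg)
  expect_equal(f2, f1[perm])
})
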