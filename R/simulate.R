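# Synthetic-data generators. Every input the pipeline consumes can be
# produced here from a seed, with the planted ground truth returned
# alongside, so all stages are testable without external cohorts. The
# default regime echoes the shape of a gastric whole-genome cohort: 100
# samples, ~12% signature-3-positive, and a roughly four-fold enrichment of
# microhomology deletions in positive samples.

#' Simulation configuration
#'
#' @param n_samples Cohort size.
#' @param k_signatures Number of planted signatures.
#' @param burden_meanlog,burden_sdlog Log-normal parameters of the
#'   per-sample mutation total (`sdlog = 0` gives a fixed burden).
#' @param exposure_concentration Dirichlet concentration of the active
#'   exposure weights.
#' @param sparsity Probability that a given signature is inactive in a
#'   sample (the first signature plays the role of signature 3 and is
#'   activated with probability `sig3_prevalence` instead).
#' @param sig3_prevalence Fraction of samples in which the signature-3
#'   surrogate is active (default 0.12).
#' @param min_active_fraction Active signatures are re-drawn until each
#'   carries at least this fraction of the sample's mutations, so planted
#'   activity is detectable in principle.
#' @param noise_model `"multinomial"` (counts sum exactly to the burden) or
#'   `"poisson"`.
#' @param mh_rate Mean number of microhomology deletions in a
#'   signature-3-negative sample.
#' @param mh_enrichment Fold enrichment of that rate in positive samples
#'   (default 4, echoing a 715-vs-172 median contrast).
#' @param filler_rate Mean number of non-microhomology filler indels per
#'   sample.
#' @param association_odds Odds ratio of the planted binary histology
#'   annotation for signature-3-positive samples.
#' @param annotation_base_rate Baseline probability of that annotation.
#' @param seed Integer seed.
#' @return A `"simulation_config"` list; unknown arguments are an error by
#'   construction.
#' @export
simulation_config <- function(n_samples = 100L, k_signatures = 4L,
                              burden_meanlog = log(8000), burden_sdlog = 0.5,
                              exposure_concentration = 5,
                              sparsity = 0.3, sig3_prevalence = 0.12,
                              min_active_fraction = 0.1,
                              noise_model = c("multinomial", "poisson"),
                              mh_rate = 170, mh_enrichment = 4,
                              filler_rate = 170,
                              association_odds = 15,
                              annotation_base_rate = 0.07,
                              seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_samples >= 1, k_signatures >= 1, exposure_concentration > 0,
            sparsity >= 0, sparsity <= 1, sig3_prevalence >= 0,
            sig3_prevalence <= 1, mh_rate > 0, mh_enrichment > 0,
            filler_rate >= 0, association_odds > 0,
            annotation_base_rate > 0, annotation_base_rate < 1)
  structure(as.list(environment()), class = "simulation_config")
}

# Dirichlet draw.
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), ncol = k, byrow = TRUE)
  x / rowSums(x)
}

#' Simulate well-separated mutational signatures
#'
#' Draws `k` signature densities over the 96 channels from a Dirichlet
#' distribution and rejection-resamples the set until every pair is at
#' least `min_pairwise_cosine_distance` apart in cosine distance.
#'
#' @param k Number of signatures.
#' @param concentration Dirichlet concentration (default 0.5; small values
#'   give the spiky, distinctive profiles real signatures have).
#' @param min_pairwise_cosine_distance Required separation (default 0.7).
#' @param seed Integer seed.
#' @param max_tries Rejection budget.
#' @return 96 x k matrix, columns named `sig1..sigk` summing to 1.
#' @export
simulate_signatures <- function(k, concentration = 0.5,
                                min_pairwise_cosine_distance = 0.7,
                                seed = 1L, max_tries = 2000L) {
  stopifnot(k >= 1)
  with_seed(seed, {
    # grow the set one signature at a time, rejecting draws too close to
    # any accepted one
    S <- matrix(0, 96, k)
    accepted <- 0L
    tries <- 0L
    while (accepted < k) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not draw ", k, " signatures at separation ",
             min_pairwise_cosine_distance,
             "; lower k or the required separation", call. = FALSE)
      cand <- as.numeric(.rdirichlet(1, rep(concentration, 96)))
      if (accepted > 0) {
        sims <- .cosine_sim(S[, seq_len(accepted), drop = FALSE],
                            matrix(cand, 96, 1))
        if (max(sims) > 1 - min_pairwise_cosine_distance) next
      }
      accepted <- accepted + 1L
      S[, accepted] <- cand
    }
    dimnames(S) <- list(.CHANNELS, paste0("sig", seq_len(k)))
    S
  })
}

#' Simulate a cohort of mutational catalogues
#'
#' Per sample: the mutation total is drawn log-normally; an active signature
#' set is drawn (the first signature acts as the signature-3 surrogate,
#' active with probability `sig3_prevalence`; the others are each inactive
#' with probability `sparsity`; at least one signature is always active);
#' exposure weights for the active set come from a Dirichlet, re-drawn until
#' every active weight is at least `min_active_fraction`; channel counts are
#' then drawn multinomially (or Poisson) around the mixed density.
#'
#' @param config A [simulation_config()].
#' @param signatures 96 x k matrix of planted signatures (defaults to
#'   [simulate_signatures()] under the config's seed).
#' @return List with `catalogues` (96 x n count matrix), `truth` (list:
#'   `signatures`, `exposures` k x n matrix of planted mutation counts,
#'   `calls` named logical vector of planted signature-3-surrogate
#'   activity, `sig3_name`).
#' @export
simulate_cohort <- function(config, signatures = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(signatures))
    signatures <- simulate_signatures(config$k_signatures,
                                      seed = derive_seeds(config$seed, 1L))
  S <- as.matrix(signatures)
  k <- ncol(S)
  n <- config$n_samples
  with_seed(derive_seeds(config$seed, 2L)[2], {
    samples <- sprintf("S%03d", seq_len(n))
    totals <- round(stats::rlnorm(n, config$burden_meanlog, config$burden_sdlog))
    totals <- pmax(totals, 1)
    E <- matrix(0, k, n, dimnames = list(colnames(S), samples))
    calls <- stats::setNames(logical(n), samples)
    V <- matrix(0L, 96, n, dimnames = list(rownames(S), samples))
    for (i in seq_len(n)) {
      active <- c(stats::runif(1) < config$sig3_prevalence,
                  stats::runif(k - 1) >= config$sparsity)
      if (!any(active)) {
        if (k == 1L) active[1] <- TRUE
        else active[1 + sample.int(k - 1, 1)] <- TRUE
      }
      calls[i] <- active[1]
      na <- sum(active)
      repeat {
        w <- as.numeric(.rdirichlet(1, rep(config$exposure_concentration, na)))
        if (na == 1 || min(w) >= config$min_active_fraction) break
      }
      wfull <- numeric(k)
      wfull[active] <- w
      E[, i] <- wfull * totals[i]
      p <- as.numeric(S %*% wfull)
      V[, i] <- if (config$noise_model == "multinomial")
        as.integer(stats::rmultinom(1, totals[i], p))
      else as.integer(stats::rpois(96, p * totals[i]))
    }
    list(catalogues = V,
         truth = list(signatures = S, exposures = E, calls = calls,
                      sig3_name = colnames(S)[1]))
  })
}

#' Simulate a reference sequence with planted SNVs
#'
#' Generates a random contig and `n_snvs` SNVs at distinct interior
#' positions, and computes the expected 96-channel catalogue directly from
#' the planted `(ref, alt, context)` tuples; [build_catalogue()] on the
#' output must reproduce it exactly.
#'
#' @param length Contig length (`>= n_snvs + 2`).
#' @param n_snvs Number of SNVs to plant.
#' @param seed Integer seed.
#' @param sample_id Sample name for the variant list.
#' @return List with `reference` (named character), `variants`
#'   (data.table), `expected_catalogue` (named integer 96-vector).
#' @export
simulate_reference_and_variants <- function(length, n_snvs, seed = 1L,
                                            sample_id = "sim") {
  stopifnot(length >= n_snvs + 2)
  with_seed(seed, {
    bases <- sample(.BASES, length, replace = TRUE)
    refseq <- paste(bases, collapse = "")
    expected <- stats::setNames(integer(96), .CHANNELS)
    if (n_snvs > 0) {
      pos <- sample(2:(length - 1), n_snvs, replace = FALSE)
      ref <- bases[pos]
      alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1),
                    character(1))
      ch <- .classify_substitutions(ref, alt, bases[pos - 1], bases[pos + 1])
      tab <- table(factor(ch, levels = .CHANNELS))
      expected <- expected + as.integer(tab)
      names(expected) <- .CHANNELS
      variants <- data.table::data.table(
        sample_id = sample_id, chrom = "chrSim", pos = as.integer(pos),
        ref = ref, alt = unname(alt))
    } else {
      variants <- data.table::data.table(
        sample_id = character(0), chrom = character(0), pos = integer(0),
        ref = character(0), alt = character(0))
    }
    list(reference = c(chrSim = refseq), variants = variants,
         expected_catalogue = expected)
  })
}

# Build one synthetic contig holding n planted indel loci at a fixed stride.
# MH deletions get a planted prefix-copy microhomology of mh bp; fillers are
# forced to mh = 0 by breaking agreement at both breakpoints. Fully
# vectorised: loci never overlap, so all edits can be applied at once.
.plant_indel_contig <- function(n_mh, n_filler,
                                del_len_range = c(4L, 12L),
                                small_len_range = c(1L, 3L),
                                mh_len_range = c(1L, 3L)) {
  n <- n_mh + n_filler
  stride <- 3L * del_len_range[2] + 20L
  clen <- n * stride + stride
  bases <- sample(.BASES, clen, replace = TRUE)
  kind_mh <- c(rep(TRUE, n_mh), rep(FALSE, n_filler))
  if (n > 1) kind_mh <- sample(kind_mh)
  pos <- (seq_len(n) - 1L) * stride + 20L
  L <- integer(n); mh <- integer(n)
  # draw a base different from `cur` by a cyclic offset: never equal
  not_base <- function(cur) {
    .BASES[(match(cur, .BASES) + sample.int(3L, length(cur), replace = TRUE)
            - 1L) %% 4L + 1L]
  }
  imh <- which(kind_mh)
  if (length(imh)) {
    Li <- sample(del_len_range[1]:del_len_range[2], length(imh),
                 replace = TRUE)
    mi <- pmin(mh_len_range[1] +
                 sample.int(mh_len_range[2] - mh_len_range[1] + 1L,
                            length(imh), replace = TRUE) - 1L,
               Li - 1L)
    st <- pos[imh]
    # downstream prefix copies the deletion prefix ...
    dest <- sequence(mi, from = st + Li)
    src <- sequence(mi, from = st)
    bases[dest] <- bases[src]
    # ... then mismatches, so the planted length is exact (p = mi < Li)
    bases[st + Li + mi] <- not_base(bases[st + mi])
    # kill upstream suffix agreement so q = 0 and at_repeat is impossible
    bases[st - 1L] <- not_base(bases[st + Li - 1L])
    L[imh] <- Li
    mh[imh] <- mi
  }
  ifl <- which(!kind_mh)
  if (length(ifl)) {
    Li <- sample(small_len_range[1]:del_len_range[2], length(ifl),
                 replace = TRUE)
    st <- pos[ifl]
    # force zero microhomology at both breakpoints
    bases[st + Li] <- not_base(bases[st])
    bases[st - 1L] <- not_base(bases[st + Li - 1L])
    L[ifl] <- Li
    mh[ifl] <- 0L
  }
  list(seq = paste(bases, collapse = ""), pos = pos, len = L,
       is_mh = kind_mh, mh = mh)
}

#' Simulate an indel cohort with planted breakpoint microhomology
#'
#' For each sample a synthetic contig is generated carrying deletions with
#' planted microhomology (all longer than 3 bp, microhomology 1-3 bp,
#' never repeat-mediated) at a Poisson rate of `mh_rate * mh_enrichment`
#' for signature-3-positive samples and `mh_rate` otherwise, plus filler
#' deletions with no breakpoint microhomology (sizes 1 bp up to the
#' deletion maximum) at `filler_rate`. Every planted microhomology deletion
#' is recoverable by [classify_indels()] at `min_mh = 1` and no filler
#' qualifies.
#'
#' @param config A [simulation_config()].
#' @param calls Named logical vector of per-sample signature-3 status.
#' @param reference Ignored unless NULL; the generator must control the
#'   flanking sequence to plant microhomology, so it always builds one
#'   contig per sample and returns the reference it used.
#' @return List with `indels` (data.table: `sample_id`, `chrom`, `pos`,
#'   `kind`, `seq`), `reference` (named character, one contig per sample),
#'   `truth` (data.table with `is_mh` and planted `mh_length` per record).
#' @export
simulate_indel_cohort <- function(config, calls, reference = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  samples <- names(calls)
  with_seed(derive_seeds(config$seed, 3L)[3], {
    ref_out <- character(0)
    rows <- vector("list", length(samples))
    for (i in seq_along(samples)) {
      s <- samples[i]
      rate <- config$mh_rate * if (calls[[s]]) config$mh_enrichment else 1
      n_mh <- stats::rpois(1, rate)
      n_fill <- stats::rpois(1, config$filler_rate)
      if (n_mh + n_fill == 0) next
      contig <- paste0("ctg_", s)
      pl <- .plant_indel_contig(n_mh, n_fill)
      ref_out[contig] <- pl$seq
      rows[[i]] <- data.table::data.table(
        sample_id = s, chrom = contig, pos = pl$pos, kind = "deletion",
        seq = substring(pl$seq, pl$pos, pl$pos + pl$len - 1L),
        is_mh = pl$is_mh, planted_mh = pl$mh)
    }
    all <- data.table::rbindlist(rows)
    if (nrow(all) == 0)
      all <- data.table::data.table(sample_id = character(0),
                                    chrom = character(0), pos = integer(0),
                                    kind = character(0), seq = character(0),
                                    is_mh = logical(0), planted_mh = integer(0))
    truth <- all[, c("sample_id", "chrom", "pos", "is_mh", "planted_mh"),
                 with = FALSE]
    indels <- all[, c("sample_id", "chrom", "pos", "kind", "seq"),
                  with = FALSE]
    list(indels = indels, reference = ref_out, truth = truth)
  })
}

#' Simulate histology annotations with a planted association
#'
#' Draws a binary annotation (the compact discohesive growth pattern) whose
#' log-odds are shifted by `log(association_odds)` in
#' signature-3-positive samples, and a Lauren type drawn independently of
#' the call for the remaining columns.
#'
#' @param calls Named logical vector of per-sample signature-3 status.
#' @param base_rate Baseline annotation probability.
#' @param association_odds Planted odds ratio.
#' @param seed Integer seed.
#' @return data.frame as from [read_annotations()].
#' @export
simulate_annotations <- function(calls, base_rate = 0.07,
                                 association_odds = 15, seed = 1L) {
  samples <- names(calls)
  with_seed(seed, {
    lo <- stats::qlogis(base_rate) + log(association_odds) * as.numeric(calls)
    dg <- stats::runif(length(samples)) < stats::plogis(lo)
    lauren <- sample(c("intestinal", "diffuse", "mixed", "unknown"),
                     length(samples), replace = TRUE,
                     prob = c(0.5, 0.3, 0.1, 0.1))
    data.frame(sample_id = samples, cohort = "sim",
               histology_lauren = lauren, discohesive_growth = dg,
               stringsAsFactors = FALSE)
  })
}
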