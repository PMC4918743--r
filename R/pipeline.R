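# End-to-end orchestration: filter -> catalogue -> (extract) -> refit ->
# indels -> associate -> report, driven by a validated configuration list.
# All outputs are plain text (TSV/JSON) and byte-identical on rerun with
# the same config and inputs.

.RUN_CONFIG_KEYS <- c(
  "variants", "reference", "germline_sites", "panel", "signatures",
  "registry_cancer_type", "feature_flags", "registry", "features",
  "indels", "sv_counts", "annotations", "out_dir", "seed",
  "extract_k_range", "extract_bootstraps", "call_min_mutations",
  "call_min_fraction", "indel_min_size", "indel_min_mh", "sig3_name",
  "verbose")

#' Build and validate a pipeline configuration
#'
#' @param variants Path to a variant TSV/VCF (required).
#' @param reference Path to the reference FASTA (required).
#' @param signatures Path to a 96 x k signature TSV (required for
#'   refitting).
#' @param out_dir Output directory (required).
#' @param germline_sites,panel Optional filter inputs (paths).
#' @param registry Optional named list cancer type -> signature names; by
#'   default every signature is fitted in every sample.
#' @param registry_cancer_type Cancer type label for all samples (default
#'   `"cohort"`).
#' @param feature_flags Optional named list signature -> feature flags.
#' @param features Optional named list of [sample_features()].
#' @param indels Optional indel TSV (`sample`, `chrom`, `pos`, `kind`,
#'   `seq`).
#' @param sv_counts Optional SV-count TSV/BEDPE.
#' @param annotations Optional annotation TSV (see [read_annotations()]).
#' @param extract_k_range Optional integer range to run de novo extraction.
#' @param extract_bootstraps Bootstraps for extraction (default 20).
#' @param call_min_mutations,call_min_fraction Signature-call thresholds.
#' @param indel_min_size,indel_min_mh Microhomology-deletion thresholds.
#' @param sig3_name Which signature column to call (default the first).
#' @param seed Integer seed.
#' @param verbose Log stage progress to stderr.
#' @return A validated `"run_config"` list.
#' @export
run_config <- function(variants, reference, signatures, out_dir,
                       germline_sites = NULL, panel = NULL,
                       registry = NULL, registry_cancer_type = "cohort",
                       feature_flags = list(), features = NULL,
                       indels = NULL, sv_counts = NULL, annotations = NULL,
                       extract_k_range = NULL, extract_bootstraps = 20L,
                       call_min_mutations = 10, call_min_fraction = 0.05,
                       indel_min_size = 3L, indel_min_mh = 1L,
                       sig3_name = NULL, seed = 1L, verbose = TRUE) {
  cfg <- as.list(environment())
  unknown <- setdiff(names(cfg), .RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (key in c("variants", "reference", "signatures", "germline_sites",
                "panel", "indels", "sv_counts", "annotations")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p))
      stop("input file for '", key, "' not found: ", p, call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

.stage_log <- function(verbose, stage, ...) {
  if (verbose) message("[", stage, "] ", ...)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: variant filtering, catalogue construction, optional
#' de novo signature extraction, exposure refitting with signature calls,
#' optional microhomology-indel classification and burden summary, optional
#' association tests, and report writing. Any stage failure aborts with the
#' stage name. Outputs under `out_dir`: `catalogues.tsv`, `exposures.tsv`,
#' `calls.tsv`, optionally `extracted_signatures.tsv`,
#' `extraction_report.tsv`, `burdens.tsv`, `associations.tsv`, plus
#' `manifest.json` recording the resolved configuration and seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  v <- config$verbose
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  .stage_log(v, "filter", "reading and filtering variants")
  filt <- run_stage("filter", {
    variants <- read_variants(config$variants)
    germ <- if (!is.null(config$germline_sites))
      read_germline_sites(config$germline_sites) else NULL
    pan <- if (!is.null(config$panel)) read_panel_evidence(config$panel)
      else NULL
    filter_variants(variants, germ, pan)
  })

  .stage_log(v, "catalogue", "building 96-channel catalogues")
  catalogues <- run_stage("catalogue", {
    reference <- read_reference(config$reference)
    build_catalogue_matrix(filt$kept, reference)
  })
  write_catalogue_matrix(catalogues, file.path(config$out_dir,
                                               "catalogues.tsv"))

  extraction <- NULL
  if (!is.null(config$extract_k_range)) {
    .stage_log(v, "extract", "de novo signature extraction")
    extraction <- run_stage("extract", {
      extract_signatures(catalogues, config$extract_k_range,
                         n_bootstraps = config$extract_bootstraps,
                         seed = config$seed)
    })
    write_signature_matrix(extraction$consensus_signatures,
                           file.path(config$out_dir,
                                     "extracted_signatures.tsv"))
    rep_dt <- data.frame(k = sub("^k", "", names(extraction$per_k_stability)),
                         stability = extraction$per_k_stability,
                         recon_error = extraction$per_k_error,
                         distinct = extraction$per_k_valid)
    data.table::fwrite(rep_dt, file.path(config$out_dir,
                                         "extraction_report.tsv"),
                       sep = "\t")
  }

  .stage_log(v, "refit", "fitting signature exposures")
  refit <- run_stage("refit", {
    sigmat <- read_signature_matrix(config$signatures)
    registry <- config$registry
    if (is.null(registry))
      registry <- stats::setNames(list(colnames(sigmat)),
                                  config$registry_cancer_type)
    sigset <- signature_set(sigmat, feature_flags = config$feature_flags,
                            registry = registry)
    fits <- fit_cohort(catalogues, features = config$features,
                       registry = sigset)
    sig3 <- if (is.null(config$sig3_name)) colnames(sigmat)[1]
      else config$sig3_name
    calls <- vapply(fits, function(f) {
      if (!sig3 %in% names(f$exposures)) return(FALSE)
      call_signature_present(f, sig3,
                             min_mutations = config$call_min_mutations,
                             min_fraction = config$call_min_fraction)
    }, logical(1))
    list(fits = fits, calls = calls, sig3_name = sig3,
         signature_order = colnames(sigmat))
  })

  burdens <- NULL
  if (!is.null(config$indels)) {
    .stage_log(v, "indels", "classifying indels for microhomology")
    burdens <- run_stage("indels", {
      idt <- data.table::fread(config$indels, sep = "\t", header = TRUE,
                               colClasses = list(character = "chrom"))
      data.table::setnames(idt, "sample", "sample_id",
                           skip_absent = TRUE)
      reference <- read_reference(config$reference)
      cls <- classify_indels(idt, reference,
                             min_size = config$indel_min_size,
                             min_mh = config$indel_min_mh)
      svc <- if (!is.null(config$sv_counts))
        read_sv_counts(config$sv_counts) else NULL
      burden_table(cls, svc, refit$calls)
    })
  }

  associations <- NULL
  if (!is.null(config$annotations)) {
    .stage_log(v, "associate", "association tests")
    associations <- run_stage("associate", {
      ann <- read_annotations(config$annotations)
      out <- list()
      tab <- build_contingency(ann, refit$calls,
                               list(name = "discohesive_growth",
                                    present = TRUE))
      out[[1]] <- data.frame(comparison = "discohesive_growth",
                             a = tab[1, 1], b = tab[1, 2],
                             c = tab[2, 1], d = tab[2, 2],
                             p = fisher_exact_two_tailed(tab))
      for (lv in c("intestinal", "diffuse")) {
        tab <- build_contingency(ann, refit$calls,
                                 list(name = "histology_lauren",
                                      present = lv, unknown = "unknown"))
        out[[length(out) + 1]] <-
          data.frame(comparison = paste0(lv, "_vs_rest"),
                     a = tab[1, 1], b = tab[1, 2],
                     c = tab[2, 1], d = tab[2, 2],
                     p = fisher_exact_two_tailed(tab))
      }
      if (!is.null(burdens)) {
        mh_pos <- burdens$n_mh_indels[burdens$sig3_present]
        mh_neg <- burdens$n_mh_indels[!burdens$sig3_present]
        if (length(mh_pos) && length(mh_neg)) {
          mw <- mann_whitney_u(mh_pos, mh_neg)
          out[[length(out) + 1]] <-
            data.frame(comparison = "mh_indels_by_sig3",
                       a = NA, b = NA, c = NA, d = NA, p = mw$p)
        }
      }
      do.call(rbind, out)
    })
  }

  .stage_log(v, "report", "writing report")
  run_stage("report", {
    write_report(refit$fits, burdens, associations, config$out_dir,
                 signature_order = refit$signature_order)
    calls_df <- data.frame(sample_id = names(refit$calls),
                           sig3_present = as.logical(refit$calls))
    data.table::fwrite(calls_df[order(calls_df$sample_id), ],
                       file.path(config$out_dir, "calls.tsv"), sep = "\t")
    manifest <- list(
      package = "sigscar",
      version = as.character(utils::packageVersion("sigscar")),
      seed = config$seed,
      config = Filter(Negate(is.null),
                      config[setdiff(names(config),
                                     c("features", "verbose"))]))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  invisible(list(filtered = filt, catalogues = catalogues,
                 extraction = extraction, fits = refit$fits,
                 calls = refit$calls, burdens = burdens,
                 associations = associations))
}

#' Write the exposure / burden / association report
#'
#' Deterministic ordering: samples lexicographic, signatures in registry
#' order. Empty inputs produce header-only files.
#'
#' @param fits List of `"exposure_fit"` (named by sample).
#' @param burdens Optional [burden_table()] data.frame.
#' @param associations Optional association data.frame.
#' @param out_dir Output directory.
#' @param signature_order Optional signature column order.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(fits, burdens = NULL, associations = NULL,
                         out_dir = ".", signature_order = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  exp_path <- file.path(out_dir, "exposures.tsv")
  if (length(fits)) {
    tab <- exposure_table(fits[order(names(fits))],
                          signatures = signature_order)
  } else {
    tab <- data.frame(sample_id = character(0), total = numeric(0),
                      residual_norm = numeric(0))
  }
  data.table::fwrite(tab, exp_path, sep = "\t")
  paths <- c(paths, exp_path)
  if (!is.null(burdens)) {
    bp <- file.path(out_dir, "burdens.tsv")
    data.table::fwrite(burdens[order(burdens$sample_id), ], bp, sep = "\t")
    paths <- c(paths, bp)
  }
  if (!is.null(associations)) {
    ap <- file.path(out_dir, "associations.tsv")
    assoc <- associations
    assoc$p_formatted <- format_pvalue(assoc$p)
    data.table::fwrite(assoc, ap, sep = "\t")
    paths <- c(paths, ap)
  }
  invisible(paths)
}
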