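# sigscar

Mutational-signature analysis for cancer genomics, centred on detecting the
genomic scars of defective homologous-recombination (HR) double-strand-break
repair: **signature 3** and breakpoint-microhomology deletions. Tumours with
these scars — classically *BRCA1/2*-mutant breast, ovarian and pancreatic
cancers, but also a subset of gastric cancers — are candidates for platinum
therapy and PARP inhibition, so a reliable signature-3 call is a clinically
meaningful output.

The package covers the whole chain:

* **Catalogues** — filter somatic variant lists (germline sites,
  panel-of-normals artifact rule) and count SNVs into the 96
  pyrimidine-referenced substitution-in-context channels; exome-to-genome
  trinucleotide renormalisation; mutations per megabase.
* **De novo extraction** — bootstrapped NMF under the Frobenius objective
  with agglomerative consensus clustering and stability-based rank
  selection.
* **Refitting** — per-sample exposures $E_i$ for a fixed signature set by
  constrained least squares:
  minimise $\lVert \bar m - \sum_i E_i \bar s_i \rVert_2$ subject to
  $E_i \ge 0$, $E_i \le N$, $\sum_i E_i = N$ (the sample's mutation
  total), with registry- and feature-based selection of the candidate
  subset and a thresholded presence call.
* **Indel scars** — breakpoint-microhomology length for deletions
  (prefix/suffix rule, tandem-repeat exclusion) and per-sample burden
  tables joined with SV counts and signature-3 calls.
* **Statistics** — two-tailed Fisher exact tests (probability-mass
  convention) and exact/approximate Mann–Whitney U tests.
* **Simulators** — cohorts from planted signature mixtures, references
  with planted SNVs, indel sets with planted microhomology, annotations
  with a planted association; ground truth always returned.

See the methods vignette (`vignettes/signature-refitting-methods.Rmd`) for
the models, conventions and design decisions.

## Worked example

Simulate a 100-sample cohort in the default regime (log-normal burdens
around 8,000 mutations, four signatures, the first playing signature 3 and
active in ~12% of samples), refit exposures, call signature 3, and test the
microhomology-deletion contrast:

```r
library(sigscar)

sigs <- simulate_signatures(4, seed = 42)
cfg  <- simulation_config(n_samples = 100, seed = 42)
sim  <- simulate_cohort(cfg, sigs)

reg  <- signature_set(sigs, registry = list(gastric = colnames(sigs)))
fits <- fit_cohort(sim$catalogues, registry = reg)
fits[["S001"]]
#> exposure fit: total 9938 mutations, residual 88.55
#>    sig1    sig2    sig3    sig4
#>   49.70 7414.69   14.85 2458.76

calls <- vapply(fits, call_signature_present, logical(1),
                signature_name = "sig1")
sum(calls)                       # 7 called; identical to the planted truth
mean(calls == sim$truth$calls)   # 1

indels <- simulate_indel_cohort(cfg, calls)
cls <- classify_indels(indels$indels, indels$reference)
b   <- burden_table(cls, NULL, calls)
mann_whitney_u(b$n_mh_indels[b$sig3_present],
               b$n_mh_indels[!b$sig3_present])$p
#> 1.12e-05   (median 693 vs 171 microhomology deletions)
```

The first sample's exposures say: of its 9,938 mutations, ~7,415 are
attributed to `sig2` and ~2,459 to `sig4`; the signature-3 surrogate
(`sig1`) gets only 50 mutations (0.5%), below the 10-mutation / 5% call
thresholds, so the sample is called negative. Across the cohort the calls
match the planted truth exactly, and the called-positive group carries a
~4-fold excess of breakpoint-microhomology deletions, detected by the
Mann–Whitney test at p ≈ 10⁻⁵.

The bundled published gastric histology tables reproduce their printed
p-values:

```r
fisher_exact_two_tailed(gastric_histology_tables()$discohesive_growth)
#> 0.000269  (prints as 0.0003)
```

File-based runs go through `run_config()` + `run_pipeline()`, which execute
filter → catalogue → (extract) → refit → indels → associate → report on
TSV/VCF/FASTA inputs and write TSV reports plus a JSON manifest.

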