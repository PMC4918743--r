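---
title: "Methods: signature refitting, extraction and HRD genomic scars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature refitting, extraction and HRD genomic scars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigscar)
```

## The problem

Mutational processes — exogenous mutagens, defective repair pathways,
enzymatic DNA editing — each leave a characteristic imprint on a cancer
genome. For single-base substitutions that imprint is summarised over 96
channels: the six pyrimidine-referenced substitution classes (C>A, C>G,
C>T, T>A, T>C, T>G) crossed with the 4 × 4 possible bases immediately 5'
and 3' of the mutated base. A *mutational signature* is a probability
density over these 96 channels; a sample's *mutational catalogue* is its
vector of observed channel counts. Signature 3 — flat, broad, depleted of
sharp context preferences — marks failure of homologous-recombination (HR)
double-strand-break repair, the phenotype of *BRCA1/2* loss, and predicts
sensitivity to platinum drugs and PARP inhibitors. Its presence is
corroborated by two genomic scars of the compensating error-prone
end-joining repair: large deletions (>3 bp) with overlapping microhomology
at the breakpoints, and elevated structural-variant counts.

`sigscar` implements the full analysis chain: variant filtering, catalogue
construction, de novo signature extraction, constrained refitting of known
signatures, microhomology-deletion classification, and the exact
association statistics that link a signature-3 call to histology and indel
burden. A synthetic-data module generates every input the pipeline reads,
with ground truth attached, so the whole chain is testable without access
to any cohort.

## Catalogue construction

Coordinates are 1-based and fully closed, as in VCF. Candidate somatic
variants are filtered by two rules before counting: exact membership in a
user-supplied germline site list, and the recurrent-artifact rule — a
site supported by at least two well-mapping reads in at least two
panel-of-normals samples is discarded. The panel is consumed as a
precomputed site-evidence table; read-level inspection of BAMs is upstream
of this package's scope. Multi-allelic records are split one variant per
alternate allele; records with ambiguity codes are rejected at parse time.

Each SNV is assigned a channel from its reference trinucleotide context;
purine-referenced events are re-expressed on the opposite strand
(reference and alternate complemented, flanks complemented and swapped),
so the 192 raw representations collapse 2-to-1 onto the 96 channels. SNVs
at contig edges or with an N in context are excluded and counted, so the
catalogue total plus exclusions always equals the input SNV count.
Multi-nucleotide substitutions are not modelled as channels. Signatures
estimated from exome data are rescaled to genome-wide trinucleotide
composition by multiplying each channel by the genome/exome abundance
ratio of its trinucleotide and renormalising; frequencies collapse
reverse-complement pairs onto the 32 pyrimidine-centric trinucleotides.
Mutation prevalence is reported per haploid megabase,
`n_mutations / (territory_bp / 1e6)`.

## Exposure refitting

Given a catalogue $\bar m$ and candidate signatures $\bar s_1 \dots
\bar s_q$, the exposures $E_i$ — the number of mutations each signature
contributed — minimise

$$\left\lVert \bar m - \sum_{i=1}^{q} E_i \bar s_i \right\rVert_2
\quad\text{subject to}\quad E_i \ge 0,\; E_i \le N,\;
\sum_i E_i = N,$$

where $N$ is the sample's mutation total. The cap $E_i \le N$ is implied
by non-negativity and the equality constraint, so the feasible set is the
simplex scaled by $N$ and the problem is a convex quadratic program. It is
solved by accelerated projected gradient descent (FISTA with Euclidean
projection onto the scaled simplex), followed by an active-set polish that
solves the equality-constrained least-squares KKT system on the support of
the iterate; the polished solution is accepted only when it is feasible
and no worse. A ridge of $10^{-10}$ on the objective breaks ties between
collinear signatures in favour of the minimum-Euclidean-norm solution.
This formulation was chosen over an NNLS-plus-projection scheme because
the simplex structure makes the projection exact and the whole solver
deterministic; the unit tests verify it against exhaustive integer-grid
enumeration on small instances.

The candidate set $Q$ for a sample starts from the registry of signatures
known operative in its cancer type. Signatures carrying *feature flags* —
activity only credible alongside indels at repeats, microhomology indels,
transcriptional strand bias, dinucleotide mutations, or a hypermutator
phenotype — are retained only when the sample shows the corresponding
feature. Count thresholds default to 10 supporting indels and 5
dinucleotides; the choice of "a few" is necessarily a convention and both
are exposed as configuration. Exposures are fitted once over the selected
$Q$, with no post-fit pruning.

A signature is *called present* when its exposure reaches both 10
mutations and 5% of the sample total. These defaults are this package's
convention for a usable binary call (no canonical rule exists); both are
configurable, and the acceptance checks use them unchanged.

## De novo extraction

For each candidate rank $k$, each of `n_bootstraps` multinomial resamples
of the cohort catalogue matrix (per-sample totals preserved exactly) is
factorised by NMF under the Frobenius objective with the classical
multiplicative updates — monotone non-increasing per iteration,
deterministic given the seed, random-uniform initialisation scaled to the
data. The pooled $k \times$ `n_bootstraps` signature draws are clustered
by agglomerative hierarchical clustering under cosine distance with
average linkage, cut at $k$; consensus signatures are normalised cluster
centroids.

Model selection balances reproducibility against validity:

* **Stability** is the mean silhouette width of the draws under cosine
  distance (1 at $k = 1$ by construction). A solution qualifies when
  stability is at least `stability_floor` (default 0.8).
* **Distinctness**: a solution with two centroids at cosine similarity
  above 0.85 has split one process across clusters and is rejected.
* **Bootstrap support**: every cluster must contain draws from at least
  half the bootstraps. Without this rule, spurious components at
  $k$ above the true rank form singleton clusters which barely depress
  mean silhouette, and the largest-$k$ rule overestimates the rank; a
  "signature" reproduced by one resample is a noise component, not a
  mutational process.

The chosen $k$ is the largest qualifying candidate — the minimal set of
stable, distinct, reproducible signatures that explains the catalogues.
If nothing qualifies the most stable $k$ is returned with a warning. All
three thresholds are exposed as arguments.

## Microhomology deletions

For a deletion with removed sequence $s$ (length $L$), breakpoint
microhomology is $\max(p, q)$: $p$ the longest prefix of $s$ recurring as
a prefix of the downstream flank, $q$ the longest suffix of $s$ recurring
as a suffix of the upstream flank. A full-length match ($p = L$ or
$q = L$) means the deletion removed one unit of an adjacent tandem repeat;
such events are polymerase-slippage territory, flagged `at_repeat`,
capped at $L - 1$, and excluded from the microhomology-deletion count so
that replication slippage does not inflate the end-joining scar class. A
deletion counts toward the per-sample burden when it is strictly longer
than 3 bp, has microhomology of at least 1 bp (no canonical minimum
exists; the threshold is configurable and monotonicity in it is tested),
and is not repeat-mediated. Insertions are annotated through but never
counted. The statistic is reverse-complement invariant with the flanks
swapped, and each record's classification depends only on its own locus.

## Association statistics

Fisher's exact test on 2×2 tables uses the probability-mass two-sided
convention — the sum of hypergeometric probabilities of all tables with
the observed margins no more probable than the observed table. This
convention reproduces the printed p-values of the published gastric
histology tables bundled in `gastric_histology_tables()` (0.0003, 0.0058,
0.0015) at their printed precision, so no alternative convention is
computed. Zero-margin tables return p = 1.

The Mann–Whitney U statistic is computed from midrank rank sums. The
two-sided p-value is exact — enumeration of all $\binom{n+m}{n}$ group
assignments, counting those whose U deviates from its null mean at least
as much as observed — when requested or, in `auto` mode, when
$n + m \le 16$ without ties; otherwise the normal approximation with tie
correction and continuity correction is used. The enumeration handles
ties via midranks; the approximation thresholds are this package's
convention, and the exact path is what the acceptance checks exercise.

Report formatting follows the source tables: p ≥ 0.001 to four decimals,
smaller values in scientific notation with three significant digits.

## The synthetic cohort

The generators emulate the statistical structure the analysis assumes,
not sequencing data:

* **Signatures** are Dirichlet draws (concentration 0.5, giving the spiky
  profiles real signatures have) grown one at a time under a minimum
  pairwise cosine-distance constraint (default 0.7).
* **Catalogues**: per-sample totals are log-normal (default
  $\mu = \log 8000$, $\sigma = 0.5$, echoing the order-of-magnitude burden
  spread of whole-genome cohorts); the first signature plays the role of
  signature 3 and is active in 12% of samples (the whole-genome gastric
  prevalence); other signatures are each inactive with probability 0.3;
  active weights are Dirichlet with every active weight at least 0.1, so
  planted activity is detectable in principle; channel counts are
  multinomial (or Poisson) around the mixed density.
* **Indels**: one synthetic contig per sample carries deletions with
  planted prefix-copy microhomology (1–3 bp, deletion 4–12 bp, never
  repeat-mediated, breakpoints forced to mismatch beyond the planted
  length) at Poisson rate 170 × 4 in signature-3-positive samples and 170
  otherwise — the four-fold contrast mirroring the published 715-vs-172
  median split — plus equally many filler deletions with zero breakpoint
  microhomology. The generator must control flanking sequence to plant
  microhomology, so it constructs and returns its own reference.
* **Annotations**: a binary growth-pattern annotation whose log-odds
  shift by `log(15)` in positive samples, over a 7% baseline — the
  regime of the published histology table.

What passing tests on these cohorts shows is parameter recovery under the
model's own assumptions: well-separated signatures, independent samples,
multinomial noise, exactly planted microhomology. Real cohorts add
caller-specific artifact structure, correlated signatures (signature 3 is
notoriously flat and confusable with signature 5/8 territory), copy-number
variation in mutation rate along the genome, and alignment ambiguity at
indel breakpoints — none of which the generators emulate. Recovery
accuracy reported here is therefore an upper bound on real-data behaviour.

## Numerical choices and problem sizes

All stochastic routines take explicit integer seeds and restore the
caller's RNG state; extraction is reproducible bit-for-bit given (seed,
k_range, n_bootstraps). NMF stops at a relative objective decrease below
`1e-8` or 2000 iterations, with a machine-epsilon guard in the update
denominators. The refitting solver iterates to a relative objective change
below `1e-12` (checked every 50 iterations, cap 5000) before the KKT
polish. The test and acceptance workloads use cohorts of 50–100 samples
at 5,000–10,000 mutations per sample, 20 bootstraps over ranks 1–5, and
100-seed replication for the indel power analysis — sizes at which every
stage's behaviour is already asymptotic while the full suite runs in
about two minutes.

## Known limitations

* Signature subsets are selected once per sample before fitting; there is
  no post-fit pruning of signatures whose removal would leave the
  reconstruction unchanged, so collinear registry entries can share
  exposure (the minimum-norm tie-break makes this deterministic).
* The 192-channel transcriptional-strand-resolved representation, indel
  (ID-83) and dinucleotide catalogues, and structural-variant signatures
  are out of scope; SV counts are consumed as annotations.
* The microhomology scan assumes left-aligned indel calls and exact
  breakpoints; it does not re-align.
* No confidence intervals on exposures and no multiple-testing
  correction across association tests (none is applied in the source
  analyses this package follows).
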