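# isomix

Structural classification, quality control, and mixture-model patient
stratification for full-length transcript isoform catalogs.

Long-read (PacBio/ONT-style) sequencing yields full-length transcript
models, but raw catalogs mix genuine novel isoforms with library
artifacts, and the downstream question — *which splicing changes are
tumor-specific and clinically relevant?* — needs statistics that respect
how splicing varies across patient subpopulations. `isomix` implements
that workflow end-to-end for transcriptomics researchers:

* **Structural classification** of each query isoform against a
  reference annotation by its splice-junction chain: full-splice match
  (FSM), incomplete-splice match (ISM), novel-in-catalog (NIC),
  novel-not-in-catalog (NNC), antisense, intergenic, fusion, genic.
* **Quality filters** for poly(A) intrapriming (3' ends > 100 bp from an
  annotated TTS with > 80% downstream adenine and no poly(A)-site
  support), RT-switching direct repeats, noncanonical splice sites,
  short-read junction support (≥ 5 reads or ≥ 3 long-read samples), and
  intron retention — combined under a category-dependent keep policy
  (FSM is never filtered).
* **Protein-level consequences**: best-ORF selection, Needleman–Wunsch
  global identity to a reference proteome, domain/transmembrane/
  localization deltas, the 55-nt NMD rule, peptide-support classes, and
  Ribo-seq translation cutoffs calibrated on housekeeping genes.
* **AS events and PSI**: the seven local event types (SE, MX, A5SS,
  A3SS, RI, AF, AL) with per-sample percent-spliced-in from transcript
  TPMs.
* **GMM stratification**: per event, a 1–3 component Gaussian mixture
  over tumor *and* control PSI selected by BIC; subpopulations with
  > 90% tumor purity, ≥ 50 patients and |ΔPSI| ≥ 20 percentage points
  versus controls are tumor-specific, and subpopulations of ≥ 30
  patients are compared by global + pairwise log-rank tests
  (Benjamini–Hochberg, adjusted P < 0.01) for survival association.

For an event with inclusion-form transcript set *I* and exclusion set
*E*, `PSI_s = Σ_{t∈I} TPM_ts / Σ_{t∈I∪E} TPM_ts` in sample *s*; the
mixture model is `PSI_s ~ Σ_k π_k N(μ_k, σ_k²)` with
`BIC = −2·loglik + (3k−1)·ln n`.

A synthetic-data module generates toy genomes, annotations, isoform
catalogs and tumor/control cohorts with planted ground truth, so the
whole pipeline is testable without any external data.

## Worked example

```r
library(isomix)

spec <- fixture_spec()                       # planted study conditions
ann  <- make_genome_and_annotation(spec)
fx   <- plant_query_isoforms(spec, ann)

cls <- classify_catalog(fx$queries, fx$ref_index)
cls$summary
#>        FSM        ISM        NIC        NNC  ANTISENSE INTERGENIC
#>         10         15         25         15          5          5
#>     FUSION      GENIC
#>          0          0
```

The 75 planted queries are recovered in exactly their planted
categories (10 FSM copies, 10 ISM truncations + 5 ISM intrapriming
artifacts, 10 NIC novel combinations + 15 NIC-type artifacts, 10 NNC
splice-site shifts + 5 noncanonical artifacts, 5 antisense,
5 intergenic).

```r
co  <- simulate_cohort(spec)                 # 200 tumors, 100 controls
res <- stratify_cohort(co$psi, co$samples, stratify_config(seed = 11))
res$summary$n_tumor_specific_events
#> [1] 5
res$summary$survival_events
#> [1] "pe01;SE:chrS:1500-1900:+"
```

All 5 planted tumor-specific events (among 50 nulls) are recovered with
no false positives, and the planted survival-associated subpopulation
(hazard ratio 3) is flagged; its pairwise log-rank adjusted p-value is
reported in `res$survival`. Fitting one event looks like:

```r
f <- res$fits[["pe01;SE:chrS:1500-1900:+"]]
f
#> GmmFit: k = 2 (BIC 1=-38.2 2=-579.9 3=-568.8), n = 300
#>   comp 1: weight 0.267 mean 0.205 sd 0.041
#>   comp 2: weight 0.733 mean 0.697 sd 0.052
```

Component 1 is the planted tumor-only subpopulation (80 of 200 tumors at
PSI ≈ 0.2 against a 0.7 background): purity 1.0, ΔPSI = −48.5 percentage
points.

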