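---
title: "Methods: isoform classification, quality control, and mixture-model stratification"
author: "isomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform classification, quality control, and mixture-model stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomix)
```

# Overview

`isomix` analyses catalogs of full-length (long-read) transcript isoforms
against a reference annotation. The pipeline has four stages:

1. **Structural classification** of each query isoform by its
   splice-junction chain (FSM, ISM, NIC, NNC, plus antisense, intergenic,
   fusion and genic calls).
2. **Quality control** against the artifacts that long-read cDNA
   protocols produce: poly(A) intrapriming, reverse-transcriptase
   template switching, noncanonical junctions, unsupported junctions, and
   intron retention — applied with a category-dependent keep policy.
3. **Protein-level consequence annotation**: ORF selection, global
   identity to a reference proteome, domain / transmembrane /
   localization deltas, nonsense-mediated decay (NMD) prediction, peptide
   support classes, and ribosome-occupancy translation calls.
4. **Alternative-splicing quantification and patient stratification**:
   local AS events with per-sample percent-spliced-in (PSI), then a
   per-event univariate Gaussian mixture over tumors and controls that
   discovers tumor-specific subpopulations and tests them for survival
   differences.

Everything is testable offline through a synthetic-data generator that
plants known structural categories, artifacts and cohort effects.

# Coordinate conventions

Internally all intervals are 0-based, half-open `[start, end)` on a named
chromosome with an explicit strand. GTF I/O (1-based, inclusive) and BED
I/O convert at the boundary. A splice junction is identified by `(chrom,
donor_pos, acceptor_pos, strand)` where `[donor_pos, acceptor_pos)` is
the intron; junction identity is exact (`±0` bp), because the
junction-chain categories presume exact splice-site coordinates. An
n-exon transcript has exactly n−1 junctions.

# Structural classification

A multi-exon query is **FSM** when its ordered junction chain equals a
reference transcript's full chain, and **ISM** when it equals a
*consecutive* sub-chain (a non-consecutive subset is NIC — it implies a
novel junction combination). Otherwise the query is assigned to the
overlapping same-strand gene with maximal exonic overlap: **NIC** when
every donor and acceptor is annotated for that gene but the chain is
novel, **NNC** when at least one splice site is unannotated. Queries
whose junctions bridge two or more same-strand genes with mutually
disjoint bodies are **FUSION**; queries overlapping genes only on the
opposite strand are **ANTISENSE**, and queries with no gene-body overlap
**INTERGENIC**.

Mono-exon rules are necessarily heuristic (junction chains are empty):
FSM requires a mono-exon reference transcript with both ends within 50 bp
(configurable); containment within an annotated exon gives ISM; a
same-strand overlap otherwise gives GENIC. Transcript *ends* are ignored
for multi-exon matching — only junction chains are compared — because end
variability in long-read data is dominated by library artifacts handled
separately by QC.

Donor/acceptor novelty is evaluated against the assigned gene's site sets
rather than genome-wide (configurable), so a site borrowed from a distant
gene does not mask novelty.

# Quality filters

* **Intrapriming** (unreliable 3' end): oligo-dT priming on genomic
  A-stretches. A 3' end is unreliable only when all three hold: distance
  to the nearest same-strand annotated TTS > 100 bp; adenine fraction of
  the 20 nt immediately downstream (read on the transcript strand)
  strictly > 80%; and no poly(A)-site catalog interval within ±10 bp.
  The 20-nt window and the ±10 bp slack are the package's defaults where
  only the 100 bp / 80% thresholds are canonical.
* **Junction support**: a transcript passes when all junctions have ≥ 5
  short reads of coverage or it was seen in ≥ 3 long-read samples.
  The sample-count reading is the default; a full-length-read-count mode
  is available because the two readings are not distinguishable from the
  stated rule.
* **Canonical splice sites**: strand-corrected intron dinucleotides in
  {GT–AG, GC–AG, AT–AC}.
* **RT switching**: a junction is flagged when the two 2k-nt windows
  spanning the exon/intron boundary at donor and acceptor share an exact
  direct repeat of length ≥ k (default k = 8). The direct-repeat rule is
  a parameterized reconstruction — detection is monotone in k.
* **Intron retention** class codes, natively implemented: `i` (query
  inside a reference intron), `m` (≥ 1 reference intron fully inside a
  query exon, all other introns matched — all-intron retention), `n`
  (full retention with a partially compatible chain), `y` (retention
  without any shared junction). A query exon that merely extends a few
  bases into an intron is *not* retention; this matters because 4-bp
  splice-site shifts (NNC-type novelty) must not be mistaken for
  retention.

The keep policy is category-dependent: **FSM — no filtering (always
kept); ISM — unreliable 3' ends dropped; NIC — unreliable 3' ends, read
coverage, intron retention; NNC — those plus RT-switch and canonical
splice sites; all other categories (antisense, intergenic, fusion,
genic) — coverage, retention, RT-switch, canonical.** GENIC is treated
under the "other" policy, which names antisense/intergenic/fusion
explicitly but leaves mono-exon genic isoforms unaddressed.

Orthogonal end validation is separate from filtering: a TSS is supported
by a CAGE or ATAC peak within 50 bp; a TTS by a 3'-seq peak within 50 bp
or a poly(A) motif (AATAAA/ATTAAA) in the final 50 nt.

# ORF annotation

Candidate ORFs are enumerated on the sense transcript sequence in the
three forward frames: per stop-to-stop region the 5'-most ATG-initiated
ORF, plus stop-terminated 5'-incomplete ORFs open at the transcript start
and ATG-initiated 3'-incomplete ORFs at the end, all ≥ 100 aa by default.
The single best ORF is chosen by: significant homology to the reference
proteome (e ≤ 1e−5), then bitscore, then domain conservation, then
length, then 5'-most start. Homology and domain evidence arrive as
precomputed tables (the package does not run a search engine).

Global identity uses true Needleman–Wunsch (BLOSUM62, gap open 10,
extension 0.5; identity = matches / alignment length). ORFs under 99%
identity to their best reference hit are *novel proteins*; domain and
transmembrane deltas are set/count differences and localization switches
are label differences, all against precomputed annotation tables.

**NMD rule**: a transcript is NMD-sensitive when the stop codon (first
base, transcript coordinates) lies in a non-terminal exon more than 55 nt
upstream of the last splice junction — the classic EJC rule with a strict
inequality, so exactly 55 nt is *not* NMD. ORFs without stop codons and
mono-exon transcripts are never NMD-sensitive.

**Peptide classes**: exact substring matching of a peptide against the
long-read ORF database and the reference proteome yields `unique_PacBio`,
`non_unique_PacBio`, `nonunique_PacBio_UniProt`, or `multigene` (matches
spanning more than one gene take precedence). Peptides matching only the
reference proteome fall outside the four classes and return `NA`.

**Translation cutoffs**: from Ribo-seq periodicity (f1) and uniformity
(pme) metrics, the largest `(f1, pme)` cutoff pair — maximizing the sum
over the grid of observed housekeeping values, ties broken toward larger
f1 — such that ≥ 80% of single-ORF housekeeping genes with ≥ 10 reads
classify as translated. "Largest pair" is not unique in two dimensions;
the sum-maximizing rule makes the choice canonical and reproducible.

# AS events and PSI

Seven local event types are extracted from exon chains per gene: SE, MX,
A5SS, A3SS, RI, AF, AL. Inclusion-form conventions: the exon-containing
form (SE), the intron-retaining form (RI), the extended-exon form
(A5/A3), the genomically 5'-most exon (MX), and the distal first/last
exon (AF/AL). Two thresholds govern variant merging: first/last exons
overlapping by more than 250 bp, or local boundaries within 10 bp, are
one variant rather than an alternative — mirroring the overlap-threshold
semantics of transcriptome-based event generators. A5/A3 variants must be
alternative boundaries of *overlapping* exons, and AF/AL variants must
differ at their distal boundary, so splice-site variation is never
double-reported as an end event.

PSI is the inclusion share of abundance,
`PSI = Σ TPM(inclusion) / (Σ TPM(inclusion) + Σ TPM(exclusion))`,
masked (`NA`) when the denominator falls below 1 TPM by default
(configurable; 0 masks only zero totals). PSI is scale-invariant in the
per-sample TPM normalization, and a binary event and its mirrored twin
sum to exactly 1.

# GMM stratification

For each event, the non-missing PSI values of tumors *and* controls are
fitted with univariate Gaussian mixtures for k = 1, 2, 3 by EM
(unequal variances; means initialized at the (1..k)/(k+1) quantiles,
equal weights, pooled variance; 5 restarts with jittered means;
tolerance 1e−6; ≤ 500 iterations; variance floor 1e−4 against
boundary-piled PSI). BIC = −2·loglik + (3k−1)·ln n selects k, and
samples are hard-assigned by maximum posterior. Fitting on raw PSI in
[0, 1] keeps fidelity with the mixture model as applied in practice; a
logit-transform mode would change boundary behavior and is deliberately
not the default.

A component is a **tumor-specific subpopulation** when its tumor purity
exceeds 90%, it contains at least 50 tumors, and its ΔPSI — the mean PSI
of the component's tumors minus the mean PSI of *all* controls, in
percentage points — is at least 20 in magnitude, with a two-sided
Wilcoxon rank-sum test against the controls below 0.05 (the Wilcoxon
gate is switchable, since the size/purity/ΔPSI gates already define the
phenotype and the rank test mostly guards small-n edge cases). The exact
rank-sum distribution is used when both groups have ≤ 25 observations
and no ties; otherwise the tie-corrected normal approximation without
continuity correction, so both paths estimate the same quantity.

Events with a tumor-specific subpopulation proceed to survival analysis:
components with ≥ 30 tumor patients are compared by a global log-rank
test and all pairwise log-rank tests with Benjamini–Hochberg adjustment
within the event; an event is survival-associated when the global p and
at least one adjusted pairwise p are below 0.01. The global test uses
only eligible (n ≥ 30) components, matching the components that are
actually compared. Kaplan–Meier estimation and the log-rank statistic
(hypergeometric observed-minus-expected with the full covariance matrix)
are implemented natively and agree with the `survival` package to
better than 1e−8 in the test suite.

# Synthetic data: what it emulates, and what it does not

The generator builds a toy genome (20 genes of 5–8 exons on 2
chromosomes, both strands, canonical GT–AG introns by construction), a
reference annotation with a skip-one-exon second transcript per gene,
and a query catalog with planted categories (FSM copies, ISM
truncations, NIC novel combinations, NNC 4-bp splice-site shifts,
antisense, intergenic) and planted artifacts (A-rich 3' genomic
extensions placed > 100 bp past the TTS, exact 8-mer direct repeats at
novel junctions, an under-covered junction, merged-exon intron
retention, non-GT dinucleotides). A cleanup pass removes accidental
direct repeats at non-planted junctions so artifact truth tables are
exact by construction.

The simulated cohort (200 tumors, 100 controls by default) plants 5
tumor-specific events — a tumor-only subpopulation of 40% of tumors at
PSI ~ N(0.2, 0.05) against a N(0.7, 0.05) background — among 50 null
events drawn from single Gaussians (sd 0.1, means uniform in
[0.3, 0.7]). PSI is sampled by rejection from truncated Gaussians so
planted moments are honest near the [0, 1] boundary; truth tables record
realized means. Survival is exponential (base hazard 2e−3/day, chosen to
give a realistic event fraction over a multi-year follow-up window) with
hazard ratio 3 for one planted subpopulation, and independent
exponential censoring at 0.3 × the base hazard (≈ 25% censoring). These
are the study conditions for all end-to-end tests; the problem sizes
(500-observation mixtures, 100 seeds, 55-event cohorts, 100 null
replicates) were chosen once as the smallest scales at which the
selection-consistency and power statements are stable.

Passing on these fixtures demonstrates correctness of the algorithms
under their stated assumptions, not performance on real data: the
generator has no alignment noise, no degraded-RNA length biases, no
expression-dependent PSI estimation error, no batch structure, and
Gaussian (not empirically bimodal-at-the-boundary) PSI. Real cohorts
also violate the mixture's independence-across-events assumption.

# Numerical choices and degenerate inputs

* EM variance floor 1e−4 (sd 0.01) prevents likelihood spikes on
  constant PSI; a constant vector fits k = 1 at the floor.
* All tie-breaks are lexicographic or 5'-most and documented at the
  operation (FSM/ISM matched transcript, best-ORF start, clustering
  sample order), so every pipeline stage is order-independent.
* Jaccard of two empty sets is defined as 1 (indistinguishable samples);
  hierarchical clustering uses average linkage on 1 − Jaccard by
  default (the linkage is not canonical, hence configurable).
* The log-rank covariance matrix is inverted with a pseudo-inverse
  fallback for degenerate designs; identical groups give chisq 0, p 1.
* Peak-index distances follow the interval-gap convention of the
  underlying range machinery (bases strictly between query and peak).
* Events with fewer than 10 non-missing PSI values are skipped and
  reported, not errored.

# Known limitations

* Mono-exon classification rules and the RT-switch direct-repeat rule
  are reconstructions of common practice; both are parameterized.
* Intron-retention codes are native reimplementations of the
  transcript-comparison class codes and are validated against
  hand-constructed fixtures, not against an external tool run.
* The event extractor targets the seven local event types only; complex
  nested events are represented by their local projections.
* Survival analysis is label-based (log-rank over subpopulations);
  covariate adjustment (Cox models) is out of scope.
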