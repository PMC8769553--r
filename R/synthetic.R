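#' Fixture specification for the synthetic-data generator
#'
#' Collects every knob of the toy-data generator in one list: genome and
#' annotation geometry, planted structural-category counts, planted
#' artifact counts, and the simulated cohort layout. Every output is
#' bit-reproducible from (`spec`, `seed`).
#'
#' @param seed Base RNG seed.
#' @param n_genes Number of genes (split over `n_chroms` chromosomes,
#'   alternating strands).
#' @param exons_per_gene Integer range of exon counts (minimum 5, so every
#'   novel-combination plant has room).
#' @param exon_len,intron_len,gene_gap Length ranges in bp.
#' @param n_chroms Number of chromosomes.
#' @param categories Named counts of planted query isoforms per structural
#'   category (FSM, ISM, NIC, NNC, ANTISENSE, INTERGENIC).
#' @param artifacts Named counts of planted artifact isoforms
#'   (intrapriming, rt_switch, low_coverage, intron_retention,
#'   noncanonical).
#' @param cohort Cohort layout for [simulate_cohort()]: tumor/control
#'   sizes, planted and null event counts, subpopulation weight, PSI
#'   component means/sds, survival hazards and the censoring fraction.
#' @return A `FixtureSpec` list.
#' @export
fixture_spec <- function(seed = 42L, n_genes = 20L,
                         exons_per_gene = c(5L, 8L),
                         exon_len = c(100L, 250L),
                         intron_len = c(250L, 600L),
                         gene_gap = c(700L, 1200L), n_chroms = 2L,
                         categories = c(FSM = 10L, ISM = 10L, NIC = 10L,
                                        NNC = 10L, ANTISENSE = 5L,
                                        INTERGENIC = 5L),
                         artifacts = c(intrapriming = 5L, rt_switch = 5L,
                                       low_coverage = 5L,
                                       intron_retention = 5L,
                                       noncanonical = 5L),
                         cohort = list(n_tumor = 200L, n_control = 100L,
                                       n_planted = 5L, n_null = 50L,
                                       subpop_weight = 0.4,
                                       tumor_psi = c(mean = 0.2, sd = 0.05),
                                       background_psi = c(mean = 0.7,
                                                          sd = 0.05),
                                       null_sd = 0.1,
                                       base_hazard = 0.002,
                                       hazard_ratio = 3,
                                       censor_rate_frac = 0.3,
                                       survival_event = 1L)) {
  stopifnot(exons_per_gene[1L] >= 5L, all(categories >= 0L),
            all(artifacts >= 0L))
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_len = as.integer(exon_len),
                 intron_len = as.integer(intron_len),
                 gene_gap = as.integer(gene_gap),
                 n_chroms = as.integer(n_chroms),
                 categories = categories, artifacts = artifacts,
                 cohort = cohort),
            class = "FixtureSpec")
}

#' Generate a toy genome and reference annotation
#'
#' Genes of 5-8 exons are laid out sequentially on each chromosome with
#' alternating strands and non-overlapping bodies. Every intron carries
#' canonical GT..AG dinucleotides (strand-aware) by construction. Each
#' gene gets a full-chain transcript (`<gene>.t1`) and, when it has at
#' least 4 exons, a skip-one-exon variant (`<gene>.t2`), so annotated
#' donors/acceptors support novel-combination planting and event
#' extraction.
#'
#' @param spec A `FixtureSpec`.
#' @return A `SyntheticAnnotation` list: `chrom_seq` (named character
#'   vector of chromosome sequences), `transcripts` (reference
#'   `TranscriptModel`s), `genes` (layout table), `spec`.
#' @export
make_genome_and_annotation <- function(spec) {
  set.seed(spec$seed)
  runif_int <- function(n, r) sample(seq(r[1L], r[2L]), n, replace = TRUE)
  genes <- data.frame(gene_id = sprintf("g%02d", seq_len(spec$n_genes)),
                      chrom = sprintf("chr%d",
                                      rep(seq_len(spec$n_chroms),
                                          length.out = spec$n_genes)),
                      strand = rep(c("+", "-"),
                                   length.out = spec$n_genes),
                      n_exons = runif_int(spec$n_genes, spec$exons_per_gene),
                      stringsAsFactors = FALSE)
  transcripts <- list()
  chrom_len <- stats::setNames(rep(1000L, spec$n_chroms),
                               sprintf("chr%d", seq_len(spec$n_chroms)))
  genes$start <- NA_integer_; genes$end <- NA_integer_
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    pos <- chrom_len[[ch]] + runif_int(1L, spec$gene_gap)
    ne <- genes$n_exons[i]
    elen <- runif_int(ne, spec$exon_len)
    ilen <- runif_int(max(ne - 1L, 0L), spec$intron_len)
    starts <- pos + cumsum(c(0L, elen[-ne] + ilen))
    ends <- starts + elen
    genes$start[i] <- starts[1L]; genes$end[i] <- ends[ne]
    chrom_len[[ch]] <- ends[ne]
    tid <- paste0(genes$gene_id[i], ".t1")
    transcripts[[tid]] <- transcript_model(tid, genes$gene_id[i], ch,
                                           genes$strand[i],
                                           cbind(starts, ends))
    if (ne >= 4L) {
      tid2 <- paste0(genes$gene_id[i], ".t2")
      keep <- setdiff(seq_len(ne), 2L)   # skip genomic exon 2
      transcripts[[tid2]] <- transcript_model(tid2, genes$gene_id[i], ch,
                                              genes$strand[i],
                                              cbind(starts[keep],
                                                    ends[keep]))
    }
  }
  chrom_seq <- vapply(names(chrom_len), function(ch) {
    paste(sample(c("A", "C", "G", "T"), chrom_len[[ch]] + 1500L,
                 replace = TRUE), collapse = "")
  }, "")
  # canonical dinucleotides at every annotated intron
  for (tx in transcripts) {
    j <- junctions(tx)
    for (r in seq_len(nrow(j))) {
      chrom_seq[tx$chrom] <- .plant_dinucs(chrom_seq[[tx$chrom]],
                                           j[r, 1L], j[r, 2L], tx$strand)
    }
  }
  structure(list(chrom_seq = chrom_seq, transcripts = transcripts,
                 genes = genes, spec = spec),
            class = "SyntheticAnnotation")
}

# write canonical splice dinucleotides for intron [d, a) on `strand`
.plant_dinucs <- function(s, d, a, strand) {
  if (strand == "+") {
    substr(s, d + 1L, d + 2L) <- "GT"
    substr(s, a - 1L, a) <- "AG"
  } else {
    substr(s, d + 1L, d + 2L) <- "CT"
    substr(s, a - 1L, a) <- "AC"
  }
  s
}

.put <- function(s, pos0, text) {        # overwrite at 0-based pos0
  substr(s, pos0 + 1L, pos0 + nchar(text)) <- text
  s
}

#' Plant a labeled query-isoform catalog with artifacts
#'
#' Generates query transcripts with known structural categories (FSM
#' copies, ISM truncations, NIC novel combinations of annotated sites, NNC
#' shifted splice sites, antisense and intergenic isoforms) and known
#' artifacts (A-rich 3' genomic extensions for intrapriming, planted
#' direct repeats at novel junctions for RT-switching, an under-covered
#' novel junction, retained introns, noncanonical splice sites). The
#' genome is edited where an artifact requires it; a cleanup pass then
#' removes any *accidental* direct repeat at a non-planted junction so the
#' RT-switch truth table is exact by construction.
#'
#' @param spec A `FixtureSpec`.
#' @param ann A `SyntheticAnnotation` from [make_genome_and_annotation()].
#' @return A `SyntheticCatalog` list: `queries` (list of
#'   `TranscriptModel`), `truth` (`data.frame`: transcript_id, gene_id,
#'   category, artifact), `genome` (`DNAStringSet`), `reference`
#'   (transcripts), `ref_index`, `coverage` (junction read counts),
#'   `lr_counts` (per-query long-read sample counts), `polyA_db`, `cage`,
#'   `threeprime` (`PeakIndex`es).
#' @export
plant_query_isoforms <- function(spec, ann) {
  set.seed(spec$seed + 1L)
  seqs <- ann$chrom_seq
  ref <- ann$transcripts
  genes <- ann$genes
  queries <- list(); truth <- NULL
  qn <- 0L
  low_cov_keys <- character(0)
  rt_keys <- character(0)
  nid <- function() { qn <<- qn + 1L; sprintf("q%04d", qn) }
  add <- function(tx, category, artifact = "none") {
    queries[[tx$transcript_id]] <<- tx
    truth <<- rbind(truth, data.frame(
      transcript_id = tx$transcript_id, gene_id = tx$gene_id,
      category = category, artifact = artifact, stringsAsFactors = FALSE))
  }
  gene_cycle <- function(k, n) genes$gene_id[(seq_len(n) + k - 1L) %%
                                               nrow(genes) + 1L]
  full_tx <- function(g) ref[[paste0(g, ".t1")]]

  # --- structural categories -------------------------------------------
  for (g in gene_cycle(0L, spec$categories[["FSM"]])) {
    t <- full_tx(g)
    add(transcript_model(nid(), "", t$chrom, t$strand, t$exons), "FSM")
  }
  for (g in gene_cycle(3L, spec$categories[["ISM"]])) {
    t <- full_tx(g)
    add(transcript_model(nid(), "", t$chrom, t$strand,
                         t$exons[-1L, , drop = FALSE]), "ISM")
  }
  for (g in gene_cycle(6L, spec$categories[["NIC"]])) {
    t <- full_tx(g)                      # skip genomic exons 3 and 4
    keep <- setdiff(seq_len(nrow(t$exons)), c(3L, 4L))
    add(transcript_model(nid(), "", t$chrom, t$strand,
                         t$exons[keep, , drop = FALSE]), "NIC")
  }
  for (g in gene_cycle(9L, spec$categories[["NNC"]])) {
    t <- full_tx(g)                      # shift a boundary of intron 2
    ex <- t$exons
    if (t$strand == "+") {
      d <- ex[2L, 2L]; ex[2L, 2L] <- d + 4L
      seqs[t$chrom] <- .put(seqs[[t$chrom]], d + 4L, "GT")
    } else {
      a <- ex[3L, 1L]; ex[3L, 1L] <- a - 4L
      seqs[t$chrom] <- .put(seqs[[t$chrom]], a - 6L, "AC")
    }
    add(transcript_model(nid(), "", t$chrom, t$strand, ex), "NNC")
  }
  for (g in gene_cycle(0L, spec$categories[["ANTISENSE"]])) {
    t <- full_tx(g)
    opp <- if (t$strand == "+") "-" else "+"
    add(transcript_model(nid(), "", t$chrom, opp,
                         cbind(t$exons[2L, 1L] - 20L,
                               t$exons[2L, 2L] + 20L)), "ANTISENSE")
  }
  for (k in seq_len(spec$categories[["INTERGENIC"]])) {
    gi <- (k - 1L) %% nrow(genes) + 1L
    ch <- genes$chrom[gi]
    s <- genes$end[gi] + 250L
    add(transcript_model(nid(), "", ch, "+", cbind(s, s + 180L)),
        "INTERGENIC")
  }

  # --- artifacts --------------------------------------------------------
  for (g in gene_cycle(1L, spec$artifacts[["intrapriming"]])) {
    t <- full_tx(g); ex <- t$exons; n <- nrow(ex)
    if (t$strand == "+") {               # drop 3'-terminal exon, extend
      ex <- ex[-n, , drop = FALSE]
      newend <- ex[n - 1L, 2L] + 150L
      ex[n - 1L, 2L] <- newend
      seqs[t$chrom] <- .put(seqs[[t$chrom]], newend,
                            paste0(strrep("A", 18L), "GC"))
    } else {
      ex <- ex[-1L, , drop = FALSE]
      newstart <- ex[1L, 1L] - 150L
      ex[1L, 1L] <- newstart
      seqs[t$chrom] <- .put(seqs[[t$chrom]], newstart - 20L,
                            paste0("GC", strrep("T", 18L)))
    }
    add(transcript_model(nid(), "", t$chrom, t$strand, ex), "ISM",
        "intrapriming")
  }
  for (g in gene_cycle(4L, spec$artifacts[["rt_switch"]])) {
    t <- full_tx(g)                      # skip genomic exons 2 and 3
    keep <- setdiff(seq_len(nrow(t$exons)), c(2L, 3L))
    d <- t$exons[1L, 2L]; a <- t$exons[4L, 1L]
    rep8 <- substr(seqs[[t$chrom]], d - 2L, d + 5L)   # spans the GT
    seqs[t$chrom] <- .put(seqs[[t$chrom]], a, rep8)
    rt_keys <- c(rt_keys, paste(t$chrom, d, a, t$strand, sep = ":"))
    add(transcript_model(nid(), "", t$chrom, t$strand,
                         t$exons[keep, , drop = FALSE]), "NIC",
        "rt_switch")
  }
  for (g in gene_cycle(7L, spec$artifacts[["low_coverage"]])) {
    t <- full_tx(g)                      # skip genomic exons 2..4
    keep <- setdiff(seq_len(nrow(t$exons)), 2:4)
    d <- t$exons[1L, 2L]; a <- t$exons[5L, 1L]
    low_cov_keys <- c(low_cov_keys, paste(t$chrom, d, a, t$strand,
                                          sep = ":"))
    add(transcript_model(nid(), "", t$chrom, t$strand,
                         t$exons[keep, , drop = FALSE]), "NIC",
        "low_coverage")
  }
  for (g in gene_cycle(10L, spec$artifacts[["intron_retention"]])) {
    t <- full_tx(g); ex <- t$exons       # merge genomic exons 2 and 3
    merged <- rbind(ex[1L, ], c(ex[2L, 1L], ex[3L, 2L]),
                    ex[-(1:3), , drop = FALSE])
    add(transcript_model(nid(), "", t$chrom, t$strand, merged), "NIC",
        "intron_retention")
  }
  for (g in gene_cycle(13L, spec$artifacts[["noncanonical"]])) {
    t <- full_tx(g); ex <- t$exons       # shift intron-3 boundary, no GT
    if (t$strand == "+") {
      d <- ex[3L, 2L]; ex[3L, 2L] <- d + 4L
      seqs[t$chrom] <- .put(seqs[[t$chrom]], d + 4L, "CC")
    } else {
      a <- ex[4L, 1L]; ex[4L, 1L] <- a - 4L
      seqs[t$chrom] <- .put(seqs[[t$chrom]], a - 6L, "CC")
    }
    add(transcript_model(nid(), "", t$chrom, t$strand, ex), "NNC",
        "noncanonical")
  }

  # --- RT-switch cleanup: no accidental repeats off the planted set ----
  all_tx <- c(ref, queries)
  protect <- list()
  mark <- function(ch, from, to) {       # 0-based [from, to)
    protect[[ch]] <<- c(protect[[ch]], seq(from, to - 1L))
  }
  for (t in all_tx) {
    j <- junctions(t)
    for (r in seq_len(nrow(j))) {
      mark(t$chrom, j[r, 1L], j[r, 1L] + 2L)
      mark(t$chrom, j[r, 2L] - 2L, j[r, 2L])
    }
  }
  for (key in rt_keys) {
    p <- strsplit(key, ":")[[1L]]
    d <- as.integer(p[2L]); a <- as.integer(p[3L])
    mark(p[1L], d - 3L, d + 5L)
    mark(p[1L], a, a + 8L)
  }
  rebuild <- function() {
    g <- Biostrings::DNAStringSet(seqs)
    names(g) <- names(seqs)
    g
  }
  genome <- rebuild()
  k <- 8L
  for (t in all_tx) {
    j <- junctions(t)
    keys <- junction_keys(t)
    for (r in seq_len(nrow(j))) {
      if (keys[r] %in% rt_keys) next
      tries <- 0L
      while (detect_rt_switch(t$chrom, j[r, 1L], j[r, 2L], t$strand,
                              genome, k = k) && tries < 60L) {
        win <- setdiff(seq(j[r, 1L] - k, j[r, 1L] + k - 1L),
                       protect[[t$chrom]])
        pos <- win[tries %% length(win) + 1L]
        old <- substr(seqs[[t$chrom]], pos + 1L, pos + 1L)
        seqs[t$chrom] <- .put(seqs[[t$chrom]], pos,
                              setdiff(c("A", "C", "G", "T"), old)[
                                tries %% 3L + 1L])
        genome <- rebuild()
        tries <- tries + 1L
      }
    }
  }

  # --- coverage table, long-read counts, peak tracks -------------------
  all_keys <- unique(unlist(lapply(all_tx, junction_keys)))
  coverage <- stats::setNames(rep(10, length(all_keys)), all_keys)
  coverage[low_cov_keys] <- 2
  lr_counts <- stats::setNames(rep(1L, length(queries)), names(queries))
  ref_index <- build_reference_index(ref)
  peak_at <- function(pos_tab, pad = 5L) {
    peak_index(GenomicRanges::GRanges(
      pos_tab$chrom,
      IRanges::IRanges(pmax(1L, pos_tab$pos - pad + 1L), pos_tab$pos + pad),
      strand = pos_tab$strand))
  }
  structure(list(queries = queries, truth = truth, genome = genome,
                 reference = ref, ref_index = ref_index,
                 coverage = coverage, lr_counts = lr_counts,
                 polyA_db = peak_at(ref_index$tts, 5L),
                 cage = peak_at(ref_index$tss, 20L),
                 threeprime = peak_at(ref_index$tts, 20L),
                 spec = spec),
            class = "SyntheticCatalog")
}

# truncated-normal sampling by rejection, bounded to [0, 1]
.rtnorm01 <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= 0 & x <= 1])
  }
  out[seq_len(n)]
}

#' Simulate a tumor/control cohort with planted splicing subpopulations
#'
#' Builds a PSI matrix and clinical table with known ground truth.
#' Planted tumor-specific events draw a latent tumor-only subpopulation
#' (weight `subpop_weight` of the tumors) from a truncated Gaussian at
#' `tumor_psi` while all remaining samples (tumors and controls) draw from
#' `background_psi`; null events draw every sample from a single Gaussian.
#' Tumor survival is exponential with hazard `base_hazard` per day,
#' multiplied by `hazard_ratio` for members of the designated survival
#' event's subpopulation; censoring is an independent exponential with
#' rate `censor_rate_frac * base_hazard`. Controls carry no survival.
#'
#' @param spec A `FixtureSpec` (its `cohort` element drives everything).
#' @return List: `psi` (events x samples matrix), `samples` (clinical
#'   `data.frame`), `truth` (planted event ids, the survival event id,
#'   per-event subpopulation membership, realized PSI means).
#' @export
simulate_cohort <- function(spec) {
  co <- spec$cohort
  set.seed(spec$seed + 2L)
  n_t <- co$n_tumor; n_c <- co$n_control
  tumor_ids <- sprintf("T%03d", seq_len(n_t))
  control_ids <- sprintf("C%03d", seq_len(n_c))
  ids <- c(tumor_ids, control_ids)
  types <- c("SE", "RI", "A3SS", "AF", "MX", "A5SS", "AL")
  planted_ids <- sprintf("pe%02d;%s:chrS:%d-%d:+",
                         seq_len(co$n_planted),
                         types[(seq_len(co$n_planted) - 1L) %% 7L + 1L],
                         1000L + 500L * seq_len(co$n_planted),
                         1400L + 500L * seq_len(co$n_planted))
  null_ids <- sprintf("ne%02d;SE:chrS:%d-%d:+", seq_len(co$n_null),
                      50000L + 300L * seq_len(co$n_null),
                      50200L + 300L * seq_len(co$n_null))
  psi <- matrix(NA_real_, co$n_planted + co$n_null, length(ids),
                dimnames = list(c(planted_ids, null_ids), ids))
  n_sub <- round(co$subpop_weight * n_t)
  members <- list()
  realized <- numeric(co$n_planted)
  for (i in seq_len(co$n_planted)) {
    memb <- sample(tumor_ids, n_sub)
    members[[planted_ids[i]]] <- memb
    v <- stats::setNames(
      .rtnorm01(length(ids), co$background_psi[["mean"]],
                co$background_psi[["sd"]]), ids)
    v[memb] <- .rtnorm01(n_sub, co$tumor_psi[["mean"]],
                         co$tumor_psi[["sd"]])
    psi[planted_ids[i], ] <- v
    realized[i] <- 100 * (mean(v[memb]) - mean(v[control_ids]))
  }
  for (i in seq_len(co$n_null)) {
    mu <- stats::runif(1L, 0.3, 0.7)
    psi[null_ids[i], ] <- .rtnorm01(length(ids), mu, co$null_sd)
  }
  surv_event <- if (co$hazard_ratio != 1 && co$n_planted >= 1L)
    planted_ids[co$survival_event] else character(0)
  hz <- rep(co$base_hazard, n_t)
  if (length(surv_event))
    hz[tumor_ids %in% members[[surv_event]]] <-
      co$base_hazard * co$hazard_ratio
  death <- stats::rexp(n_t, rate = hz)
  cens <- stats::rexp(n_t, rate = co$base_hazard * co$censor_rate_frac)
  samples <- data.frame(
    sample_id = ids,
    group = c(rep("tumor", n_t), rep("control", n_c)),
    subtype = NA_character_,
    survival_time = c(round(pmin(death, cens), 1), rep(NA_real_, n_c)),
    event_observed = c(death <= cens, rep(NA, n_c)),
    stringsAsFactors = FALSE)
  list(psi = psi, samples = samples,
       truth = list(tumor_specific = planted_ids,
                    survival = surv_event, members = members,
                    realized_delta_psi = stats::setNames(realized,
                                                         planted_ids)))
}

#' Write the synthetic fixture to standard-format files
#'
#' Emits genome FASTA, reference and query GTFs, the junction coverage
#' TSV, the truth table TSV, and BED tracks for the peak indexes.
#'
#' @param cat A `SyntheticCatalog` from [plant_query_isoforms()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_fixture <- function(cat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             reference = file.path(dir, "reference.gtf"),
             queries = file.path(dir, "queries.gtf"),
             coverage = file.path(dir, "junction_coverage.tsv"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(cat$genome, paths["genome"])
  write_gtf(cat$reference, paths["reference"])
  write_gtf(cat$queries, paths["queries"])
  utils::write.table(data.frame(junction = names(cat$coverage),
                                reads = unname(cat$coverage)),
                     paths["coverage"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cat$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
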