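# Shared fixtures and independent oracles. The planted synthetic catalog
# is expensive to build, so it is memoized for the whole test run.

.fx_cache <- new.env(parent = emptyenv())

default_catalog <- function() {
  if (is.null(.fx_cache$cat)) {
    spec <- fixture_spec()
    ann <- make_genome_and_annotation(spec)
    .fx_cache$spec <- spec
    .fx_cache$ann <- ann
    .fx_cache$cat <- plant_query_isoforms(spec, ann)
  }
  .fx_cache$cat
}

default_annotation <- function() {
  default_catalog()
  .fx_cache$ann
}

default_qc_flags <- function() {
  if (is.null(.fx_cache$flags)) {
    cat <- default_catalog()
    .fx_cache$flags <- lapply(cat$queries, function(q)
      compute_qc_flags(q, cat$genome, cat$ref_index,
                       coverage_table = cat$coverage,
                       lr_sample_count = cat$lr_counts[[q$transcript_id]],
                       polyA_db = cat$polyA_db))
  }
  .fx_cache$flags
}

default_cohort <- function() {
  if (is.null(.fx_cache$cohort)) {
    default_catalog()
    .fx_cache$cohort <- simulate_cohort(.fx_cache$spec)
  }
  .fx_cache$cohort
}

default_stratification <- function() {
  if (is.null(.fx_cache$strat)) {
    co <- default_cohort()
    .fx_cache$strat <- stratify_cohort(co$psi, co$samples,
                                       stratify_config(seed = 11L))
  }
  .fx_cache$strat
}

# ---- independent brute-force structural classifier -------------------
# Recomputes everything from the raw reference transcript list with plain
# loops; shares no code with the package implementation.
oracle_classify <- function(q, refs, mono_end_tol = 50L) {
  chain_of <- function(tx) {
    e <- tx$exons
    if (nrow(e) < 2L) return(character(0))
    paste(e[-nrow(e), 2L], e[-1L, 1L], sep = ",")
  }
  span_of <- function(tx) c(tx$exons[1L, 1L], tx$exons[nrow(tx$exons), 2L])
  gene_of <- vapply(refs, function(t) t$gene_id, "")
  same <- vapply(refs, function(t)
    t$chrom == q$chrom && t$strand == q$strand, TRUE)
  qspan <- span_of(q)
  overlaps_gene <- function(strand_same) {
    hits <- character(0)
    for (g in unique(gene_of)) {
      gtx <- refs[gene_of == g]
      if (gtx[[1L]]$chrom != q$chrom) next
      sstrand <- gtx[[1L]]$strand == q$strand
      if (sstrand != strand_same) next
      gs <- min(vapply(gtx, function(t) t$exons[1L, 1L], 0L))
      ge <- max(vapply(gtx, function(t) t$exons[nrow(t$exons), 2L], 0L))
      anyov <- FALSE
      for (r in seq_len(nrow(q$exons)))
        if (q$exons[r, 1L] < ge && gs < q$exons[r, 2L]) anyov <- TRUE
      if (anyov) hits <- c(hits, g)
    }
    hits
  }
  if (nrow(q$exons) == 1L) {
    for (t in refs[same]) {
      if (nrow(t$exons) == 1L) {
        s <- span_of(t)
        if (abs(s[1L] - qspan[1L]) <= mono_end_tol &&
            abs(s[2L] - qspan[2L]) <= mono_end_tol) return("FSM")
      }
    }
    for (t in refs[same]) {
      for (r in seq_len(nrow(t$exons)))
        if (t$exons[r, 1L] <= qspan[1L] && t$exons[r, 2L] >= qspan[2L])
          return("ISM")
    }
    if (length(overlaps_gene(TRUE))) return("GENIC")
    if (length(overlaps_gene(FALSE))) return("ANTISENSE")
    return("INTERGENIC")
  }
  qc <- chain_of(q)
  for (t in refs[same]) {
    if (identical(chain_of(t), qc)) return("FSM")
  }
  for (t in refs[same]) {
    rc <- chain_of(t)
    if (length(rc) > length(qc)) {
      for (i in seq_len(length(rc) - length(qc) + 1L)) {
        if (identical(rc[i:(i + length(qc) - 1L)], qc)) return("ISM")
      }
    }
  }
  genes <- overlaps_gene(TRUE)
  if (length(genes) == 0L) {
    if (length(overlaps_gene(FALSE))) return("ANTISENSE")
    return("INTERGENIC")
  }
  if (length(genes) >= 2L) {
    spans <- lapply(genes, function(g) {
      gtx <- refs[gene_of == g]
      c(min(vapply(gtx, function(t) t$exons[1L, 1L], 0L)),
        max(vapply(gtx, function(t) t$exons[nrow(t$exons), 2L], 0L)))
    })
    disjoint <- TRUE
    for (i in seq_along(spans)) for (j in seq_len(i - 1L))
      if (spans[[i]][1L] < spans[[j]][2L] &&
          spans[[j]][1L] < spans[[i]][2L]) disjoint <- FALSE
    if (disjoint) return("FUSION")
  }
  # assigned gene: maximal exonic overlap
  best <- NULL; best_ov <- -1
  for (g in sort(genes)) {
    gex <- do.call(rbind, lapply(refs[gene_of == g], function(t) t$exons))
    ov <- 0
    for (r in seq_len(nrow(q$exons))) {
      covered <- logical(0)
      lo <- q$exons[r, 1L]; hi <- q$exons[r, 2L]
      pts <- rep(FALSE, hi - lo)
      for (x in seq_len(nrow(gex))) {
        a <- max(lo, gex[x, 1L]); b <- min(hi, gex[x, 2L])
        if (b > a) pts[(a - lo + 1L):(b - lo)] <- TRUE
      }
      ov <- ov + sum(pts)
    }
    if (ov > best_ov) { best_ov <- ov; best <- g }
  }
  gtx <- refs[gene_of == best]
  donors <- integer(0); acceptors <- integer(0)
  for (t in gtx) {
    e <- t$exons
    if (nrow(e) >= 2L) {
      donors <- c(donors, e[-nrow(e), 2L])
      acceptors <- c(acceptors, e[-1L, 1L])
    }
  }
  qd <- q$exons[-nrow(q$exons), 2L]
  qa <- q$exons[-1L, 1L]
  if (all(qd %in% donors) && all(qa %in% acceptors)) "NIC" else "NNC"
}

# ---- affine-gap global alignment (Gotoh) score oracle ----------------
gotoh_score <- function(a, b, open = 10, ext = 0.5) {
  sub <- get_blosum62()
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (i in seq_len(n) + 1L) X[i, 1L] <- -(open + (i - 1L) * ext)
  for (j in seq_len(m) + 1L) Y[1L, j] <- -(open + (j - 1L) * ext)
  for (i in seq_len(n) + 1L) for (j in seq_len(m) + 1L) {
    M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                   Y[i - 1L, j - 1L]) + sub[A[i - 1L], B[j - 1L]]
    X[i, j] <- max(M[i - 1L, j] - open - ext, X[i - 1L, j] - ext,
                   Y[i - 1L, j] - open - ext)
    Y[i, j] <- max(M[i, j - 1L] - open - ext, Y[i, j - 1L] - ext,
                   X[i, j - 1L] - open - ext)
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# ---- brute-force forward-frame ORF scan ------------------------------
# returns a list of (start, end) transcript coordinates, end including the
# stop codon when one bounds the ORF
oracle_orfs <- function(s, min_aa) {
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  n <- nchar(s)
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 1L) next
    starts <- f + 3L * (seq_len(ncod) - 1L)
    codons <- substring(s, starts + 1L, starts + 3L)
    stop_idx <- which(codons %in% stops)
    bounds <- c(0L, stop_idx)            # region r: codons bounds[r]+1 ..
    for (r in seq_along(bounds)) {
      lo <- bounds[r] + 1L
      hi <- if (r < length(bounds)) bounds[r + 1L] - 1L else ncod
      has_stop <- r < length(bounds)
      if (r == 1L && has_stop && hi >= lo && codons[lo] != "ATG") {
        aa <- hi - lo + 1L               # leading 5'-incomplete
        if (aa >= min_aa)
          out <- c(out, list(c(starts[lo], starts[hi] + 6L)))
      }
      atg <- if (hi >= lo) which(codons[lo:hi] == "ATG") else integer(0)
      if (length(atg)) {
        a0 <- lo + atg[1L] - 1L
        aa <- hi - a0 + 1L
        if (aa >= min_aa) {
          end <- if (has_stop) starts[hi] + 6L else starts[hi] + 3L
          out <- c(out, list(c(starts[a0], end)))
        }
      }
    }
  }
  out
}

# exact Wilcoxon two-sided p by full enumeration of group assignments
enumerate_wilcoxon_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2L, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
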