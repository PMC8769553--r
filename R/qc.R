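#' Poly(A) intrapriming detection (unreliable 3' end)
#'
#' Oligo-dT priming on genomic A-rich stretches creates false 3' ends. A
#' transcript's genomic 3' end is flagged *unreliable* only when all three
#' conditions hold: (i) it lies more than `max_tts_dist` bp (default 100)
#' from any annotated TTS on the same chromosome and strand; (ii) the
#' adenine fraction of the `a_window` nt (default 20) immediately downstream
#' of the 3' end, read on the transcript's strand, exceeds `a_frac`
#' (default 0.80, strictly); (iii) the 3' end overlaps no interval of the
#' poly(A)-site catalog within `polya_slack` bp (default 10).
#'
#' @param tx A `TranscriptModel`.
#' @param genome `DNAStringSet`.
#' @param polyA_db A `PeakIndex` of curated poly(A) sites, or `NULL` (then
#'   sub-flag (iii) is treated as "no overlap", i.e. `TRUE`).
#' @param ref A `ReferenceIndex` (source of annotated TTS positions).
#' @param max_tts_dist,a_window,a_frac,polya_slack Tunable thresholds, see
#'   above.
#' @return List with logical `far_from_tts`, `a_rich_downstream`,
#'   `no_polyA_db_overlap`, the downstream adenine fraction `a_fraction`,
#'   and the conjunction `unreliable_3prime`.
#' @export
detect_intrapriming <- function(tx, genome, polyA_db, ref,
                                max_tts_dist = 100L, a_window = 20L,
                                a_frac = 0.80, polya_slack = 10L) {
  far <- nearest_tts_distance(ref, tx) > max_tts_dist
  end3 <- tts(tx)
  if (tx$strand == "+") {
    win <- fetch_seq(genome, tx$chrom, end3, end3 + a_window)
    afrac <- if (nchar(win)) mean(strsplit(win, "")[[1]] == "A") else 0
    end_base <- end3 - 1L
  } else {
    win <- fetch_seq(genome, tx$chrom, end3 - a_window, end3)
    # downstream in transcript orientation = upstream genomic, complemented
    afrac <- if (nchar(win)) mean(strsplit(win, "")[[1]] == "T") else 0
    end_base <- end3
  }
  arich <- afrac > a_frac
  nodb <- if (is.null(polyA_db)) TRUE else
    !peak_overlaps(polyA_db, tx$chrom, end_base, tx$strand, slack = polya_slack)
  list(far_from_tts = far, a_rich_downstream = arich,
       no_polyA_db_overlap = nodb, a_fraction = afrac,
       unreliable_3prime = far && arich && nodb)
}

#' Short-read junction support filter
#'
#' A transcript passes when *all* of its splice junctions are covered by at
#' least `min_coverage` short reads (default 5) **or** it was detected in at
#' least `min_samples` long-read samples (default 3). With
#' `mode = "fl_reads"`, the second clause counts full-length reads instead
#' of samples (the two readings of "detected in at least three samples,
#' i.e. minimum of three FL reads").
#'
#' @param tx A `TranscriptModel`.
#' @param coverage_table Named numeric vector of read counts keyed by
#'   junction (`"chrom:donor:acceptor:strand"`); absent junctions count 0.
#' @param lr_sample_count Number of long-read samples (or FL reads, see
#'   `mode`) in which the transcript was observed.
#' @param min_coverage,min_samples Thresholds.
#' @param mode `"samples"` (default) or `"fl_reads"`; both compare
#'   `lr_sample_count >= min_samples`, the mode only documents the unit.
#' @return `TRUE` (pass) or `FALSE`.
#' @export
junction_support_filter <- function(tx, coverage_table, lr_sample_count,
                                    min_coverage = 5, min_samples = 3,
                                    mode = c("samples", "fl_reads")) {
  mode <- match.arg(mode)
  keys <- junction_keys(tx)
  cov <- if (length(keys)) {
    v <- coverage_table[keys]
    v[is.na(v)] <- 0
    min(v)
  } else Inf
  cov >= min_coverage || lr_sample_count >= min_samples
}

#' Canonical splice-site check
#'
#' A junction is canonical when its strand-corrected intronic dinucleotide
#' pair is GT-AG, GC-AG or AT-AC.
#'
#' @param chrom,donor_pos,acceptor_pos,strand Junction coordinates (intron
#'   is `[donor_pos, acceptor_pos)` on the forward genomic axis).
#' @param genome `DNAStringSet`.
#' @return `"canonical"` or `"noncanonical"`.
#' @export
canonical_status <- function(chrom, donor_pos, acceptor_pos, strand, genome) {
  if (!chrom %in% names(genome)) stop("contig '", chrom, "' not in genome")
  len <- Biostrings::width(genome[chrom])
  if (donor_pos < 0L || acceptor_pos > len)
    stop("junction outside contig bounds")
  five <- fetch_seq(genome, chrom, donor_pos, donor_pos + 2L)
  three <- fetch_seq(genome, chrom, acceptor_pos - 2L, acceptor_pos)
  if (strand == "-") {
    tmp <- revcomp(three); three <- revcomp(five); five <- tmp
  }
  pair <- paste0(five, "-", three)
  if (pair %in% c("GT-AG", "GC-AG", "AT-AC")) "canonical" else "noncanonical"
}

#' RT-switching detection at a junction
#'
#' Template switching of the reverse transcriptase at direct repeats
#' produces artifactual junctions. The test compares two `2k`-nt windows
#' spanning the exon/intron boundary on each side of the junction (`k`
#' exonic + `k` intronic bases at the donor; `k` intronic + `k` exonic at
#' the acceptor) and flags the junction when they share an exact direct
#' repeat of length `>= k`.
#'
#' @inheritParams canonical_status
#' @param k Minimum repeat length (default 8); detection is monotone
#'   (non-increasing) in `k`.
#' @return `TRUE` when a direct repeat of length `>= k` is shared.
#' @export
detect_rt_switch <- function(chrom, donor_pos, acceptor_pos, strand, genome,
                             k = 8L) {
  dwin <- fetch_seq(genome, chrom, donor_pos - k, donor_pos + k)
  awin <- fetch_seq(genome, chrom, acceptor_pos - k, acceptor_pos + k)
  if (strand == "-") { dwin2 <- revcomp(awin); awin <- revcomp(dwin); dwin <- dwin2 }
  n1 <- nchar(dwin); n2 <- nchar(awin)
  if (n1 < k || n2 < k) return(FALSE)
  kmers <- unique(substring(dwin, seq_len(n1 - k + 1L), seq_len(n1 - k + 1L) + k - 1L))
  kmers2 <- substring(awin, seq_len(n2 - k + 1L), seq_len(n2 - k + 1L) + k - 1L)
  any(kmers %in% kmers2)
}

#' Intron-retention signature of a query transcript
#'
#' Native implementation of the transcript-comparison class codes used for
#' retention screening, evaluated against every overlapping same-strand
#' reference transcript:
#'
#' * `"i"` — query fully contained within a reference intron;
#' * `"m"` — at least one reference intron fully inside a query exon and
#'   *every* reference intron either exactly matched by a query junction or
#'   fully retained (all-intron retention);
#' * `"y"` — a reference intron fully inside a query exon while the query
#'   shares no splice junction with that reference transcript;
#' * `"n"` — a reference intron fully retained while the chain is
#'   otherwise only partially compatible (some junctions shared, but not
#'   every reference intron matched or retained).
#'
#' A query exon merely extending a few bases into an intron, or an exon
#' lying inside an intron without containing it, is not a retention
#' signature.
#'
#' Precedence when several reference transcripts yield codes:
#' `i > m > y > n`.
#'
#' @param query A `TranscriptModel`.
#' @param ref A `ReferenceIndex`.
#' @return One of `"i"`, `"m"`, `"y"`, `"n"`, or `NULL` when no retention
#'   signature exists.
#' @export
detect_intron_retention <- function(query, ref) {
  span <- transcript_span(query)
  cands <- Filter(function(t)
    t$chrom == query$chrom && t$strand == query$strand &&
      transcript_span(t)["start"] < span["end"] &&
      span["start"] < transcript_span(t)["end"],
    ref$transcripts)
  if (length(cands) == 0L) return(NULL)
  qex <- query$exons
  qkeys <- junction_keys(query)
  codes <- character(0)
  for (t in cands) {
    ri <- introns(t)
    if (nrow(ri) == 0L) next
    # i: query entirely inside one reference intron
    if (any(ri[, 1L] <= span["start"] & ri[, 2L] >= span["end"])) {
      codes <- c(codes, "i"); next
    }
    in_exon <- function(s, e) any(qex[, 1L] <= s & qex[, 2L] >= e)
    retained <- vapply(seq_len(nrow(ri)),
                       function(i) in_exon(ri[i, 1L], ri[i, 2L]), TRUE)
    matched <- paste(t$chrom, ri[, 1L], ri[, 2L], t$strand, sep = ":") %in% qkeys
    if (any(retained)) {
      if (all(retained | matched)) codes <- c(codes, "m")
      else if (!any(matched)) codes <- c(codes, "y")
      else codes <- c(codes, "n")
    }
  }
  if (length(codes) == 0L) return(NULL)
  for (c in c("i", "m", "y", "n")) if (c %in% codes) return(c)
}

#' Compute the full QC flag set for one transcript
#'
#' Convenience wrapper that evaluates every filter and returns a `QcFlags`
#' record consumed by [apply_filter_policy()].
#'
#' @inheritParams detect_intrapriming
#' @inheritParams junction_support_filter
#' @param params Optional named list overriding filter defaults
#'   (`max_tts_dist`, `a_window`, `a_frac`, `polya_slack`, `min_coverage`,
#'   `min_samples`, `rt_k`).
#' @return A `QcFlags` list.
#' @export
compute_qc_flags <- function(tx, genome, ref, coverage_table = numeric(0),
                             lr_sample_count = 1L, polyA_db = NULL,
                             params = list()) {
  p <- utils::modifyList(list(max_tts_dist = 100L, a_window = 20L,
                              a_frac = 0.80, polya_slack = 10L,
                              min_coverage = 5, min_samples = 3, rt_k = 8L),
                         params)
  ip <- detect_intrapriming(tx, genome, polyA_db, ref,
                            max_tts_dist = p$max_tts_dist,
                            a_window = p$a_window, a_frac = p$a_frac,
                            polya_slack = p$polya_slack)
  j <- junctions(tx)
  keys <- junction_keys(tx)
  noncanon <- character(0); rts <- character(0)
  for (i in seq_len(nrow(j))) {
    if (canonical_status(tx$chrom, j[i, 1L], j[i, 2L], tx$strand,
                         genome) == "noncanonical")
      noncanon <- c(noncanon, keys[i])
    if (detect_rt_switch(tx$chrom, j[i, 1L], j[i, 2L], tx$strand, genome,
                         k = p$rt_k))
      rts <- c(rts, keys[i])
  }
  cov <- stats::setNames(rep(0, length(keys)), keys)
  hit <- keys %in% names(coverage_table)
  cov[hit] <- coverage_table[keys[hit]]
  structure(list(
    transcript_id = tx$transcript_id,
    far_from_tts = ip$far_from_tts,
    a_rich_downstream = ip$a_rich_downstream,
    no_polyA_db_overlap = ip$no_polyA_db_overlap,
    unreliable_3prime = ip$unreliable_3prime,
    noncanonical_junctions = noncanon,
    rt_switch_junctions = rts,
    junction_coverage = cov,
    junction_pass = junction_support_filter(tx, coverage_table,
                                            lr_sample_count,
                                            min_coverage = p$min_coverage,
                                            min_samples = p$min_samples),
    lr_sample_count = lr_sample_count,
    intron_retention_code = detect_intron_retention(tx, ref)),
    class = "QcFlags")
}

# filters applied per structural category (the per-category keep policy)
.FILTER_POLICY <- list(
  FSM = character(0),
  ISM = "intrapriming",
  NIC = c("intrapriming", "coverage", "intron_retention"),
  NNC = c("intrapriming", "coverage", "intron_retention",
          "rt_switch", "noncanonical"),
  ANTISENSE = c("coverage", "intron_retention", "rt_switch", "noncanonical"),
  INTERGENIC = c("coverage", "intron_retention", "rt_switch", "noncanonical"),
  FUSION = c("coverage", "intron_retention", "rt_switch", "noncanonical"),
  GENIC = c("coverage", "intron_retention", "rt_switch", "noncanonical"))

#' Per-category keep/drop decision
#'
#' Applies the category-dependent filter policy: FSM transcripts are always
#' kept; ISM are dropped only for an unreliable 3' end; NIC additionally
#' require junction read support and no intron retention; NNC and the
#' remaining categories (antisense, intergenic, fusion, genic) additionally
#' require no RT-switch junctions and only canonical splice sites (the
#' 3'-end filter does not apply to the non-genic "other" categories).
#'
#' @param call A `StructuralCall`.
#' @param flags The matching `QcFlags`.
#' @return A `FilterDecision` list: `transcript_id`, `category`, `keep`,
#'   and `reasons` (names of failed filters; empty iff kept).
#' @export
apply_filter_policy <- function(call, flags) {
  if (!call$category %in% names(.FILTER_POLICY))
    stop("unknown structural category: ", call$category)
  active <- .FILTER_POLICY[[call$category]]
  failed <- c(
    if ("intrapriming" %in% active && isTRUE(flags$unreliable_3prime))
      "intrapriming",
    if ("coverage" %in% active && !isTRUE(flags$junction_pass)) "coverage",
    if ("intron_retention" %in% active &&
        !is.null(flags$intron_retention_code)) "intron_retention",
    if ("rt_switch" %in% active && length(flags$rt_switch_junctions) > 0L)
      "rt_switch",
    if ("noncanonical" %in% active &&
        length(flags$noncanonical_junctions) > 0L) "noncanonical")
  structure(list(transcript_id = call$transcript_id,
                 category = call$category,
                 keep = length(failed) == 0L,
                 reasons = as.character(failed)),
            class = "FilterDecision")
}

#' Orthogonal end support (CAGE/ATAC peaks, 3'-seq peaks, poly(A) motif)
#'
#' The 5' end is supported when it lies within `window` bp of a CAGE or
#' ATAC peak; the 3' end when it lies within `window` bp of a 3'-seq peak
#' or when a poly(A) motif (AATAAA / ATTAAA, read on the transcript strand)
#' occurs in the last `motif_window` nt of the transcript sequence.
#'
#' @param tx A `TranscriptModel`.
#' @param cage,atac,threeprime `PeakIndex` objects or `NULL`.
#' @param genome `DNAStringSet` (needed for the motif scan).
#' @param window Peak distance threshold in bp (default 50).
#' @param motif_window Length of the 3'-terminal window scanned for the
#'   poly(A) motif (default 50 nt).
#' @return List with `tss_supported`, `tts_supported`, `tts_motif`.
#' @export
validate_ends <- function(tx, cage = NULL, atac = NULL, threeprime = NULL,
                          genome = NULL, window = 50L, motif_window = 50L) {
  p5 <- tss(tx); p3 <- tts(tx)
  near <- function(idx, pos) !is.null(idx) &&
    peak_distance(idx, tx$chrom, pos, tx$strand) <= window
  tss_ok <- near(cage, p5) || near(atac, p5)
  motif <- FALSE
  if (!is.null(genome)) {
    s <- transcript_sequence(tx, genome)
    tail50 <- substr(s, max(1L, nchar(s) - motif_window + 1L), nchar(s))
    motif <- grepl("AATAAA|ATTAAA", tail50)
  }
  tts_ok <- near(threeprime, p3) || motif
  list(tss_supported = tss_ok, tts_supported = tts_ok, tts_motif = motif)
}

#' Per-category end-support rates
#'
#' @param calls Named list of `StructuralCall`.
#' @param supports Named list of [validate_ends()] records (same ids).
#' @return `data.frame` with one row per structural category: member count
#'   and TSS / TTS / both support fractions (`NA`, not 0, for empty
#'   categories).
#' @export
support_rate_report <- function(calls, supports) {
  ids <- names(calls)
  stopifnot(all(ids %in% names(supports)))
  cat <- vapply(calls, function(x) x$category, "")
  tssv <- vapply(supports[ids], function(s) isTRUE(s$tss_supported), TRUE)
  ttsv <- vapply(supports[ids], function(s) isTRUE(s$tts_supported), TRUE)
  out <- data.frame(category = STRUCTURAL_CATEGORIES, n = 0L,
                    tss_rate = NA_real_, tts_rate = NA_real_,
                    both_rate = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(STRUCTURAL_CATEGORIES)) {
    m <- cat == STRUCTURAL_CATEGORIES[i]
    out$n[i] <- sum(m)
    if (any(m)) {
      out$tss_rate[i] <- mean(tssv[m])
      out$tts_rate[i] <- mean(ttsv[m])
      out$both_rate[i] <- mean(tssv[m] & ttsv[m])
    }
  }
  out
}
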