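.STOPS <- c("TAA", "TAG", "TGA")

#' Enumerate candidate ORFs on a transcript sequence
#'
#' Scans the three forward frames of the sense transcript sequence. Per
#' stop-to-stop region the 5'-most ATG-initiated, stop-terminated ORF is
#' emitted; additionally a stop-terminated 5'-incomplete ORF (open at the
#' sequence start, no ATG, flagged `has_start = FALSE`) is emitted for
#' each frame's leading region, and an ATG-initiated 3'-incomplete ORF
#' (no stop before the sequence end, `has_stop = FALSE`) for each frame's
#' trailing region. Reverse-strand
#' frames are never scanned — the input is already the sense sequence.
#' Candidates shorter than `min_aa` amino acids (stop codon excluded) are
#' dropped.
#'
#' @param tx_seq Sense nucleotide sequence (A/C/G/T/N).
#' @param min_aa Minimum protein length in amino acids (default 100).
#' @return List of candidates, each a list with `orf_start`, `orf_stop`
#'   (0-based transcript coordinates, stop-exclusive end *including* the
#'   stop codon when present), `frame`, `has_start`, `has_stop`,
#'   `protein_seq`, `aa_length`.
#' @export
enumerate_orfs <- function(tx_seq, min_aa = 100L) {
  tx_seq <- toupper(tx_seq)
  if (grepl("[^ACGTN]", tx_seq))
    stop("transcript sequence contains non-ACGTN characters")
  n <- nchar(tx_seq)
  out <- list()
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 1L) next
    starts <- f + 3L * (seq_len(ncod) - 1L)
    codons <- substring(tx_seq, starts + 1L, starts + 3L)
    is_stop <- codons %in% .STOPS
    is_atg <- codons == "ATG"
    region_start <- 1L          # codon index where current region begins
    for (s in c(which(is_stop), NA_integer_)) {
      terminal <- is.na(s)
      region_end <- if (terminal) ncod else s - 1L   # last coding codon
      if (region_end >= region_start || !terminal) {
        cod_idx <- if (region_end >= region_start)
          region_start:region_end else integer(0)
        # 5'-incomplete candidate for the frame's leading region (must
        # still be stop-terminated; an unbounded open frame is not an ORF)
        if (region_start == 1L && length(cod_idx) && !terminal &&
            !is_atg[region_start]) {
          out <- c(out, list(.orf_candidate(tx_seq, f, region_start,
                                            region_end, terminal,
                                            has_start = FALSE)))
        }
        atgs <- cod_idx[is_atg[cod_idx]]
        if (length(atgs)) {
          out <- c(out, list(.orf_candidate(tx_seq, f, atgs[1L],
                                            region_end, terminal,
                                            has_start = TRUE)))
        }
      }
      if (terminal) break
      region_start <- s + 1L
    }
  }
  out <- Filter(function(o) o$aa_length >= min_aa, out)
  # deterministic order: 5'-most start, then longest
  ord <- order(vapply(out, function(o) o$orf_start, 0L),
               -vapply(out, function(o) o$orf_stop, 0L))
  out[ord]
}

.orf_candidate <- function(tx_seq, frame, cod_from, cod_to, terminal,
                           has_start) {
  start <- frame + 3L * (cod_from - 1L)
  aa_len <- cod_to - cod_from + 1L
  stop_ <- frame + 3L * cod_to            # end of last coding codon
  if (!terminal) stop_ <- stop_ + 3L      # include the stop codon
  cds <- substr(tx_seq, start + 1L, start + 3L * aa_len)
  prot <- if (aa_len > 0L)
    as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                       if.fuzzy.codon = "X")) else ""
  list(orf_start = start, orf_stop = stop_, frame = frame,
       has_start = has_start, has_stop = !terminal,
       protein_seq = prot, aa_length = aa_len)
}

#' Select the single best ORF for a transcript
#'
#' Candidates are ranked by: significant reference-proteome homology
#' (e-value `<= evalue_max`), then bitscore, then presence of a conserved
#' domain hit, then ORF length, then 5'-most start (the documented
#' tie-break). The top candidate becomes the transcript's `OrfRecord`;
#' an empty candidate list marks the transcript non-coding (`NULL`).
#'
#' @param transcript_id Transcript the candidates belong to.
#' @param candidates Output of [enumerate_orfs()]; candidate `i` is
#'   addressed in the hit tables as `"<transcript_id>.orf<i>"`.
#' @param homology_hits `data.frame(query, hit, evalue, bitscore)` or
#'   `NULL`.
#' @param domain_hits `data.frame(query, domain_id)` or `NULL`.
#' @param evalue_max Homology significance threshold (default `1e-5`).
#' @return An `OrfRecord` list, or `NULL` when there is no candidate.
#' @export
select_best_orf <- function(transcript_id, candidates,
                            homology_hits = NULL, domain_hits = NULL,
                            evalue_max = 1e-5) {
  if (length(candidates) == 0L) return(NULL)
  ids <- paste0(transcript_id, ".orf", seq_along(candidates))
  has_hom <- rep(FALSE, length(ids)); bits <- rep(0, length(ids))
  best_hit <- rep(NA_character_, length(ids)); evals <- rep(NA_real_, length(ids))
  if (!is.null(homology_hits) && nrow(homology_hits)) {
    for (i in seq_along(ids)) {
      h <- homology_hits[homology_hits$query == ids[i] &
                           homology_hits$evalue <= evalue_max, , drop = FALSE]
      if (nrow(h)) {
        h <- h[order(-h$bitscore, h$hit), , drop = FALSE]
        has_hom[i] <- TRUE; bits[i] <- h$bitscore[1L]
        best_hit[i] <- h$hit[1L]; evals[i] <- h$evalue[1L]
      }
    }
  }
  has_dom <- rep(FALSE, length(ids))
  if (!is.null(domain_hits) && nrow(domain_hits))
    has_dom <- ids %in% domain_hits$query
  len <- vapply(candidates, function(o) o$aa_length, 0L)
  start5 <- vapply(candidates, function(o) o$orf_start, 0L)
  ord <- order(-has_hom, -bits, -has_dom, -len, start5)
  i <- ord[1L]
  o <- candidates[[i]]
  doms <- if (!is.null(domain_hits) && nrow(domain_hits))
    sort(unique(domain_hits$domain_id[domain_hits$query == ids[i]]))
  else character(0)
  structure(list(transcript_id = transcript_id, orf_id = ids[i],
                 orf_start = o$orf_start, orf_stop = o$orf_stop,
                 has_start = o$has_start, has_stop = o$has_stop,
                 protein_seq = o$protein_seq,
                 best_reference_hit = best_hit[i], evalue = evals[i],
                 bitscore = bits[i], identity_pct = NA_real_,
                 domain_set = doms, tm_region_count = 0L,
                 localization = NA_character_, nmd_sensitive = NA),
            class = "OrfRecord")
}

#' Global protein identity (Needleman-Wunsch)
#'
#' True global alignment with BLOSUM62, gap opening 10 and extension 0.5
#' (configurable); identity is the number of matched positions over the
#' alignment length (gaps included), in percent.
#'
#' @param query_protein,reference_protein Amino-acid strings.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return Identity percentage in `[0, 100]`.
#' @examples
#' global_identity("ACDEFG", "ACDEFG")   # 100
#' round(global_identity("ACDEFG", "ACDQFG"), 2)   # 83.33
#' @export
global_identity <- function(query_protein, reference_protein,
                            gap_opening = 10, gap_extension = 0.5) {
  if (!nchar(query_protein) || !nchar(reference_protein))
    stop("empty protein sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query_protein),
    Biostrings::AAString(reference_protein),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  as.numeric(Biostrings::pid(aln, type = "PID1"))
}

#' Protein-level consequence deltas versus the reference proteome
#'
#' Compares a selected ORF to its closest reference protein: identity below
#' `novel_identity` percent (default 99) marks a novel protein; PFAM domain
#' gains/losses are set differences; transmembrane deltas compare region
#' counts; a localization switch is any label difference. Query-side TM
#' counts and localization labels come from precomputed tables
#' (`query_tm`, `query_loc`: `data.frame(id, value)` keyed by ORF id), as
#' do the reference-side annotations (keyed by protein id).
#'
#' @param orf An `OrfRecord` (with `best_reference_hit` resolved or `NA`).
#' @param proteome Named character vector (or `AAStringSet`) of reference
#'   protein sequences.
#' @param ref_domains `data.frame(protein, domain_id)` for the reference.
#' @param ref_tm `data.frame(protein, tm_count)` or `NULL`.
#' @param ref_loc `data.frame(protein, label)` or `NULL`.
#' @param query_tm,query_loc Query-side annotation tables or `NULL`.
#' @param novel_identity Identity threshold in percent.
#' @return List: `identity_pct`, `novel_protein`, `domains_gained`,
#'   `domains_lost`, `tm_gained`, `tm_lost`, `localization_switch`.
#' @export
compare_to_reference <- function(orf, proteome, ref_domains = NULL,
                                 ref_tm = NULL, ref_loc = NULL,
                                 query_tm = NULL, query_loc = NULL,
                                 novel_identity = 99) {
  hit <- orf$best_reference_hit
  if (is.na(hit) || !(hit %in% names(proteome))) {
    return(list(identity_pct = NA_real_, novel_protein = TRUE,
                domains_gained = orf$domain_set,
                domains_lost = character(0),
                tm_gained = NA_integer_, tm_lost = NA_integer_,
                localization_switch = NA))
  }
  refseq <- as.character(proteome[[hit]])
  idy <- global_identity(orf$protein_seq, refseq)
  rdom <- if (!is.null(ref_domains))
    sort(unique(ref_domains$domain_id[ref_domains$protein == hit]))
  else character(0)
  qtm <- orf$tm_region_count
  if (!is.null(query_tm) && orf$orf_id %in% query_tm$id)
    qtm <- query_tm$value[match(orf$orf_id, query_tm$id)]
  rtm <- if (!is.null(ref_tm) && hit %in% ref_tm$protein)
    ref_tm$tm_count[match(hit, ref_tm$protein)] else NA_integer_
  qloc <- orf$localization
  if (!is.null(query_loc) && orf$orf_id %in% query_loc$id)
    qloc <- query_loc$value[match(orf$orf_id, query_loc$id)]
  rloc <- if (!is.null(ref_loc) && hit %in% ref_loc$protein)
    ref_loc$label[match(hit, ref_loc$protein)] else NA_character_
  list(identity_pct = idy,
       novel_protein = idy < novel_identity,
       domains_gained = setdiff(orf$domain_set, rdom),
       domains_lost = setdiff(rdom, orf$domain_set),
       tm_gained = if (is.na(rtm)) NA_integer_ else max(0L, qtm - rtm),
       tm_lost = if (is.na(rtm)) NA_integer_ else max(0L, rtm - qtm),
       localization_switch = if (is.na(rloc) || is.na(qloc)) NA
       else !identical(qloc, rloc))
}

#' Nonsense-mediated decay prediction (55-nt rule)
#'
#' A transcript is predicted NMD-sensitive when its stop codon lies in a
#' non-terminal exon *and* more than 55 nt upstream of the last splice
#' junction, both measured in transcript coordinates with the stop-codon
#' position taken as the first base of the stop codon. Mono-exon
#' transcripts and ORFs without a stop codon are never NMD-sensitive.
#'
#' @param orf An `OrfRecord` (transcript coordinates).
#' @param tx The `TranscriptModel` carrying the ORF.
#' @param min_distance Distance threshold in nt (default 55, strict `>`).
#' @return Logical.
#' @export
predict_nmd <- function(orf, tx, min_distance = 55L) {
  total <- spliced_length(tx)
  if (orf$orf_stop > total) stop("ORF extends past transcript end")
  if (nrow(tx$exons) < 2L || !isTRUE(orf$has_stop)) return(FALSE)
  term_len <- if (tx$strand == "+") {
    tx$exons[nrow(tx$exons), 2L] - tx$exons[nrow(tx$exons), 1L]
  } else {
    tx$exons[1L, 2L] - tx$exons[1L, 1L]
  }
  last_junction <- total - term_len
  stop_first <- orf$orf_stop - 3L
  stop_first < last_junction && (last_junction - stop_first) > min_distance
}

#' Classify a peptide by its mapping across long-read ORFs and the
#' reference proteome
#'
#' Exact substring matching: `unique_PacBio` — one long-read ORF, no
#' reference protein; `non_unique_PacBio` — several long-read ORFs of one
#' gene, no reference; `nonunique_PacBio_UniProt` — both a long-read ORF
#' and a reference protein; `multigene` — long-read ORFs of more than one
#' gene (takes precedence). A peptide matching only the reference (no
#' long-read ORF) falls outside the four classes and returns `NA`.
#'
#' @param peptide Amino-acid string (length `>= 6`, else an error).
#' @param orf_db Named character vector of long-read ORF protein sequences.
#' @param orf_gene Named character vector mapping ORF ids to gene ids.
#' @param reference_proteome Named character vector of reference proteins.
#' @return One of `"unique_PacBio"`, `"non_unique_PacBio"`,
#'   `"nonunique_PacBio_UniProt"`, `"multigene"`, or `NA`.
#' @export
classify_peptide <- function(peptide, orf_db, orf_gene, reference_proteome) {
  if (nchar(peptide) < 6L) stop("peptide shorter than 6 aa rejected")
  fl <- names(orf_db)[vapply(orf_db, function(p)
    grepl(peptide, p, fixed = TRUE), TRUE)]
  nref <- sum(vapply(reference_proteome, function(p)
    grepl(peptide, p, fixed = TRUE), TRUE))
  if (length(fl) == 0L) return(NA_character_)
  genes <- unique(orf_gene[fl])
  if (length(genes) > 1L) return("multigene")
  if (nref > 0L) return("nonunique_PacBio_UniProt")
  if (length(fl) == 1L) "unique_PacBio" else "non_unique_PacBio"
}

#' Derive ribosome-occupancy translation cutoffs from housekeeping ORFs
#'
#' Finds the largest `(f1_cutoff, pme_cutoff)` pair — maximizing their sum
#' over the grid of observed housekeeping metric values, ties broken by
#' larger f1 — such that at least `target_frac` of the single-ORF
#' housekeeping ORFs with Ribo-seq coverage `>= min_reads` satisfy
#' `f1 >= f1_cutoff` and `pme >= pme_cutoff`.
#'
#' @param metrics `data.frame(orf_id, f1, pme, reads)` of ribosome
#'   occupancy periodicity (f1), uniformity (pme) and read counts.
#' @param housekeeping_ids Character vector of housekeeping ORF ids
#'   (must be non-empty and present in `metrics`).
#' @param target_frac Fraction of housekeeping ORFs that must classify as
#'   translated (default 0.8).
#' @param min_reads Minimum Ribo-seq read count (default 10).
#' @return A `TranslationCutoffs` list: `f1_cutoff`, `pme_cutoff`,
#'   `min_reads`.
#' @export
derive_translation_cutoffs <- function(metrics, housekeeping_ids,
                                       target_frac = 0.8, min_reads = 10L) {
  hk <- metrics[metrics$orf_id %in% housekeeping_ids, , drop = FALSE]
  if (nrow(hk) == 0L) stop("no housekeeping ORFs present in metrics")
  hk <- hk[hk$reads >= min_reads, , drop = FALSE]
  if (nrow(hk) == 0L)
    stop("no housekeeping ORF reaches the read-count floor")
  gf <- sort(unique(hk$f1)); gp <- sort(unique(hk$pme))
  # count(a, b) = number of housekeeping ORFs with f1 >= a and pme >= b
  A <- outer(gf, hk$f1, "<=")
  B <- outer(gp, hk$pme, "<=")
  cnt <- A %*% t(B)
  ok <- cnt / nrow(hk) >= target_frac
  if (!any(ok)) stop("target fraction unattainable on the observed grid")
  idx <- which(ok, arr.ind = TRUE)
  score <- gf[idx[, 1L]] + gp[idx[, 2L]]
  best <- idx[order(-score, -gf[idx[, 1L]])[1L], ]
  structure(list(f1_cutoff = gf[best[1L]], pme_cutoff = gp[best[2L]],
                 min_reads = as.integer(min_reads)),
            class = "TranslationCutoffs")
}

#' Call actively translated ORFs
#'
#' An ORF is translated when `f1 >= f1_cutoff`, `pme >= pme_cutoff` and its
#' Ribo-seq coverage is at least `min_reads`.
#'
#' @param metrics `data.frame(orf_id, f1, pme, reads)`.
#' @param cutoffs A `TranslationCutoffs` from
#'   [derive_translation_cutoffs()].
#' @return Named logical vector over `metrics$orf_id`.
#' @export
classify_translated <- function(metrics, cutoffs) {
  stats::setNames(metrics$f1 >= cutoffs$f1_cutoff &
                    metrics$pme >= cutoffs$pme_cutoff &
                    metrics$reads >= cutoffs$min_reads,
                  metrics$orf_id)
}
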