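#' Extract local alternative-splicing events from a transcript catalog
#'
#' Detects the seven classic local event types from the exon chains of a
#' gene's transcripts, in the style of transcriptome-based event
#' generators:
#'
#' * **SE** (skipped exon) — an internal exon bounded by two junctions whose
#'   direct skip junction also exists in the gene;
#' * **MX** (mutually exclusive exons) — two non-overlapping internal exons
#'   sharing both outer flanking boundaries, never co-occurring in one
#'   transcript;
#' * **A5SS / A3SS** — two junctions sharing one boundary and differing at
#'   the other by more than `local_threshold` bp, where the variant
#'   boundaries are alternative ends of overlapping exons (variants within
#'   the threshold are merged, not called alternative);
#' * **RI** (retained intron) — an intron flanked by exons `(s1,d)` and
#'   `(a,e2)` in one transcript while another transcript carries the single
#'   exon `(s1,e2)`;
#' * **AF / AL** (alternative first / last exon) — distinct first (last)
#'   exons splicing to the same shared boundary, called alternative when
#'   their genomic spans overlap by at most `af_al_threshold` bp.
#'
#' Inclusion-form conventions: SE/RI — the exon-containing (intron-
#' retaining) form; A5/A3 — the shorter-intron (extended-exon) form; MX —
#' the genomically 5'-most exon; AF/AL — the more distal end. Events are
#' deduplicated genome-wide by (gene, type, coordinates); extraction is a
#' pure function of the annotation, independent of transcript order.
#'
#' @param transcripts List of `TranscriptModel` grouped by their `gene_id`.
#' @param af_al_threshold Overlap threshold (bp) above which first/last
#'   exon variants are merged (default 250).
#' @param local_threshold Boundary tolerance (bp) for the local event
#'   types (default 10).
#' @return List of `AsEvent` records (`event_id`, `gene_id`, `event_type`,
#'   `chrom`, `strand`, `coordinates`, `inclusion_transcripts`,
#'   `exclusion_transcripts`).
#' @export
extract_events <- function(transcripts, af_al_threshold = 250L,
                           local_threshold = 10L) {
  gids <- vapply(transcripts, function(t) t$gene_id, "")
  out <- list()
  for (g in sort(unique(gids))) {
    txs <- transcripts[gids == g]
    txs <- txs[order(vapply(txs, function(t) t$transcript_id, ""))]
    if (length(txs) < 2L) next
    out <- c(out, .gene_events(g, txs, af_al_threshold, local_threshold))
  }
  # dedupe by event id, deterministic order
  ids <- vapply(out, function(e) e$event_id, "")
  out <- out[!duplicated(ids)]
  out[order(vapply(out, function(e) e$event_id, ""))]
}

.as_event <- function(gene, type, chrom, strand, coords, incl, excl) {
  id <- sprintf("%s;%s:%s:%s:%s", gene, type, chrom,
                paste(coords, collapse = "-"), strand)
  structure(list(event_id = id, gene_id = gene, event_type = type,
                 chrom = chrom, strand = strand,
                 coordinates = as.integer(coords),
                 inclusion_transcripts = sort(unname(incl)),
                 exclusion_transcripts = sort(unname(excl))),
            class = "AsEvent")
}

.gene_events <- function(gene, txs, af_al_threshold, local_threshold) {
  chrom <- txs[[1L]]$chrom; strand <- txs[[1L]]$strand
  ids <- vapply(txs, function(t) t$transcript_id, "")
  ex <- lapply(txs, function(t) t$exons)
  jn <- lapply(txs, junctions)
  jkey <- lapply(jn, function(j) paste(j[, 1L], j[, 2L], sep = "-"))
  ekey <- lapply(ex, function(e) paste(e[, 1L], e[, 2L], sep = "-"))
  has_j <- function(d, a) vapply(jkey, function(k)
    paste(d, a, sep = "-") %in% k, TRUE)
  has_e <- function(s, e) vapply(ekey, function(k)
    paste(s, e, sep = "-") %in% k, TRUE)
  all_j <- unique(do.call(rbind, jn))
  events <- list()

  # --- internal-exon tuples (d, es, ee, a) for SE and MX ----------------
  tuples <- NULL
  for (t in seq_along(txs)) {
    e <- ex[[t]]; n <- nrow(e)
    if (n < 3L) next
    for (i in 2:(n - 1L)) {
      tuples <- rbind(tuples, c(e[i - 1L, 2L], e[i, 1L], e[i, 2L],
                                e[i + 1L, 1L]))
    }
  }
  if (!is.null(tuples)) tuples <- unique(tuples)

  # SE: skip junction (d, a) exists
  if (!is.null(tuples)) for (r in seq_len(nrow(tuples))) {
    d <- tuples[r, 1L]; es <- tuples[r, 2L]; ee <- tuples[r, 3L]
    a <- tuples[r, 4L]
    skip <- has_j(d, a)
    if (!any(skip)) next
    incl <- has_j(d, es) & has_j(ee, a)
    events <- c(events, list(.as_event(gene, "SE", chrom, strand,
                                       c(d, es, ee, a),
                                       ids[incl], ids[skip])))
  }

  # MX: two non-overlapping internal exons sharing both outer flanks
  if (!is.null(tuples) && nrow(tuples) >= 2L) {
    for (r1 in seq_len(nrow(tuples) - 1L)) for (r2 in (r1 + 1L):nrow(tuples)) {
      if (tuples[r1, 1L] != tuples[r2, 1L] ||
          tuples[r1, 4L] != tuples[r2, 4L]) next
      e1 <- tuples[r1, 2:3]; e2 <- tuples[r2, 2:3]
      if (e1[1L] > e2[1L]) { tmp <- e1; e1 <- e2; e2 <- tmp }
      if (e1[2L] > e2[1L]) next              # exons overlap -> not MX
      d <- tuples[r1, 1L]; a <- tuples[r1, 4L]
      in1 <- has_j(d, e1[1L]) & has_j(e1[2L], a)
      in2 <- has_j(d, e2[1L]) & has_j(e2[2L], a)
      if (any(in1 & in2)) next               # co-occur -> not exclusive
      if (!any(in1) || !any(in2)) next
      events <- c(events, list(.as_event(gene, "MX", chrom, strand,
                                         c(d, e1, e2, a),
                                         ids[in1], ids[in2])))
    }
  }

  # A5/A3: junction pairs sharing one boundary; variant boundaries must be
  # alternative ends of overlapping exons and differ by > local_threshold
  if (nrow(all_j) >= 2L) {
    exons_ending <- function(pos) {
      m <- do.call(rbind, lapply(seq_along(txs), function(t) {
        e <- ex[[t]]
        e[e[, 2L] == pos, , drop = FALSE]
      }))
      unique(m)
    }
    exons_starting <- function(pos) {
      m <- do.call(rbind, lapply(seq_along(txs), function(t) {
        e <- ex[[t]]
        e[e[, 1L] == pos, , drop = FALSE]
      }))
      unique(m)
    }
    overlap_any <- function(m1, m2) {
      if (is.null(m1) || is.null(m2) || nrow(m1) == 0L || nrow(m2) == 0L)
        return(FALSE)
      for (i in seq_len(nrow(m1))) for (j in seq_len(nrow(m2))) {
        if (m1[i, 1L] < m2[j, 2L] && m2[j, 1L] < m1[i, 2L]) return(TRUE)
      }
      FALSE
    }
    for (r1 in seq_len(nrow(all_j) - 1L)) for (r2 in (r1 + 1L):nrow(all_j)) {
      j1 <- all_j[r1, ]; j2 <- all_j[r2, ]
      if (j1[2L] == j2[2L] && j1[1L] != j2[1L]) {
        # shared intron end, variant intron start (exon ends)
        dmin <- min(j1[1L], j2[1L]); dmax <- max(j1[1L], j2[1L])
        if (dmax - dmin <= local_threshold) next
        if (!overlap_any(exons_ending(dmin), exons_ending(dmax))) next
        type <- if (strand == "+") "A5SS" else "A3SS"
        # inclusion: shorter intron = larger variant start
        incl <- has_j(dmax, j1[2L]); excl <- has_j(dmin, j1[2L])
        events <- c(events, list(.as_event(gene, type, chrom, strand,
                                           c(dmax, j1[2L], dmin, j1[2L]),
                                           ids[incl], ids[excl])))
      } else if (j1[1L] == j2[1L] && j1[2L] != j2[2L]) {
        # shared intron start, variant intron end (exon starts)
        amin <- min(j1[2L], j2[2L]); amax <- max(j1[2L], j2[2L])
        if (amax - amin <= local_threshold) next
        if (!overlap_any(exons_starting(amin), exons_starting(amax))) next
        type <- if (strand == "+") "A3SS" else "A5SS"
        incl <- has_j(j1[1L], amin); excl <- has_j(j1[1L], amax)
        events <- c(events, list(.as_event(gene, type, chrom, strand,
                                           c(j1[1L], amin, j1[1L], amax),
                                           ids[incl], ids[excl])))
      }
    }
  }

  # RI: exon (s1, e2) spanning an intron (d, a) with matching flank exons
  for (t in seq_along(txs)) {
    e <- ex[[t]]; n <- nrow(e)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      s1 <- e[i, 1L]; d <- e[i, 2L]; a <- e[i + 1L, 1L]; e2 <- e[i + 1L, 2L]
      ret <- has_e(s1, e2)
      if (!any(ret)) next
      spliced <- has_e(s1, d) & has_e(a, e2) & has_j(d, a)
      events <- c(events, list(.as_event(gene, "RI", chrom, strand,
                                         c(s1, d, a, e2),
                                         ids[ret], ids[spliced])))
    }
  }

  # AF/AL: distinct terminal exons sharing the adjacent boundary
  multi <- which(vapply(ex, nrow, 0L) >= 2L)
  if (length(multi) >= 2L) {
    term <- function(t, which_end) {
      e <- ex[[t]]; n <- nrow(e)
      first_genomic_left <- (txs[[t]]$strand == "+") == (which_end == "first")
      if (first_genomic_left)
        c(shared = e[2L, 1L], s = e[1L, 1L], e = e[1L, 2L])
      else
        c(shared = e[n - 1L, 2L], s = e[n, 1L], e = e[n, 2L])
    }
    for (we in c("first", "last")) {
      type <- if (we == "first") "AF" else "AL"
      tab <- t(vapply(multi, term, c(shared = 0L, s = 0L, e = 0L),
                      which_end = we))
      rownames(tab) <- ids[multi]
      for (sh in unique(tab[, "shared"])) {
        sub <- tab[tab[, "shared"] == sh, , drop = FALSE]
        vars <- unique(sub[, c("s", "e"), drop = FALSE])
        if (nrow(vars) < 2L) next
        for (v1 in seq_len(nrow(vars) - 1L)) for (v2 in (v1 + 1L):nrow(vars)) {
          a1 <- vars[v1, ]; a2 <- vars[v2, ]
          ov <- min(a1["e"], a2["e"]) - max(a1["s"], a2["s"])
          if (ov > af_al_threshold) next     # merged variant, not alternative
          # distal variant = farther from the gene body in transcript 5'(3')
          left_is_distal <- (strand == "+") == (we == "first")
          # same distal boundary = splice-site variability, not an
          # alternative first/last exon (that is an A5/A3 event)
          if (left_is_distal && a1["s"] == a2["s"]) next
          if (!left_is_distal && a1["e"] == a2["e"]) next
          d1 <- if (left_is_distal) -a1["s"] else a1["e"]
          d2 <- if (left_is_distal) -a2["s"] else a2["e"]
          if (d2 > d1) { tmp <- a1; a1 <- a2; a2 <- tmp }
          m1 <- sub[, "s"] == a1["s"] & sub[, "e"] == a1["e"]
          m2 <- sub[, "s"] == a2["s"] & sub[, "e"] == a2["e"]
          events <- c(events, list(.as_event(gene, type, chrom, strand,
                                             c(a1["s"], a1["e"], a2["s"],
                                               a2["e"], sh),
                                             rownames(sub)[m1],
                                             rownames(sub)[m2])))
        }
      }
    }
  }

  Filter(function(e) length(e$inclusion_transcripts) > 0L &&
           length(e$exclusion_transcripts) > 0L &&
           !length(intersect(e$inclusion_transcripts,
                             e$exclusion_transcripts)),
         events)
}

#' @export
print.AsEvent <- function(x, ...) {
  cat(sprintf("AsEvent %s [%s] incl={%s} excl={%s}\n", x$event_id,
              x$event_type,
              paste(x$inclusion_transcripts, collapse = ","),
              paste(x$exclusion_transcripts, collapse = ",")))
  invisible(x)
}

#' Percent-spliced-in quantification from transcript abundances
#'
#' `PSI = sum TPM(inclusion) / (sum TPM(inclusion) + sum TPM(exclusion))`,
#' per sample; the value is masked (`NA`) when the denominator falls below
#' `min_total_tpm`. PSI is invariant to per-sample rescaling of the TPM
#' matrix (up to the masking rule).
#'
#' @param events List of `AsEvent` from [extract_events()].
#' @param tpm Numeric matrix, transcripts (rows, named) x samples
#'   (columns, named); all event transcripts must be present and no entry
#'   may be negative.
#' @param min_total_tpm Masking threshold on the event's total abundance
#'   (default 1.0; 0 masks only zero-total samples).
#' @return A `PsiMatrix` list: `psi` (events x samples), `total` (the
#'   denominator matrix), `events`.
#' @export
compute_psi <- function(events, tpm, min_total_tpm = 1.0) {
  if (any(tpm < 0)) stop("negative TPM")
  need <- unique(unlist(lapply(events, function(e)
    c(e$inclusion_transcripts, e$exclusion_transcripts))))
  miss <- setdiff(need, rownames(tpm))
  if (length(miss))
    stop("event transcripts absent from TPM matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  ids <- vapply(events, function(e) e$event_id, "")
  psi <- matrix(NA_real_, length(events), ncol(tpm),
                dimnames = list(ids, colnames(tpm)))
  tot <- psi
  for (i in seq_along(events)) {
    inc <- colSums(tpm[events[[i]]$inclusion_transcripts, , drop = FALSE])
    exc <- colSums(tpm[events[[i]]$exclusion_transcripts, , drop = FALSE])
    denom <- inc + exc
    v <- ifelse(denom < min_total_tpm | denom == 0, NA_real_, inc / denom)
    psi[i, ] <- v
    tot[i, ] <- denom
  }
  structure(list(psi = psi, total = tot, events = events),
            class = "PsiMatrix")
}

#' Write events in an ioe-style table
#'
#' One row per event: `event_id`, `gene_id`, `event_type`,
#' `inclusion_transcripts`, `total_transcripts` (comma-separated).
#'
#' @param events List of `AsEvent`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_events_ioe <- function(events, path) {
  d <- data.frame(
    event_id = vapply(events, function(e) e$event_id, ""),
    gene_id = vapply(events, function(e) e$gene_id, ""),
    event_type = vapply(events, function(e) e$event_type, ""),
    inclusion_transcripts = vapply(events, function(e)
      paste(e$inclusion_transcripts, collapse = ","), ""),
    total_transcripts = vapply(events, function(e)
      paste(sort(c(e$inclusion_transcripts, e$exclusion_transcripts)),
            collapse = ","), ""),
    stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
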