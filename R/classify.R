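#' @title Structural categories
#' @description The eight SQANTI-style structural categories a query isoform
#'   can receive relative to the reference annotation.
#' @format Character vector of category labels.
#' @export
STRUCTURAL_CATEGORIES <- c("FSM", "ISM", "NIC", "NNC",
                           "ANTISENSE", "INTERGENIC", "FUSION", "GENIC")

# is `sub` (m x 2) a consecutive window of `full` (n x 2), m < n?
.is_consecutive_subchain <- function(sub, full) {
  m <- nrow(sub); n <- nrow(full)
  if (m == 0L || m >= n) return(FALSE)
  for (i in seq_len(n - m + 1L)) {
    if (all(full[i:(i + m - 1L), ] == sub)) return(TRUE)
  }
  FALSE
}

.structural_call <- function(tx, category, assigned_gene = NA_character_,
                             matched = NA_character_,
                             novel_junctions = NULL,
                             novel_splice_sites = integer(0)) {
  if (is.null(novel_junctions))
    novel_junctions <- matrix(integer(0), ncol = 2L,
                              dimnames = list(NULL, c("donor_pos", "acceptor_pos")))
  structure(list(transcript_id = tx$transcript_id, category = category,
                 assigned_gene = assigned_gene,
                 matched_reference_transcript = matched,
                 novel_junctions = novel_junctions,
                 novel_splice_sites = as.integer(novel_splice_sites)),
            class = "StructuralCall")
}

#' @export
print.StructuralCall <- function(x, ...) {
  cat(sprintf("StructuralCall %s: %s (gene %s%s)\n", x$transcript_id,
              x$category, x$assigned_gene,
              if (!is.na(x$matched_reference_transcript))
                paste0(", matches ", x$matched_reference_transcript) else ""))
  invisible(x)
}

#' Classify a query transcript against the reference
#'
#' Assigns one structural category by comparing the query's splice-junction
#' chain to the reference annotation:
#'
#' * **FSM** (full-splice match) — the ordered junction chain equals some
#'   reference transcript's full chain;
#' * **ISM** (incomplete splice match) — the chain equals a *consecutive*
#'   sub-chain of some reference transcript (a non-consecutive subset is
#'   NIC);
#' * **NIC** (novel in catalog) — every splice donor and acceptor (or every
#'   junction individually) is annotated for the assigned gene, but the
#'   chain as a whole is new;
#' * **NNC** (novel not in catalog) — at least one donor or acceptor is not
#'   annotated for the assigned gene;
#' * **FUSION** — the query's junctions span two or more same-strand genes
#'   whose annotated bodies do not overlap each other;
#' * **ANTISENSE** — gene-body overlap only on the opposite strand;
#' * **INTERGENIC** — no gene-body overlap at all;
#' * **GENIC** — mono-exon query inside a same-strand gene that matches no
#'   rule above.
#'
#' Junction identity is exact (`±0` bp). Mono-exon queries follow separate
#' rules: FSM if both ends are within `mono_end_tol` of a mono-exon
#' reference transcript's ends, ISM if fully contained in a reference exon,
#' then GENIC / ANTISENSE / INTERGENIC by overlap.
#'
#' @param query A `TranscriptModel`.
#' @param ref A `ReferenceIndex` from [build_reference_index()].
#' @param mono_end_tol End tolerance (bp) for mono-exon FSM calls.
#' @param site_scope `"gene"` (default) evaluates donor/acceptor novelty
#'   against the assigned gene's site sets; `"genome"` against the union of
#'   all genes.
#' @return A `StructuralCall` with the category, assigned gene, matched
#'   reference transcript (FSM/ISM only), the query junctions absent from
#'   the assigned gene's junction set, and any unannotated splice-site
#'   positions.
#' @export
classify_transcript <- function(query, ref, mono_end_tol = 50L,
                                site_scope = c("gene", "genome")) {
  site_scope <- match.arg(site_scope)
  if (nrow(query$exons) == 0L) stop("query has zero exons")
  if (nrow(query$exons) == 1L)
    return(.classify_mono_exon(query, ref, mono_end_tol))

  qj <- junctions(query)
  qkey <- junction_chain_key(query)
  same_cs <- Filter(function(t) t$chrom == query$chrom && t$strand == query$strand,
                    ref$transcripts)

  # FSM: exact full-chain match (ties broken by transcript id)
  hits <- names(same_cs)[vapply(same_cs, function(t)
    junction_chain_key(t) == qkey, TRUE)]
  if (length(hits)) {
    m <- sort(hits)[1L]
    return(.structural_call(query, "FSM",
                            assigned_gene = ref$transcripts[[m]]$gene_id,
                            matched = m))
  }

  # ISM: consecutive sub-chain of a longer reference chain
  hits <- names(same_cs)[vapply(same_cs, function(t)
    .is_consecutive_subchain(qj, junctions(t)), TRUE)]
  if (length(hits)) {
    m <- sort(hits)[1L]
    return(.structural_call(query, "ISM",
                            assigned_gene = ref$transcripts[[m]]$gene_id,
                            matched = m))
  }

  genes <- overlapping_genes(ref, query, same_strand = TRUE)
  if (length(genes) == 0L) {
    anti <- overlapping_genes(ref, query, same_strand = FALSE)
    return(.structural_call(query,
                            if (length(anti)) "ANTISENSE" else "INTERGENIC"))
  }

  # FUSION: junctions bridge >= 2 genes with mutually disjoint bodies
  if (length(genes) >= 2L) {
    bodies <- lapply(ref$genes[genes], function(g) g$body)
    disjoint <- TRUE
    for (i in seq_along(bodies)) for (j in seq_len(i - 1L)) {
      if (bodies[[i]]["start"] < bodies[[j]]["end"] &&
          bodies[[j]]["start"] < bodies[[i]]["end"]) disjoint <- FALSE
    }
    if (disjoint)
      return(.structural_call(query, "FUSION",
                              assigned_gene = paste(sort(genes), collapse = "+")))
  }

  ov <- vapply(genes, function(g) exonic_overlap_bp(ref, query, g), 0)
  gene <- sort(genes[ov == max(ov)])[1L]
  gi <- ref$genes[[gene]]
  if (site_scope == "genome") {
    donors <- sort(unique(unlist(lapply(ref$genes, function(g)
      if (g$strand == query$strand && g$chrom == query$chrom) g$donors))))
    acceptors <- sort(unique(unlist(lapply(ref$genes, function(g)
      if (g$strand == query$strand && g$chrom == query$chrom) g$acceptors))))
    jk <- sort(unique(unlist(lapply(ref$genes, function(g)
      if (g$strand == query$strand && g$chrom == query$chrom) g$junction_keys))))
  } else {
    donors <- gi$donors; acceptors <- gi$acceptors; jk <- gi$junction_keys
  }

  qkeys <- junction_keys(query)
  novel_j <- qj[!(qkeys %in% jk), , drop = FALSE]
  novel_sites <- sort(unique(c(qj[!(qj[, 1L] %in% donors), 1L],
                               qj[!(qj[, 2L] %in% acceptors), 2L])))
  if (length(novel_sites))
    return(.structural_call(query, "NNC", assigned_gene = gene,
                            novel_junctions = novel_j,
                            novel_splice_sites = novel_sites))
  .structural_call(query, "NIC", assigned_gene = gene,
                   novel_junctions = novel_j)
}

.classify_mono_exon <- function(query, ref, mono_end_tol) {
  span <- transcript_span(query)
  same_cs <- Filter(function(t) t$chrom == query$chrom && t$strand == query$strand,
                    ref$transcripts)
  mono_refs <- Filter(function(t) nrow(t$exons) == 1L, same_cs)
  hits <- names(mono_refs)[vapply(mono_refs, function(t) {
    s <- transcript_span(t)
    abs(s["start"] - span["start"]) <= mono_end_tol &&
      abs(s["end"] - span["end"]) <= mono_end_tol
  }, TRUE)]
  if (length(hits)) {
    m <- sort(hits)[1L]
    return(.structural_call(query, "FSM",
                            assigned_gene = ref$transcripts[[m]]$gene_id,
                            matched = m))
  }
  # contained within any annotated exon -> ISM fragment
  hits <- names(same_cs)[vapply(same_cs, function(t)
    any(t$exons[, 1L] <= span["start"] & t$exons[, 2L] >= span["end"]), TRUE)]
  if (length(hits)) {
    m <- sort(hits)[1L]
    return(.structural_call(query, "ISM",
                            assigned_gene = ref$transcripts[[m]]$gene_id,
                            matched = m))
  }
  genes <- overlapping_genes(ref, query, same_strand = TRUE)
  if (length(genes)) {
    ov <- vapply(genes, function(g) exonic_overlap_bp(ref, query, g), 0)
    return(.structural_call(query, "GENIC",
                            assigned_gene = sort(genes[ov == max(ov)])[1L]))
  }
  anti <- overlapping_genes(ref, query, same_strand = FALSE)
  .structural_call(query, if (length(anti)) "ANTISENSE" else "INTERGENIC")
}

#' Classify a full query catalog
#'
#' Applies [classify_transcript()] to every query and tabulates category
#' counts. The result is independent of query order.
#'
#' @inheritParams classify_transcript
#' @param queries List of `TranscriptModel`.
#' @return List with `calls` (named list of `StructuralCall`), `summary`
#'   (named integer vector over all categories, summing to the number of
#'   queries), and `table` (a per-transcript `data.frame`).
#' @export
classify_catalog <- function(queries, ref, mono_end_tol = 50L,
                             site_scope = c("gene", "genome")) {
  site_scope <- match.arg(site_scope)
  calls <- lapply(queries, classify_transcript, ref = ref,
                  mono_end_tol = mono_end_tol, site_scope = site_scope)
  names(calls) <- vapply(calls, function(x) x$transcript_id, "")
  cats <- factor(vapply(calls, function(x) x$category, ""),
                 levels = STRUCTURAL_CATEGORIES)
  tab <- data.frame(
    transcript_id = names(calls),
    category = as.character(cats),
    assigned_gene = vapply(calls, function(x) x$assigned_gene, ""),
    matched_transcript = vapply(calls, function(x) x$matched_reference_transcript, ""),
    n_novel_junctions = vapply(calls, function(x) nrow(x$novel_junctions), 0L),
    n_novel_sites = vapply(calls, function(x) length(x$novel_splice_sites), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  list(calls = calls,
       summary = stats::setNames(as.integer(table(cats)), STRUCTURAL_CATEGORIES),
       table = tab)
}
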