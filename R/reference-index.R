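#' Build the reference annotation index
#'
#' Precomputes, from a list of reference transcripts, everything the
#' structural classifier and QC filters look up: per-gene donor / acceptor /
#' junction sets, the set of full junction chains, gene bodies as a
#' strand-aware interval index, and the genome-wide TSS / TTS sets.
#'
#' @param transcripts Named list of `TranscriptModel`, each carrying a
#'   non-empty `gene_id`.
#' @return A `ReferenceIndex` object.
#' @examples
#' ref <- build_reference_index(list(
#'   transcript_model("t1", "g1", "chr1", "+",
#'                    cbind(c(100L, 300L), c(200L, 400L)))))
#' ref$genes$g1$junction_keys   # "chr1:200:300:+"
#' @export
build_reference_index <- function(transcripts) {
  ids <- vapply(transcripts, function(t) t$transcript_id, "")
  if (anyDuplicated(ids))
    stop("duplicate transcript_id in reference: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gids <- vapply(transcripts, function(t) t$gene_id, "")
  if (any(!nzchar(gids))) stop("reference transcripts must carry gene_id")
  names(transcripts) <- ids

  genes <- list()
  for (g in unique(gids)) {
    txs <- transcripts[gids == g]
    chrom <- txs[[1L]]$chrom; strand <- txs[[1L]]$strand
    if (!all(vapply(txs, function(t) t$chrom == chrom && t$strand == strand, TRUE)))
      stop("gene '", g, "': transcripts on multiple chroms/strands")
    jn <- lapply(txs, junctions)
    donors <- sort(unique(unlist(lapply(jn, function(j) j[, 1L]))))
    acceptors <- sort(unique(unlist(lapply(jn, function(j) j[, 2L]))))
    jkeys <- sort(unique(unlist(lapply(txs, junction_keys))))
    chains <- vapply(txs, junction_chain_key, "")
    span <- range(unlist(lapply(txs, function(t) as.vector(t$exons))))
    genes[[g]] <- list(
      gene_id = g, chrom = chrom, strand = strand,
      transcripts = txs,
      donors = as.integer(donors), acceptors = as.integer(acceptors),
      junction_keys = jkeys, chains = chains,
      body = c(start = span[1L], end = span[2L]))
  }

  body_gr <- GenomicRanges::GRanges(
    vapply(genes, function(g) g$chrom, ""),
    IRanges::IRanges(vapply(genes, function(g) g$body[["start"]], 0L) + 1L,
                     vapply(genes, function(g) g$body[["end"]], 0L)),
    strand = vapply(genes, function(g) g$strand, ""),
    gene_id = names(genes))

  tss_tbl <- data.frame(
    chrom = vapply(transcripts, function(t) t$chrom, ""),
    strand = vapply(transcripts, function(t) t$strand, ""),
    pos = vapply(transcripts, tss, 0L), stringsAsFactors = FALSE)
  tts_tbl <- data.frame(
    chrom = vapply(transcripts, function(t) t$chrom, ""),
    strand = vapply(transcripts, function(t) t$strand, ""),
    pos = vapply(transcripts, tts, 0L), stringsAsFactors = FALSE)

  structure(list(transcripts = transcripts, genes = genes,
                 gene_bodies = body_gr,
                 tss = unique(tss_tbl), tts = unique(tts_tbl)),
            class = "ReferenceIndex")
}

#' @export
print.ReferenceIndex <- function(x, ...) {
  cat(sprintf("ReferenceIndex: %d transcripts in %d genes\n",
              length(x$transcripts), length(x$genes)))
  invisible(x)
}

# gene ids whose bodies overlap the query's exons, per strand relation
overlapping_genes <- function(ref, tx, same_strand = TRUE) {
  q <- GenomicRanges::GRanges(
    tx$chrom, IRanges::IRanges(tx$exons[, 1L] + 1L, tx$exons[, 2L]),
    strand = tx$strand)
  if (!same_strand) GenomicRanges::strand(q) <- ifelse(tx$strand == "+", "-", "+")
  hits <- GenomicRanges::findOverlaps(q, ref$gene_bodies, ignore.strand = FALSE)
  unique(S4Vectors::mcols(ref$gene_bodies)$gene_id[S4Vectors::subjectHits(hits)])
}

# exonic overlap in bp between a query transcript and a gene's annotated exons
exonic_overlap_bp <- function(ref, tx, gene_id) {
  g <- ref$genes[[gene_id]]
  gex <- unique(do.call(rbind, lapply(g$transcripts, function(t) t$exons)))
  q <- IRanges::IRanges(tx$exons[, 1L] + 1L, tx$exons[, 2L])
  s <- IRanges::reduce(IRanges::IRanges(gex[, 1L] + 1L, gex[, 2L]))
  sum(IRanges::width(IRanges::intersect(IRanges::reduce(q), s)))
}

# strand-aware distance from a transcript 3' end to the nearest annotated
# TTS on the same chrom and strand; Inf when none exists
nearest_tts_distance <- function(ref, tx) {
  tab <- ref$tts
  tab <- tab[tab$chrom == tx$chrom & tab$strand == tx$strand, , drop = FALSE]
  if (nrow(tab) == 0L) return(Inf)
  min(abs(tab$pos - tts(tx)))
}
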