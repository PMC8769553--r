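#' Read transcript models from a GTF file
#'
#' Parses `exon` (and, when present, `CDS`) features and assembles one
#' [transcript_model()] per `transcript_id`. GTF coordinates (1-based,
#' inclusive) are converted to the package's internal 0-based half-open
#' convention at this boundary. Parsing itself is delegated to
#' `rtracklayer::import()`, so any GTF dialect it accepts is accepted here.
#'
#' @param path Path to a GTF file.
#' @param attribute_keys Additional attribute names to retain; they are
#'   attached to each model as an `attributes` list entry.
#' @return Named list of `TranscriptModel` (names = transcript ids), ordered
#'   by (chrom, span start, transcript_id).
#' @seealso [write_gtf()]
#' @export
read_gtf <- function(path, attribute_keys = character(0)) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type %in% c("exon", "CDS")]
  if (length(gr) == 0L) return(list())
  txid <- S4Vectors::mcols(gr)$transcript_id
  if (is.null(txid) || anyNA(txid))
    stop("GTF '", path, "': exon/CDS feature without transcript_id")
  gid <- S4Vectors::mcols(gr)$gene_id
  if (is.null(gid)) gid <- rep("", length(gr))
  gid[is.na(gid)] <- ""
  type <- as.character(S4Vectors::mcols(gr)$type)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)

  out <- list()
  for (id in unique(txid)) {
    i <- which(txid == id)
    ex <- i[type[i] == "exon"]
    if (length(ex) == 0L)
      stop("GTF '", path, "': transcript '", id, "' has CDS but no exon features")
    if (length(unique(chrom[i])) != 1L || length(unique(strand[i])) != 1L)
      stop("GTF '", path, "': transcript '", id, "' spans multiple chroms/strands")
    cd <- i[type[i] == "CDS"]
    tx <- transcript_model(
      transcript_id = id, gene_id = gid[ex[1L]],
      chrom = chrom[ex[1L]], strand = strand[ex[1L]],
      exons = cbind(start0[ex], end0[ex]),
      cds = if (length(cd)) cbind(start0[cd], end0[cd]) else NULL)
    if (length(attribute_keys)) {
      tx$attributes <- lapply(stats::setNames(attribute_keys, attribute_keys),
                              function(k) {
                                v <- S4Vectors::mcols(gr)[[k]]
                                if (is.null(v)) NA_character_ else as.character(v[ex[1L]])
                              })
    }
    out[[id]] <- tx
  }
  ord <- order(vapply(out, function(t) t$chrom, ""),
               vapply(out, function(t) t$exons[1L, 1L], 0L),
               names(out))
  out[ord]
}

#' Write transcript models to GTF
#'
#' Emits one `exon` feature per exon (plus `CDS` features when the model
#' carries a coding region), converting back to 1-based inclusive
#' coordinates. Features are ordered by (chrom, start, transcript_id) so the
#' output is deterministic for a given input.
#'
#' @param transcripts List of `TranscriptModel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  if (length(transcripts) == 0L) {
    writeLines("##gff-version 2", path)
    return(invisible(path))
  }
  ord <- order(vapply(transcripts, function(t) t$chrom, ""),
               vapply(transcripts, function(t) t$exons[1L, 1L], 0L),
               vapply(transcripts, function(t) t$transcript_id, ""))
  transcripts <- transcripts[ord]
  rows <- lapply(transcripts, function(tx) {
    ex <- data.frame(chrom = tx$chrom, start = tx$exons[, 1L] + 1L,
                     end = tx$exons[, 2L], strand = tx$strand, type = "exon",
                     transcript_id = tx$transcript_id, gene_id = tx$gene_id,
                     stringsAsFactors = FALSE)
    if (!is.null(tx$cds) && nrow(tx$cds) > 0L) {
      cd <- data.frame(chrom = tx$chrom, start = tx$cds[, 1L] + 1L,
                       end = tx$cds[, 2L], strand = tx$strand, type = "CDS",
                       transcript_id = tx$transcript_id, gene_id = tx$gene_id,
                       stringsAsFactors = FALSE)
      ex <- rbind(ex, cd)
    }
    ex
  })
  d <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    d$chrom, IRanges::IRanges(d$start, d$end), strand = d$strand,
    source = "isomix", type = d$type,
    transcript_id = d$transcript_id, gene_id = d$gene_id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
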