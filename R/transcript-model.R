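#' Stranded genomic interval
#'
#' Internal coordinates throughout the package are 0-based, half-open
#' `[start, end)`; all standard-format I/O (GTF, BED) converts at the
#' boundary.
#'
#' @param chrom Chromosome / contig name.
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must satisfy `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return A one-row `data.frame` with columns `chrom`, `start`, `end`,
#'   `strand`.
#' @export
genomic_interval <- function(chrom, start, end, strand) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid interval: require 0 <= start < end, got [", start, ", ", end, ")")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Construct a transcript model
#'
#' A `TranscriptModel` is an exon chain on one chromosome and strand, the
#' unit consumed by the structural classifier, the QC filters, the ORF
#' annotator and the event extractor.
#'
#' @param transcript_id Transcript identifier (unique within a catalog).
#' @param gene_id Gene identifier; may be `""` for novel loci.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column integer matrix (`start`, `end`), 0-based
#'   half-open; rows are sorted by start and must be separated by at least
#'   one intronic base.
#' @param cds Optional two-column matrix of coding sub-intervals (same
#'   convention), or `NULL`.
#' @return An object of class `TranscriptModel`.
#' @examples
#' tx <- transcript_model("t1", "g1", "chr1", "+",
#'                        exons = cbind(c(100L, 300L), c(200L, 400L)))
#' n_exons(tx)       # 2
#' junctions(tx)     # one junction: (200, 300)
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds = NULL) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("transcript '", transcript_id, "' has zero exons")
  if (any(exons[, 1L] < 0L) || any(exons[, 1L] >= exons[, 2L]))
    stop("transcript '", transcript_id, "': exon with start >= end")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1L] <= exons[-nrow(exons), 2L]))
    stop("transcript '", transcript_id,
         "': exons overlap or abut (introns must be >= 1 bp)")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!is.null(cds)) {
    cds <- matrix(as.integer(cds), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
    cds <- cds[order(cds[, 1L]), , drop = FALSE]
  }
  structure(list(transcript_id = as.character(transcript_id),
                 gene_id = as.character(gene_id),
                 chrom = as.character(chrom), strand = strand,
                 exons = exons, cds = cds),
            class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (gene %s) %s:%d-%d(%s), %d exon(s)\n",
              x$transcript_id,
              if (nzchar(x$gene_id)) x$gene_id else "<novel>",
              x$chrom, x$exons[1L, 1L], x$exons[nrow(x$exons), 2L],
              x$strand, nrow(x$exons)))
  invisible(x)
}

#' @rdname transcript_model
#' @param tx A `TranscriptModel`.
#' @export
n_exons <- function(tx) nrow(tx$exons)

#' Splice junctions of a transcript
#'
#' A junction is identified by `(chrom, donor_pos, acceptor_pos, strand)`:
#' `donor_pos` is the first intronic base (0-based) and `acceptor_pos` the
#' last intronic base + 1, i.e. the genomic interval `[donor_pos,
#' acceptor_pos)` is the intron. An n-exon transcript has exactly n-1
#' junctions.
#'
#' @param tx A `TranscriptModel`.
#' @return Integer matrix with columns `donor_pos`, `acceptor_pos` (zero
#'   rows for mono-exon transcripts), ordered by genomic position.
#' @export
junctions <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("donor_pos", "acceptor_pos"))))
  cbind(donor_pos = tx$exons[-n, 2L], acceptor_pos = tx$exons[-1L, 1L])
}

# junction chain as a canonical string key, used for exact chain matching
junction_chain_key <- function(tx) {
  j <- junctions(tx)
  if (nrow(j) == 0L) return("")
  paste(paste(j[, 1L], j[, 2L], sep = "-"), collapse = ";")
}

junction_keys <- function(tx) {
  j <- junctions(tx)
  if (nrow(j) == 0L) return(character(0))
  paste(tx$chrom, j[, 1L], j[, 2L], tx$strand, sep = ":")
}

#' Strand-aware transcript ends
#'
#' `tss()` returns the genomic coordinate of the transcription start site
#' (5' end), `tts()` of the termination site (3' end). On the `+` strand the
#' TSS is the start of the first exon and the TTS the end of the last exon;
#' on `-` the roles reflect.
#'
#' @param tx A `TranscriptModel`.
#' @return A single genomic coordinate (integer, on the half-open grid).
#' @export
tss <- function(tx) {
  unname(if (tx$strand == "+") tx$exons[1L, 1L]
         else tx$exons[nrow(tx$exons), 2L])
}

#' @rdname tss
#' @export
tts <- function(tx) {
  unname(if (tx$strand == "+") tx$exons[nrow(tx$exons), 2L]
         else tx$exons[1L, 1L])
}

#' @rdname transcript_model
#' @export
transcript_span <- function(tx) {
  c(start = unname(tx$exons[1L, 1L]), end = unname(tx$exons[nrow(tx$exons), 2L]))
}

# total spliced length in nt
spliced_length <- function(tx) sum(tx$exons[, 2L] - tx$exons[, 1L])

# introns as [start, end) matrix
introns <- function(tx) {
  j <- junctions(tx)
  colnames(j) <- c("start", "end")
  j
}
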