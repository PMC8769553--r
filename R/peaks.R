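#' Load a BED peak track into a queryable interval index
#'
#' Used for CAGE / ATAC / 3'-seq peak tracks and the poly(A)-site catalog.
#' BED is 0-based half-open already, so no coordinate shift is applied. If
#' the file carries no strand column the index is strand-agnostic.
#'
#' @param path BED3+ file.
#' @return A `PeakIndex` object supporting [peak_overlaps()] and
#'   [peak_distance()].
#' @export
read_bed_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  peak_index(gr)
}

#' @rdname read_bed_peaks
#' @param gr A `GRanges` of peaks (used directly, e.g. by the synthetic-data
#'   generator).
#' @export
peak_index <- function(gr) {
  structure(list(gr = gr,
                 stranded = !all(as.character(GenomicRanges::strand(gr)) == "*")),
            class = "PeakIndex")
}

#' @export
print.PeakIndex <- function(x, ...) {
  cat(sprintf("PeakIndex: %d peaks (%s)\n", length(x$gr),
              if (x$stranded) "stranded" else "strand-agnostic"))
  invisible(x)
}

# build a 1-width GRanges for a genomic point on the half-open grid;
# `pos` is a boundary coordinate, the query covers base [pos, pos+1)
.point_gr <- function(chrom, pos, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L),
                         strand = strand)
}

#' Query a peak index
#'
#' `peak_overlaps()` reports whether a genomic point (optionally padded by
#' `slack` on both sides) intersects any peak; `peak_distance()` reports the
#' distance in bp to the nearest peak (0 when overlapping, `Inf` when the
#' chromosome has no peak). Queries against a strand-agnostic index ignore
#' strand.
#'
#' @param idx A `PeakIndex`.
#' @param chrom,pos,strand Query point (0-based coordinate).
#' @param slack Symmetric padding in bp applied to the query point.
#' @return Logical (overlap) or numeric distance.
#' @export
peak_overlaps <- function(idx, chrom, pos, strand = "*", slack = 0L) {
  q <- .point_gr(chrom, pos, if (idx$stranded) strand else "*")
  q <- GenomicRanges::resize(q, width = 1L + 2L * slack, fix = "center")
  GenomicRanges::start(q) <- max(1L, GenomicRanges::start(q))
  GenomicRanges::countOverlaps(q, idx$gr,
    ignore.strand = !idx$stranded || strand == "*") > 0L
}

#' @rdname peak_overlaps
#' @export
peak_distance <- function(idx, chrom, pos, strand = "*") {
  q <- .point_gr(chrom, pos, if (idx$stranded) strand else "*")
  # a query chromosome absent from the track legitimately has no nearest
  # peak; the seqlevel mismatch warning is expected there
  hit <- suppressWarnings(GenomicRanges::distanceToNearest(q, idx$gr,
    ignore.strand = !idx$stranded || strand == "*"))
  if (length(hit) == 0L) return(Inf)
  as.numeric(S4Vectors::mcols(hit)$distance)
}
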