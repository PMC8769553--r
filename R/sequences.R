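#' Load a genome (or proteome) FASTA
#'
#' Thin wrapper over `Biostrings::readDNAStringSet()` /
#' `readAAStringSet()` that truncates record names at the first whitespace,
#' matching how chromosome names appear in GTF/BED.
#'
#' @param path FASTA file.
#' @return A `DNAStringSet` (or `AAStringSet` for `read_proteome`).
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' @rdname read_genome
#' @export
read_proteome <- function(path) {
  p <- Biostrings::readAAStringSet(path)
  names(p) <- sub("\\s.*$", "", names(p))
  p
}

# fetch genome sequence [start, end) 0-based half-open, truncated at contig
# bounds; errors on an unknown contig
fetch_seq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("contig '", chrom, "' not in genome")
  len <- Biostrings::width(genome[chrom])
  s <- max(0L, as.integer(start)); e <- min(len, as.integer(end))
  if (e <= s) return("")
  as.character(Biostrings::subseq(genome[[chrom]], s + 1L, e))
}

#' Spliced transcript sequence
#'
#' Concatenates exon sequences from the genome and reverse-complements on
#' the minus strand, yielding the sense (5'->3') transcript sequence.
#'
#' @param tx A `TranscriptModel`.
#' @param genome A `DNAStringSet` covering the transcript's chromosome.
#' @return Character string.
#' @export
transcript_sequence <- function(tx, genome) {
  parts <- vapply(seq_len(nrow(tx$exons)), function(i)
    fetch_seq(genome, tx$chrom, tx$exons[i, 1L], tx$exons[i, 2L]), "")
  s <- paste(parts, collapse = "")
  if (tx$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
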