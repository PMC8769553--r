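#' Jaccard similarity of two isoform sets
#'
#' `|a intersect b| / |a union b|`; defined as 1 when both sets are empty
#' (two samples in which nothing was detected are indistinguishable).
#'
#' @param a,b Character vectors (treated as sets).
#' @return Similarity in `[0, 1]`.
#' @examples
#' jaccard(c("i1", "i2", "i3"), c("i2", "i3", "i4"))  # 0.5
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Hierarchical clustering of samples by isoform-set similarity
#'
#' Builds the pairwise Jaccard matrix over per-sample isoform sets and
#' clusters samples agglomeratively on the distance `1 - Jaccard`. Samples
#' are processed in lexicographic id order so the result is independent of
#' input order.
#'
#' @param sets Named list mapping sample id to a character vector of
#'   isoform ids (at least 2 samples).
#' @param linkage Agglomeration method passed to `stats::hclust()`
#'   (default `"average"`).
#' @return List: `similarity` (matrix), `distance` (`dist`), `hclust`, and
#'   `newick` (the dendrogram serialized as a newick string).
#' @export
cluster_samples <- function(sets, linkage = "average") {
  if (length(sets) < 2L) stop("need at least two samples")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named by sample id")
  sets <- sets[order(names(sets))]
  n <- length(sets)
  sim <- matrix(1, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sim[i, j] <- sim[j, i] <- jaccard(sets[[i]], sets[[j]])
  }
  d <- stats::as.dist(1 - sim)
  hc <- stats::hclust(d, method = linkage)
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(similarity = sim, distance = d, hclust = hc, newick = nwk)
}
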