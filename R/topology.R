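## Bipartite topology: connectance, unweighted degrees, and NODF
## (nestedness metric based on overlap and decreasing fill), reported on the
## [0, 1] scale. Presence is weight > 0; no abundance cutoff.

#' Connectance of a bipartite network
#'
#' Number of links (nonzero weights) divided by the number of possible
#' links S x F.
#'
#' @param net a [TaxonFunctionNetwork-class].
#' @return numeric scalar in \[0, 1\].
#' @export
connectance <- function(net) {
  w <- networkWeights(net)
  if (!length(w)) return(0)
  sum(w > 0) / length(w)
}

#' Unweighted degree distribution
#'
#' The degree of a taxon is the number of functions it links to; the degree
#' of a function is the number of taxa expressing (or encoding) it.
#'
#' @param net a [TaxonFunctionNetwork-class].
#' @param axis `"taxa"` or `"functions"`.
#' @return named integer vector of degrees.
#' @export
degreeDistribution <- function(net, axis = c("taxa", "functions")) {
  axis <- match.arg(axis)
  b <- networkWeights(net) > 0
  if (axis == "taxa") rowSums(b) else colSums(b)
}

.nodf_pairs <- function(b) {
  ## mean paired-overlap contribution across all ordered-by-fill row pairs:
  ## for fill(u) > fill(v) > 0, contribution = |supp(u) & supp(v)| / fill(v);
  ## equal fills (decreasing-fill condition violated) contribute 0.
  n <- nrow(b)
  if (n < 2L) return(numeric())
  fill <- rowSums(b)
  ov <- tcrossprod(b)  # pairwise overlaps
  contrib <- numeric(n * (n - 1L) / 2L)
  k <- 0L
  for (u in seq_len(n - 1L)) for (v in seq.int(u + 1L, n)) {
    k <- k + 1L
    fu <- fill[u]; fv <- fill[v]
    if (fu == fv || min(fu, fv) == 0) next
    lo <- if (fu > fv) v else u
    contrib[k] <- ov[u, v] / fill[lo]
  }
  contrib
}

#' NODF nestedness
#'
#' Classical NODF of the binarised network (presence = weight > 0), on the
#' \[0, 1\] scale: the mean, over all row pairs and all column pairs, of the
#' paired-overlap term -- the fraction of the sparser line's links shared
#' with the denser line, counted only when the two fills strictly decrease.
#' A strictly nested staircase scores 1; a checkerboard scores 0.
#'
#' @param net a [TaxonFunctionNetwork-class] with at least 2 rows or 2
#'   columns.
#' @return list with elements `nodf` (combined), `nodf_rows`, `nodf_cols`.
#' @export
nodf <- function(net) {
  b <- networkWeights(net) > 0
  storage.mode(b) <- "double"
  if (nrow(b) < 2L && ncol(b) < 2L)
    stop("NODF undefined for a single-row, single-column network",
         call. = FALSE)
  rc <- .nodf_pairs(b)
  cc <- .nodf_pairs(t(b))
  list(nodf = sum(rc, cc) / (length(rc) + length(cc)),
       nodf_rows = if (length(rc)) mean(rc) else NA_real_,
       nodf_cols = if (length(cc)) mean(cc) else NA_real_)
}

#' Per-sample topology table
#'
#' Convenience wrapper returning one row of topology metrics for a network.
#'
#' @param net a [TaxonFunctionNetwork-class].
#' @param sampleId label for the output row.
#' @return one-row data.frame: sample_id, n_taxa, n_functions, links,
#'   connectance, nodf.
#' @export
topologySummary <- function(net, sampleId = "sample") {
  w <- networkWeights(net)
  nd <- tryCatch(nodf(net)$nodf, error = function(e) NA_real_)
  data.frame(sample_id = sampleId, n_taxa = nrow(w), n_functions = ncol(w),
             links = sum(w > 0), connectance = connectance(net), nodf = nd,
             stringsAsFactors = FALSE)
}
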