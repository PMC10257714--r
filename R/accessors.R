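#' Accessors for the core classes
#'
#' `taxa()` returns the ordered taxon labels, `functionIds()` the function
#' identifiers, `networkWeights()` the S x F weight matrix, `networkKind()`
#' `"pcn"` or `"gcn"`, `proportions()` the biomass proportions p_i, and
#' `distances()` the d_ij matrix. `td()`, `fd()`, `fr()` and `nfr()` extract
#' the four indices from a [DiversitySummary-class].
#'
#' @param x a proteoFR object.
#' @return The slot contents described above.
#' @name accessors
#' @examples
#' net <- TaxonFunctionNetwork(
#'   matrix(1, 1, 2, dimnames = list("Bacteroides", c("K1", "K2"))), "pcn")
#' taxa(net)
#' functionIds(net)
NULL

#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))
#' @rdname accessors
#' @export
setGeneric("functionIds", function(x) standardGeneric("functionIds"))
#' @rdname accessors
#' @export
setGeneric("networkWeights", function(x) standardGeneric("networkWeights"))
#' @rdname accessors
#' @export
setGeneric("networkKind", function(x) standardGeneric("networkKind"))
#' @rdname accessors
#' @export
setGeneric("proportions", function(x) standardGeneric("proportions"))
#' @rdname accessors
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))
#' @rdname accessors
#' @export
setGeneric("td", function(x) standardGeneric("td"))
#' @rdname accessors
#' @export
setGeneric("fd", function(x) standardGeneric("fd"))
#' @rdname accessors
#' @export
setGeneric("fr", function(x) standardGeneric("fr"))
#' @rdname accessors
#' @export
setGeneric("nfr", function(x) standardGeneric("nfr"))

#' @rdname accessors
#' @export
setMethod("taxa", "TaxonFunctionNetwork", function(x) rownames(x@weights))
#' @rdname accessors
#' @export
setMethod("functionIds", "TaxonFunctionNetwork", function(x) colnames(x@weights))
#' @rdname accessors
#' @export
setMethod("networkWeights", "TaxonFunctionNetwork", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("networkKind", "TaxonFunctionNetwork", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("taxa", "AbundanceProfile", function(x) names(x@p))
#' @rdname accessors
#' @export
setMethod("proportions", "AbundanceProfile", function(x) x@p)
#' @rdname accessors
#' @export
setMethod("taxa", "FunctionalDistanceMatrix", function(x) rownames(x@d))
#' @rdname accessors
#' @export
setMethod("distances", "FunctionalDistanceMatrix", function(x) x@d)
#' @rdname accessors
#' @export
setMethod("td", "DiversitySummary", function(x) x@td)
#' @rdname accessors
#' @export
setMethod("fd", "DiversitySummary", function(x) x@fd)
#' @rdname accessors
#' @export
setMethod("fr", "DiversitySummary", function(x) x@fr)
#' @rdname accessors
#' @export
setMethod("nfr", "DiversitySummary", function(x) x@nfr)

setMethod("show", "TaxonFunctionNetwork", function(object) {
  w <- object@weights
  cat(sprintf("TaxonFunctionNetwork (%s): %d taxa x %d functions, %d links, connectance %.3f\n",
              toupper(object@kind), nrow(w), ncol(w), sum(w > 0),
              if (length(w)) sum(w > 0) / length(w) else NA_real_))
})

setMethod("show", "AbundanceProfile", function(object) {
  p <- sort(object@p, decreasing = TRUE)
  cat(sprintf("AbundanceProfile: %d taxa\n", length(p)))
  top <- utils::head(p, 5)
  cat(paste(sprintf("  %s %.4f", names(top), top), collapse = "\n"), "\n")
  if (length(p) > 5) cat(sprintf("  ... and %d more\n", length(p) - 5L))
})

setMethod("show", "FunctionalDistanceMatrix", function(object) {
  cat(sprintf("FunctionalDistanceMatrix: %d taxa, mean off-diagonal d_ij %.4f\n",
              nrow(object@d),
              if (nrow(object@d) > 1)
                mean(object@d[upper.tri(object@d)]) else NA_real_))
})

setMethod("show", "DiversitySummary", function(object) {
  cat(sprintf("DiversitySummary: TD %.6f  FD %.6f  FR %.6f  nFR %.6f\n",
              object@td, object@fd, object@fr, object@nfr))
})

#' Convert a DiversitySummary to a one-row data.frame
#'
#' @param x a [DiversitySummary-class].
#' @param row.names,optional,... passed through for S3 compatibility; unused.
#' @return data.frame with columns td, fd, fr, nfr.
#' @export
as.data.frame.DiversitySummary <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(td = x@td, fd = x@fd, fr = x@fr, nfr = x@nfr)
}
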