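#' @import methods
NULL

## Tolerances used by validity checks throughout the package.
.ROW_SUM_TOL <- 1e-9
.FR_IDENTITY_TOL <- 1e-12

#' Weighted bipartite taxon-function network
#'
#' An S x F incidence matrix linking S taxa (rows, typically genera) to F
#' functions (columns, KEGG KO or COG identifiers). Weights are non-negative;
#' for networks built by [buildPCN()] / [buildGCN()] each row is normalised to
#' sum to 1, so a row is the relative functional profile of one taxon. The
#' `kind` slot records whether the weights derive from protein-group
#' intensities (`"pcn"`) or from metagenomic read counts (`"gcn"`).
#'
#' @slot weights numeric matrix (taxa x functions), non-negative, with
#'   dimnames giving taxon and function identifiers.
#' @slot kind character, `"pcn"` or `"gcn"`.
#'
#' @seealso [TaxonFunctionNetwork()] for the constructor, [taxa()],
#'   [functionIds()], [networkWeights()], [networkKind()] for accessors.
#' @export
setClass("TaxonFunctionNetwork",
  representation(weights = "matrix", kind = "character"))

setValidity("TaxonFunctionNetwork", function(object) {
  w <- object@weights
  msgs <- character()
  if (!is.numeric(w)) msgs <- c(msgs, "weights must be a numeric matrix")
  if ((nrow(w) > 0 && is.null(rownames(w))) ||
      (ncol(w) > 0 && is.null(colnames(w))))
    msgs <- c(msgs, "weights must have taxon rownames and function colnames")
  if (anyDuplicated(rownames(w))) msgs <- c(msgs, "duplicated taxon labels")
  if (anyDuplicated(colnames(w))) msgs <- c(msgs, "duplicated function labels")
  if (is.numeric(w) && length(w) && any(w < 0))
    msgs <- c(msgs, "weights must be non-negative")
  if (length(object@kind) != 1L || !object@kind %in% c("pcn", "gcn"))
    msgs <- c(msgs, "kind must be \"pcn\" or \"gcn\"")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TaxonFunctionNetwork
#'
#' @param weights non-negative numeric matrix with taxon rownames and function
#'   colnames.
#' @param kind `"pcn"` (protein intensities) or `"gcn"` (read counts).
#' @param normalize logical; if `TRUE`, divide every row with a positive sum
#'   by that sum (row-stochastic form used by all metrics).
#' @return A [TaxonFunctionNetwork-class] object.
#' @examples
#' w <- matrix(c(30, 70, 10, 0), 2, 2, byrow = TRUE,
#'             dimnames = list(c("Bacteroides", "Blautia"), c("K00001", "K00002")))
#' TaxonFunctionNetwork(w, "pcn")
#' @export
TaxonFunctionNetwork <- function(weights, kind = c("pcn", "gcn"),
                                 normalize = TRUE) {
  kind <- match.arg(kind)
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  if (normalize && nrow(weights)) {
    rs <- rowSums(weights)
    pos <- rs > 0
    weights[pos, ] <- weights[pos, , drop = FALSE] / rs[pos]
  }
  new("TaxonFunctionNetwork", weights = weights, kind = kind)
}

#' Per-taxon biomass proportions of one sample
#'
#' Holds the relative protein-level biomass p_i of each taxon, the abundance
#' weights entering the diversity indices. Proportions are non-negative and
#' sum to 1.
#'
#' @slot p named numeric vector of proportions (names are taxon labels).
#' @seealso [AbundanceProfile()], [biomassProfile()]
#' @export
setClass("AbundanceProfile", representation(p = "numeric"))

setValidity("AbundanceProfile", function(object) {
  p <- object@p
  msgs <- character()
  if (is.null(names(p)) || anyDuplicated(names(p)))
    msgs <- c(msgs, "p must have unique taxon names")
  if (length(p) && any(p < 0)) msgs <- c(msgs, "proportions must be >= 0")
  if (length(p) && abs(sum(p) - 1) > .ROW_SUM_TOL)
    msgs <- c(msgs, sprintf("proportions must sum to 1 (got %.12g)", sum(p)))
  if (length(msgs)) msgs else TRUE
})

#' @param p non-negative named numeric vector; normalised to sum to 1 when
#'   `normalize = TRUE`.
#' @param normalize logical.
#' @rdname AbundanceProfile-class
#' @examples
#' AbundanceProfile(c(Bacteroides = 60, Blautia = 40))
#' @export
AbundanceProfile <- function(p, normalize = TRUE) {
  nm <- names(p)
  p <- as.numeric(unlist(p))
  names(p) <- nm
  if (normalize && length(p) && sum(p) > 0) p <- p / sum(p)
  new("AbundanceProfile", p = p)
}

#' Pairwise functional distance matrix
#'
#' Symmetric S x S matrix of weighted Jaccard distances d_ij between the
#' row-normalised functional profiles of taxa, with zero diagonal and entries
#' in \[0, 1\].
#'
#' @slot d symmetric numeric matrix with identical taxon row/colnames.
#' @seealso [weightedJaccard()]
#' @export
setClass("FunctionalDistanceMatrix", representation(d = "matrix"))

setValidity("FunctionalDistanceMatrix", function(object) {
  d <- object@d
  msgs <- character()
  if (nrow(d) != ncol(d)) msgs <- c(msgs, "d must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    msgs <- c(msgs, "d must have identical taxon row and column names")
  if (length(d)) {
    if (max(abs(d - t(d))) > 1e-12) msgs <- c(msgs, "d must be symmetric")
    if (any(abs(diag(d)) > 1e-12)) msgs <- c(msgs, "diagonal must be zero")
    if (any(d < -1e-12) || any(d > 1 + 1e-12))
      msgs <- c(msgs, "entries must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Diversity and redundancy summary of one sample
#'
#' Bundles the four within-sample indices: taxonomic diversity TD
#' (Gini-Simpson), functional diversity FD (Rao quadratic entropy),
#' functional redundancy FR = TD - FD, and normalised redundancy
#' nFR = FR / TD (0 when TD = 0).
#'
#' @slot td,fd,fr,nfr numeric scalars.
#' @seealso [functionalRedundancy()], [sampleSummary()]
#' @export
setClass("DiversitySummary",
  representation(td = "numeric", fd = "numeric", fr = "numeric", nfr = "numeric"))

setValidity("DiversitySummary", function(object) {
  msgs <- character()
  if (abs(object@fr - (object@td - object@fd)) > .FR_IDENTITY_TOL)
    msgs <- c(msgs, "fr must equal td - fd")
  if (object@fd < -1e-12 || object@fd > object@td + 1e-9)
    msgs <- c(msgs, "fd must lie in [0, td]")
  if (object@td > 0 && (object@nfr < -1e-12 || object@nfr > 1 + 1e-12))
    msgs <- c(msgs, "nfr must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

DiversitySummary <- function(td, fd) {
  fr <- td - fd
  new("DiversitySummary", td = td, fd = fd, fr = fr,
      nfr = if (td > 0) fr / td else 0)
}
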