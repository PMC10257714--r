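## Within-sample diversity and redundancy:
##   TD  = 1 - sum_i p_i^2                       (Gini-Simpson)
##   FD  = sum_i sum_{j != i} d_ij p_i p_j       (Rao quadratic entropy)
##   FR  = TD - FD = sum_i sum_{j != i} (1 - d_ij) p_i p_j
##   nFR = FR / TD (0 for a single-taxon sample)
## with d_ij the weighted Jaccard distance between row-normalised
## functional profiles.

#' Weighted Jaccard functional distance matrix
#'
#' For every taxon pair (i, j),
#' `d_ij = 1 - sum_a min(W_ia, W_ja) / sum_a max(W_ia, W_ja)`
#' on the network's row-normalised weights. Identical profiles give 0,
#' disjoint function supports give 1.
#'
#' @param net a [TaxonFunctionNetwork-class] (rows normalised at
#'   construction).
#' @return a [FunctionalDistanceMatrix-class].
#' @examples
#' w <- rbind(A = c(0.5, 0.5, 0), B = c(0.25, 0.25, 0.5))
#' colnames(w) <- paste0("K", 1:3)
#' distances(weightedJaccard(TaxonFunctionNetwork(w, "pcn")))  # d_AB = 2/3
#' @export
weightedJaccard <- function(net) {
  w <- networkWeights(net)
  S <- nrow(w)
  if (S < 1L) stop("network has no taxa", call. = FALSE)
  if (any(rowSums(w) == 0))
    stop("all-zero taxon row: distances undefined", call. = FALSE)
  d <- matrix(0, S, S, dimnames = list(rownames(w), rownames(w)))
  if (S > 1L) {
    for (i in seq_len(S - 1L)) {
      wi <- w[i, ]
      for (j in seq.int(i + 1L, S)) {
        wj <- w[j, ]
        d[i, j] <- d[j, i] <-
          1 - sum(pmin(wi, wj)) / sum(pmax(wi, wj))
      }
    }
    d[d < 0] <- 0
    d[d > 1] <- 1
  }
  new("FunctionalDistanceMatrix", d = d)
}

#' Gini-Simpson taxonomic diversity
#'
#' `TD = 1 - sum_i p_i^2`: the probability that two members drawn at random
#' (with replacement) belong to different taxa.
#'
#' @param profile an [AbundanceProfile-class].
#' @return numeric scalar in `[0, 1 - 1/S]`.
#' @export
taxonomicDiversity <- function(profile) {
  p <- proportions(profile)
  1 - sum(p^2)
}

.check_aligned <- function(profile, dist) {
  if (!identical(taxa(profile), taxa(dist)))
    stop("alignment error: profile and distance matrix taxa differ",
         call. = FALSE)
}

#' Rao quadratic-entropy functional diversity
#'
#' `FD = sum_i sum_{j != i} d_ij p_i p_j`: the expected functional distance
#' between two randomly drawn members. Bounded above by TD because
#' `d_ij <= 1`.
#'
#' @param profile an [AbundanceProfile-class].
#' @param dist a [FunctionalDistanceMatrix-class] on the same taxa, in the
#'   same order.
#' @return numeric scalar in `[0, TD]`.
#' @export
functionalDiversity <- function(profile, dist) {
  .check_aligned(profile, dist)
  p <- proportions(profile)
  as.numeric(p %*% distances(dist) %*% p)  # diagonal is zero
}

#' Functional redundancy of one sample
#'
#' Computes TD, FD, `FR = TD - FD` and `nFR = FR / TD`. FR is the
#' abundance-weighted mean functional overlap `(1 - d_ij)` over ordered
#' pairs of distinct members; nFR rescales it to \[0, 1\], with 1 when all
#' members share identical functional profiles and 0 when all profiles are
#' pairwise disjoint. For a single-taxon sample (TD = 0) nFR is defined
#' as 0: no pair exists to be redundant.
#'
#' @inheritParams functionalDiversity
#' @return a [DiversitySummary-class].
#' @export
functionalRedundancy <- function(profile, dist) {
  .check_aligned(profile, dist)
  DiversitySummary(td = taxonomicDiversity(profile),
                   fd = functionalDiversity(profile, dist))
}

#' Full per-sample summary from a network and a biomass profile
#'
#' Aligns the network with the profile (taxa present in only one of the two
#' are dropped and the profile renormalised), computes within-sample d_ij on
#' the network rows, and returns the diversity summary. Distances are always
#' computed within the sample, never against a pooled cross-sample
#' reference, because expression profiles respond to the sample's own
#' environment.
#'
#' @param net a [TaxonFunctionNetwork-class] for this sample.
#' @param profile an [AbundanceProfile-class] for the same sample.
#' @param biomassFraction optional fraction in (0, 1]; when given, the
#'   computation is restricted to the genera holding that top share of
#'   biomass (see [filterTopBiomass()]). Default uses all shared genera.
#' @return a [DiversitySummary-class].
#' @export
sampleSummary <- function(net, profile, biomassFraction = NULL) {
  shared <- intersect(taxa(net), taxa(profile))
  if (!length(shared))
    stop("no taxa shared between network and abundance profile",
         call. = FALSE)
  p <- proportions(profile)[shared]
  if (!is.null(biomassFraction)) {
    keep <- filterTopBiomass(AbundanceProfile(p), biomassFraction)
    shared <- shared[shared %in% keep]
    p <- proportions(profile)[shared]
  }
  sub <- TaxonFunctionNetwork(
    networkWeights(net)[shared, , drop = FALSE], networkKind(net),
    normalize = FALSE)
  functionalRedundancy(AbundanceProfile(p),
                       weightedJaccard(sub))
}
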