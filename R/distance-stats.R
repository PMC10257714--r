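## Cross-sample analysis of pairwise functional distances d_ij:
## pooled pair tables under a dataset-wide top-biomass filter, histogram
## Jensen-Shannon divergence between d_ij distributions, and per-pair
## rank-sum group comparisons with BH correction.

#' Collect per-sample pairwise distances into a long table
#'
#' Genera are filtered once for the whole dataset: the mean biomass profile
#' across samples is taken and the genera holding its top
#' `biomassFraction` are retained. For each sample, d_ij is then computed
#' on the retained genera present in that sample's network, one row per
#' unordered pair (taxon_i < taxon_j). Pairs missing from a sample (a
#' genus not observed there) are simply absent, not recorded as d = 1.
#'
#' @param samples named list; each element a list with components `net`
#'   (a [TaxonFunctionNetwork-class]), `profile`
#'   (an [AbundanceProfile-class]) and optionally `group` (label).
#' @param biomassFraction dataset-wide top-biomass fraction, default 0.95.
#' @return data.frame: sample_id, group, taxon_i, taxon_j, d_ij.
#' @export
collectPairs <- function(samples, biomassFraction = 0.95) {
  if (!length(samples)) stop("no samples", call. = FALSE)
  if (is.null(names(samples)))
    names(samples) <- sprintf("S%02d", seq_along(samples))
  all_taxa <- sort(unique(unlist(lapply(samples, function(s) taxa(s$profile)))))
  mean_p <- rowMeans(vapply(samples, function(s) {
    p <- stats::setNames(numeric(length(all_taxa)), all_taxa)
    p[taxa(s$profile)] <- proportions(s$profile)
    p
  }, numeric(length(all_taxa))))
  keep <- filterTopBiomass(AbundanceProfile(mean_p), biomassFraction)
  rows <- list()
  for (sid in names(samples)) {
    s <- samples[[sid]]
    present <- sort(intersect(keep, taxa(s$net)), method = "radix")
    if (length(present) < 2L) next
    sub <- TaxonFunctionNetwork(
      networkWeights(s$net)[present, , drop = FALSE], networkKind(s$net),
      normalize = FALSE)
    d <- distances(weightedJaccard(sub))
    idx <- which(upper.tri(d), arr.ind = TRUE)
    rows[[sid]] <- data.frame(
      sample_id = sid,
      group = if (is.null(s$group)) NA_character_ else s$group,
      taxon_i = rownames(d)[idx[, 1L]], taxon_j = colnames(d)[idx[, 2L]],
      d_ij = d[idx], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out))
    stop("no retained genus pair in any sample", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Jensen-Shannon divergence between two distance samples
#'
#' Both samples are binned on the fixed grid \[0, 1\] with `bins`
#' equal-width bins, smoothed with a small pseudo-count and normalised;
#' the JSD is computed with base-2 logarithms so the value lies in
#' \[0, 1\] and is symmetric in its arguments.
#'
#' @param a,b numeric vectors of d_ij values in \[0, 1\].
#' @param bins number of histogram bins, default 50.
#' @param pseudo pseudo-count added to every bin, default 1e-10.
#' @return numeric scalar in \[0, 1\].
#' @export
jsDivergence <- function(a, b, bins = 50L, pseudo = 1e-10) {
  if (!length(a) || !length(b)) stop("empty input sample", call. = FALSE)
  if (any(c(a, b) < -1e-12) || any(c(a, b) > 1 + 1e-12))
    stop("distances must lie in [0, 1]", call. = FALSE)
  brk <- seq(0, 1, length.out = bins + 1L)
  binit <- function(x) {
    h <- tabulate(pmin(pmax(findInterval(x, brk, rightmost.closed = TRUE),
                            1L), bins), bins)
    h <- h + pseudo
    h / sum(h)
  }
  p <- binit(a); q <- binit(b)
  m <- (p + q) / 2
  kl <- function(x, y) sum(x * log2(x / y))
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Per-pair group comparison of d_ij values
#'
#' For every genus pair observed in at least `minPerGroup` samples of each
#' group, compares the two groups' d_ij values with a two-sided Wilcoxon
#' rank-sum test and reports the log2 fold-change of mean d_ij
#' (group B over group A) with Benjamini-Hochberg adjusted p-values
#' across pairs.
#'
#' @param pairTable data.frame from [collectPairs()].
#' @param groupA,groupB group labels to compare.
#' @param minPerGroup minimum samples per group per pair, default 2.
#' @return data.frame: taxon_i, taxon_j, n_a, n_b, mean_a, mean_b, log2fc,
#'   p, p_adj.
#' @export
pairwiseGroupComparison <- function(pairTable, groupA, groupB,
                                    minPerGroup = 2L) {
  ta <- pairTable[pairTable$group == groupA, , drop = FALSE]
  tb <- pairTable[pairTable$group == groupB, , drop = FALSE]
  if (!nrow(ta) || !nrow(tb))
    stop("a group has zero samples", call. = FALSE)
  key <- function(df) paste(df$taxon_i, df$taxon_j, sep = "\r")
  ka <- key(ta); kb <- key(tb)
  shared <- intersect(unique(ka), unique(kb))
  rows <- list()
  for (k in shared) {
    xa <- ta$d_ij[ka == k]; xb <- tb$d_ij[kb == k]
    if (length(xa) < minPerGroup || length(xb) < minPerGroup) next
    pv <- suppressWarnings(
      stats::wilcox.test(xa, xb, alternative = "two.sided",
                         exact = FALSE)$p.value)
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    rows[[k]] <- data.frame(
      taxon_i = parts[1L], taxon_j = parts[2L],
      n_a = length(xa), n_b = length(xb),
      mean_a = mean(xa), mean_b = mean(xb),
      log2fc = if (isTRUE(all.equal(mean(xa), mean(xb)))) 0
               else log2(mean(xb) / mean(xa)),
      p = pv,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no genus pair meets the per-group sample requirement",
         call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, -abs(out$log2fc)), , drop = FALSE]
}
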