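## Synthetic metaproteomic/metagenomic datasets with controllable structure.
##
## The binary GCN scaffold is a noisy threshold graph: taxa and functions
## carry "attractiveness" scores and an edge is present with probability
## plogis((s_i + t_a - theta) / T). As the temperature T -> 0 the graph
## becomes a strict threshold (perfectly nested) structure; large T gives an
## Erdos-Renyi-like graph. The PCN keeps a per-taxon fraction of GCN edges
## (expressed subset of encoded functions). T is calibrated so the built
## PCN's NODF lands on the requested target; the same binary scaffold is
## shared by all samples, while weights vary per sample.

.synth_function_ids <- function(nF) {
  nK <- ceiling(0.8 * nF)
  c(sprintf("K%05d", seq_len(nK)),
    if (nF > nK) sprintf("COG%04d", seq_len(nF - nK)))
}

.synth_lineage <- function(genus) {
  paste0("superkingdom:Bacteria;phylum:Bacillota;class:Clostridia;",
         "order:Eubacteriales;family:Lachnospiraceae;genus:", genus)
}

#' Specification for a synthetic dataset
#'
#' @param nTaxa,nFunctions dimensions of the taxon-function scaffold.
#' @param nestednessTarget desired NODF of the built PCN, in \[0, 1\]; the
#'   generator calibrates to within 0.1 of it or fails.
#' @param weightDistribution `"lognormal"` (meanlog 0, sdlog 1; heavy-tailed
#'   like MS intensities) or `"uniform"`.
#' @param pcnFraction per-taxon fraction of GCN edges expressed in the PCN,
#'   in (0, 1].
#' @param nSamples number of samples; groups `"A"`/`"B"` alternate.
#' @param groupEffect optional list with `group` (label), `factor`
#'   (multiplier) and `functionFraction` (share of functions shifted in
#'   that group's samples).
#' @param seed integer seed; the dataset is a pure function of the spec.
#' @return a `SyntheticSpec` list.
#' @export
syntheticSpec <- function(nTaxa = 12L, nFunctions = 40L,
                          nestednessTarget = 0.6,
                          weightDistribution = c("lognormal", "uniform"),
                          pcnFraction = 0.6, nSamples = 4L,
                          groupEffect = NULL, seed = 1L) {
  weightDistribution <- match.arg(weightDistribution)
  stopifnot(nTaxa >= 2L, nFunctions >= 2L, nSamples >= 1L,
            pcnFraction > 0, pcnFraction <= 1,
            nestednessTarget >= 0, nestednessTarget <= 1)
  structure(list(n_taxa = as.integer(nTaxa),
                 n_functions = as.integer(nFunctions),
                 nestedness_target = nestednessTarget,
                 weight_distribution = weightDistribution,
                 pcn_fraction = pcnFraction,
                 n_samples = as.integer(nSamples),
                 group_effect = groupEffect,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

## Binary GCN/PCN scaffold at temperature T; deterministic in (spec, T).
.synth_scaffold <- function(spec, T) {
  set.seed(spec$seed + round(1e4 * T) %% 10000L)
  S <- spec$n_taxa; F_ <- spec$n_functions
  s <- seq(1, 0, length.out = S)       # taxon attractiveness, descending
  t <- seq(1, 0, length.out = F_)      # function attractiveness
  z <- outer(s, t, "+")
  theta <- stats::quantile(z, 0.45)    # fixes overall fill near 55%
  prob <- stats::plogis((z - theta) / max(T, 1e-9))
  gcn <- matrix(stats::runif(S * F_) < prob, S, F_)
  gcn[, 1L] <- TRUE                    # every taxon encodes the core function
  pcn <- matrix(FALSE, S, F_)
  for (i in seq_len(S)) {
    deg <- sum(gcn[i, ])
    k <- max(1L, ceiling(spec$pcn_fraction * deg))
    idx <- which(gcn[i, ])
    ## expression biased toward high-attractiveness functions keeps the
    ## expressed subgraph nested rather than uniformly thinned
    keep <- idx[order(t[idx] + stats::runif(length(idx), 0, T),
                      decreasing = TRUE)][seq_len(k)]
    pcn[i, keep] <- TRUE
  }
  list(gcn = gcn, pcn = pcn)
}

.scaffold_nodf <- function(b) {
  ## a built network only contains observed taxa/functions, so empty lines
  ## are dropped before measuring nestedness
  b <- b[rowSums(b) > 0, colSums(b) > 0, drop = FALSE]
  net <- TaxonFunctionNetwork(
    matrix(as.numeric(b), nrow(b),
           dimnames = list(sprintf("G%03d", seq_len(nrow(b))),
                           sprintf("F%03d", seq_len(ncol(b))))),
    "pcn", normalize = FALSE)
  nodf(net)$nodf
}

## Calibrate the temperature against the realized PCN NODF.
.calibrate_scaffold <- function(spec) {
  grid <- c(1e-4, 0.02, 0.05, 0.1, 0.15, 0.2, 0.3, 0.45, 0.7, 1, 1.5, 2.5, 4)
  best <- NULL; best_err <- Inf
  for (T in grid) {
    sc <- .synth_scaffold(spec, T)
    err <- abs(.scaffold_nodf(sc$pcn) - spec$nestedness_target)
    if (err < best_err) { best <- sc; best_err <- err }
  }
  if (best_err > 0.1)
    stop("nestedness target ", spec$nestedness_target,
         " infeasible for ", spec$n_taxa, " x ", spec$n_functions,
         " (closest realized NODF off by ", signif(best_err, 3), ")",
         call. = FALSE)
  best
}

.rweight <- function(n, dist) {
  if (dist == "lognormal") stats::rlnorm(n, 0, 1) else stats::runif(n, 0.2, 1)
}

#' Generate a synthetic dataset of peptide, protein and gene tables
#'
#' Produces, per sample, the three TSV-schema tables consumed by
#' [readPeptideTable()], [readProteinTable()] and [readGeneTable()], built
#' so that running the tables through [buildPCN()] / [buildGCN()] yields
#' networks with PCN edges a subset of GCN edges and a PCN NODF within 0.1
#' of the spec's target. Each PCN edge becomes one protein group carrying a
#' genus-resolved unique peptide; a taxon-level biomass signal is encoded
#' in the unique-peptide intensities. Identical spec and seed give
#' byte-identical tables.
#'
#' @param spec a [syntheticSpec()].
#' @param dir optional directory; when given, per-sample TSVs and a
#'   `manifest.json` are written there.
#' @return list with `samples` (named list of per-sample lists: `peptides`,
#'   `proteins`, `genes`, `group`) and `manifest`.
#' @export
generateSyntheticDataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  sc <- .calibrate_scaffold(spec)
  S <- spec$n_taxa; F_ <- spec$n_functions
  genera <- sprintf("Genus%03d", seq_len(S))
  funs <- .synth_function_ids(F_)
  set.seed(spec$seed)
  base_abund <- stats::rlnorm(S, 0, 1)
  base_w <- matrix(0, S, F_)
  base_w[sc$pcn] <- .rweight(sum(sc$pcn), spec$weight_distribution)
  ge <- spec$group_effect
  shifted_funs <- if (!is.null(ge))
    seq_len(max(1L, round(ge$functionFraction * F_))) else integer()
  samples <- list()
  for (sidx in seq_len(spec$n_samples)) {
    set.seed(spec$seed + 7919L * sidx)
    sid <- sprintf("S%02d", sidx)
    grp <- c("A", "B")[(sidx - 1L) %% 2L + 1L]
    w <- base_w * matrix(stats::rlnorm(S * F_, 0, 0.25), S, F_)
    if (!is.null(ge) && grp == ge$group)
      w[, shifted_funs] <- w[, shifted_funs] * ge$factor
    abund <- base_abund * stats::rlnorm(S, 0, 0.2)
    ## gene table: one row per GCN edge
    gidx <- which(sc$gcn, arr.ind = TRUE)
    genes <- data.frame(
      gene_id = sprintf("%s_g%04d", sid, seq_len(nrow(gidx))),
      taxon = genera[gidx[, 1L]],
      function_id = funs[gidx[, 2L]],
      read_count = 1L + stats::rpois(nrow(gidx), 49),
      stringsAsFactors = FALSE)
    ## protein groups + peptides: one group per PCN edge
    pidx <- which(w > 0, arr.ind = TRUE)
    ng <- nrow(pidx)
    gid <- sprintf("%s_PG%04d", sid, seq_len(ng))
    pep_id <- sprintf("%s_pep%04d", sid, seq_len(ng))
    intensity <- abund[pidx[, 1L]] * w[cbind(pidx[, 1L], pidx[, 2L])] * 1e6
    fid <- funs[pidx[, 2L]]
    is_cog <- startsWith(fid, "COG")
    proteins <- data.frame(group_id = gid, stringsAsFactors = FALSE)
    proteins$peptide_ids <- as.list(pep_id)
    proteins$intensity <- intensity
    proteins$ko <- ifelse(is_cog, NA_character_, fid)
    proteins$cog <- ifelse(is_cog, fid, NA_character_)
    peptides <- data.frame(
      peptide_id = pep_id,
      sequence = vapply(seq_len(ng), function(k)
        paste(sample(c("A", "G", "L", "S", "V", "K", "R"), 9,
                     replace = TRUE), collapse = ""), character(1)),
      intensity = intensity * 0.5,
      is_unique = TRUE,
      lineage = .synth_lineage(genera[pidx[, 1L]]),
      stringsAsFactors = FALSE)
    ## a few shared (non-unique) peptides with above-genus LCAs: they must
    ## be ignored by both the bridge and the biomass profile
    n_shared <- max(2L, ng %/% 20L)
    shared <- data.frame(
      peptide_id = sprintf("%s_shr%03d", sid, seq_len(n_shared)),
      sequence = rep("AAGLSVKAR", n_shared),
      intensity = stats::runif(n_shared, 1e4, 1e5),
      is_unique = FALSE,
      lineage = rep("superkingdom:Bacteria;phylum:Bacillota", n_shared),
      stringsAsFactors = FALSE)
    peptides <- rbind(peptides, shared)
    peptides$genus <- lineageGenus(peptides$lineage)
    samples[[sid]] <- list(peptides = peptides, proteins = proteins,
                           genes = genes, group = grp)
  }
  manifest <- list(spec = unclass(spec)[setdiff(names(spec), "group_effect")],
                   group_effect = spec$group_effect,
                   n_samples = spec$n_samples,
                   sample_ids = names(samples))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(samples)) {
      writePeptideTable(samples[[sid]]$peptides,
                        file.path(dir, paste0(sid, "_peptides.tsv")))
      writeProteinTable(samples[[sid]]$proteins,
                        file.path(dir, paste0(sid, "_proteins.tsv")))
      writeGeneTable(samples[[sid]]$genes,
                     file.path(dir, paste0(sid, "_genes.tsv")))
    }
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(samples = samples, manifest = manifest)
}

#' Single-strain proteome
#'
#' A strain's row-normalised expressed-function profile under one culture
#' condition, the building block of in-silico communities.
#'
#' @param strainId strain label.
#' @param condition culture-condition label.
#' @param weights named non-negative vector of function weights
#'   (normalised to sum to 1).
#' @return a `StrainProteome` list.
#' @export
strainProteome <- function(strainId, condition, weights) {
  stopifnot(!is.null(names(weights)), all(weights >= 0), sum(weights) > 0)
  structure(list(strain_id = strainId, condition = condition,
                 weights = weights / sum(weights)),
            class = "StrainProteome")
}

#' Perturb a strain proteome into a new condition
#'
#' Applies multiplicative lognormal noise plus a condition-specific block
#' shift (a contiguous fraction of functions up- or down-weighted), then
#' renormalises -- emulating an expression response to a changed medium
#' while keeping the encoded gene set fixed.
#'
#' @param proteome a [strainProteome()].
#' @param condition new condition label.
#' @param noiseSd sdlog of the multiplicative noise.
#' @param blockFraction fraction of functions in the shifted block.
#' @param blockFactor multiplier applied to the block.
#' @param seed integer seed.
#' @return a new `StrainProteome`.
#' @export
perturbProteome <- function(proteome, condition, noiseSd = 0.3,
                            blockFraction = 0.25, blockFactor = 4,
                            seed = 1L) {
  set.seed(seed)
  w <- proteome$weights * stats::rlnorm(length(proteome$weights), 0, noiseSd)
  k <- max(1L, round(blockFraction * length(w)))
  block <- sample.int(length(w), k)
  w[block] <- w[block] * blockFactor
  strainProteome(proteome$strain_id, condition, w)
}

#' Assemble an in-silico community from strain proteomes
#'
#' Stacks the strains' proteomes as network rows (taxa = strains, functions
#' = union of their function sets) and pairs them with the given abundance
#' vector, ready for [sampleSummary()].
#'
#' @param proteomes list of [strainProteome()] objects.
#' @param abundances numeric vector of the same length, summing to 1.
#' @return list with `net` (a [TaxonFunctionNetwork-class], kind `"pcn"`)
#'   and `profile` (an [AbundanceProfile-class]).
#' @export
assembleInsilicoCommunity <- function(proteomes, abundances) {
  if (length(proteomes) != length(abundances))
    stop("proteomes and abundances differ in length", call. = FALSE)
  if (abs(sum(abundances) - 1) > 1e-9)
    stop("abundances must sum to 1", call. = FALSE)
  ids <- vapply(proteomes, function(p) p$strain_id, character(1))
  if (anyDuplicated(ids))
    ids <- make.unique(ids, sep = "_")
  funs <- sort(unique(unlist(lapply(proteomes, function(p) names(p$weights)))))
  w <- matrix(0, length(ids), length(funs), dimnames = list(ids, funs))
  for (k in seq_along(proteomes))
    w[k, names(proteomes[[k]]$weights)] <- proteomes[[k]]$weights
  list(net = TaxonFunctionNetwork(w, "pcn", normalize = TRUE),
       profile = AbundanceProfile(stats::setNames(abundances, ids),
                                  normalize = FALSE))
}
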