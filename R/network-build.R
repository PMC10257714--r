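## Network construction: the peptide-protein bridge for PCNs, read-count
## aggregation for GCNs, and unique-peptide biomass profiles.

#' Merge KEGG and COG annotations per protein group
#'
#' Function identity is the KEGG KO when present; groups lacking a KO fall
#' back to their COG; groups with neither are excluded (they carry no
#' functional information and never enter the PCN). KO and COG identifier
#' namespaces are disjoint by prefix, so the merged vocabulary is
#' collision-free.
#'
#' @param proteins protein-group data.frame from [readProteinTable()].
#' @return named character vector mapping `group_id` to function id.
#' @export
mergeAnnotations <- function(proteins) {
  fun <- ifelse(!is.na(proteins$ko), proteins$ko, proteins$cog)
  keep <- !is.na(fun)
  stats::setNames(fun[keep], proteins$group_id[keep])
}

#' Distribute protein-group intensity over genera via the peptide bridge
#'
#' Each protein group's intensity is split among the genera supported by its
#' genus-resolved unique peptides, proportionally to the summed
#' unique-peptide intensity each genus contributes to that group. Groups
#' whose peptides all have an LCA above genus level (or no unique peptide)
#' yield no assignment. Assigned intensities for one group always sum to the
#' group's intensity (conservation).
#'
#' @param proteins protein-group data.frame ([readProteinTable()]).
#' @param peptides peptide data.frame ([readPeptideTable()]).
#' @return data.frame with columns `group_id`, `genus`, `assigned_intensity`.
#' @examples
#' # a group of intensity 100 whose unique peptides contribute 30 to
#' # Bacteroides and 10 to Blautia is split 75 / 25
#' @export
bridgeProteinsToTaxa <- function(proteins, peptides) {
  pep_int <- stats::setNames(peptides$intensity, peptides$peptide_id)
  pep_gen <- stats::setNames(peptides$genus, peptides$peptide_id)
  pep_uni <- stats::setNames(peptides$is_unique, peptides$peptide_id)
  res <- vector("list", nrow(proteins))
  for (k in seq_len(nrow(proteins))) {
    ids <- proteins$peptide_ids[[k]]
    dangling <- setdiff(ids, peptides$peptide_id)
    if (length(dangling))
      stop("validation error: group ", proteins$group_id[k],
           " references unknown peptide(s): ",
           paste(dangling, collapse = ", "), call. = FALSE)
    use <- ids[pep_uni[ids] & !is.na(pep_gen[ids])]
    if (!length(use)) next
    by_gen <- tapply(pep_int[use], pep_gen[use], sum)
    share <- by_gen / sum(by_gen)
    res[[k]] <- data.frame(
      group_id = proteins$group_id[k], genus = names(share),
      assigned_intensity = proteins$intensity[k] * as.numeric(share),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(group_id = character(), genus = character(),
                      assigned_intensity = numeric())
  rownames(out) <- NULL
  out
}

.aggregate_network <- function(taxon, fun, value, kind) {
  keep <- value > 0
  taxon <- taxon[keep]; fun <- fun[keep]; value <- value[keep]
  if (!length(value))
    stop("empty network: no taxon retains any annotated, genus-resolved signal",
         call. = FALSE)
  tx <- sort(unique(taxon), method = "radix")
  fn <- sort(unique(fun), method = "radix")
  w <- matrix(0, length(tx), length(fn), dimnames = list(tx, fn))
  ij <- cbind(match(taxon, tx), match(fun, fn))
  for (r in seq_along(value)) w[ij[r, 1L], ij[r, 2L]] <-
      w[ij[r, 1L], ij[r, 2L]] + value[r]
  TaxonFunctionNetwork(w, kind, normalize = TRUE)
}

#' Build a proteomic content network (PCN)
#'
#' Composes [mergeAnnotations()] and [bridgeProteinsToTaxa()]: protein-group
#' intensity assigned to genus i for function a is summed into cell (i, a),
#' then each row is normalised by its total so row i holds the relative
#' expressed-function profile P_ia of taxon i. Taxa with no assigned
#' annotated intensity are absent.
#'
#' @inheritParams bridgeProteinsToTaxa
#' @return a [TaxonFunctionNetwork-class] of kind `"pcn"`.
#' @export
buildPCN <- function(proteins, peptides) {
  ann <- mergeAnnotations(proteins)
  br <- bridgeProteinsToTaxa(proteins, peptides)
  br <- br[br$group_id %in% names(ann), , drop = FALSE]
  .aggregate_network(br$genus, unname(ann[br$group_id]),
                     br$assigned_intensity, "pcn")
}

#' Build a genomic content network (GCN)
#'
#' Sums read counts per (taxon, function) and row-normalises, so row i holds
#' the relative encoded-function profile G_ia of taxon i.
#'
#' @param genes gene data.frame from [readGeneTable()].
#' @return a [TaxonFunctionNetwork-class] of kind `"gcn"`.
#' @export
buildGCN <- function(genes) {
  .aggregate_network(genes$taxon, genes$function_id,
                     as.numeric(genes$read_count), "gcn")
}

#' Genus biomass profile from unique peptides
#'
#' The protein-level biomass proportion p_i of genus i is the summed
#' intensity of unique peptides whose LCA resolves to genus i (i.e. the
#' lineage contains a genus entry), divided by the total over all genera.
#' Non-unique peptides and peptides with an LCA above genus are excluded.
#'
#' @param peptides peptide data.frame ([readPeptideTable()]).
#' @return an [AbundanceProfile-class].
#' @export
biomassProfile <- function(peptides) {
  use <- peptides$is_unique & !is.na(peptides$genus)
  if (!any(use))
    stop("no genus-resolved unique peptides: biomass profile undefined",
         call. = FALSE)
  sums <- tapply(peptides$intensity[use], peptides$genus[use], sum)
  AbundanceProfile(sums[sort(names(sums), method = "radix")])
}

#' Genera making up the top biomass fraction
#'
#' Sorts genera by descending proportion and returns the smallest prefix
#' whose cumulative biomass first reaches `fraction` (the genus crossing the
#' threshold is included). Genera tied with the boundary genus are all
#' included, which keeps the selection deterministic under relabeling.
#'
#' @param profile an [AbundanceProfile-class].
#' @param fraction target cumulative biomass in (0, 1]; default 0.95.
#' @return character vector of genus labels.
#' @export
filterTopBiomass <- function(profile, fraction = 0.95) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be a single value in (0, 1]", call. = FALSE)
  p <- sort(proportions(profile), decreasing = TRUE)
  cum <- cumsum(p)
  k <- which(cum >= fraction - 1e-12)[1L]
  if (is.na(k)) k <- length(p)
  names(p)[p >= p[k]]
}
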