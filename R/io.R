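## Tabular input/output. Schemas are deliberately minimal TSVs capturing the
## fields the peptide-protein bridge needs (not raw search-engine exports):
##   peptides : peptide_id, sequence, intensity, is_unique, lineage
##   proteins : group_id, peptide_ids (";"-joined), intensity, ko, cog
##   genes    : gene_id, taxon, function_id, read_count
## Lineage strings are ";"-separated "rank:name" pairs in superkingdom->species
## order; ranks below the LCA are simply absent.

.read_tsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("schema error in ", path, ": missing required column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

.parse_numeric <- function(x, what, nonneg = TRUE) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | (nonneg & v < 0))
  if (length(bad))
    stop("validation error: ", what, " invalid at row ", bad[1L],
         " (value \"", x[bad[1L]], "\")", call. = FALSE)
  v
}

#' Read a peptide table
#'
#' Parses a TSV of identified peptides with their MS intensities, uniqueness
#' flags and lowest-common-ancestor (LCA) lineages. Malformed rows raise
#' row-addressed errors; rows are never dropped silently.
#'
#' @param path path to a TSV with columns `peptide_id`, `sequence`,
#'   `intensity`, `is_unique`, `lineage`.
#' @return data.frame with those columns (`intensity` numeric, `is_unique`
#'   logical) plus a derived `genus` column (`NA` when the LCA is above genus).
#' @examples
#' tmp <- tempfile(fileext = ".tsv")
#' writeLines(c("peptide_id\tsequence\tintensity\tis_unique\tlineage",
#'   "pep1\tAAK\t60\tTRUE\tsuperkingdom:Bacteria;genus:Bacteroides"), tmp)
#' readPeptideTable(tmp)
#' @export
readPeptideTable <- function(path) {
  df <- .read_tsv(path, c("peptide_id", "sequence", "intensity",
                          "is_unique", "lineage"))
  out <- data.frame(
    peptide_id = df$peptide_id,
    sequence = df$sequence,
    intensity = .parse_numeric(df$intensity, "intensity"),
    is_unique = toupper(df$is_unique) %in% c("TRUE", "T", "1"),
    lineage = df$lineage,
    stringsAsFactors = FALSE)
  bad <- which(out$is_unique & !nzchar(out$lineage))
  if (length(bad))
    stop("validation error: unique peptide with empty lineage at row ",
         bad[1L], call. = FALSE)
  if (anyDuplicated(out$peptide_id))
    stop("validation error: duplicated peptide_id ",
         out$peptide_id[anyDuplicated(out$peptide_id)], call. = FALSE)
  out$genus <- lineageGenus(out$lineage)
  out
}

#' Extract the genus entry from LCA lineage strings
#'
#' @param lineage character vector of ";"-separated "rank:name" pairs.
#' @return character vector of genus names; `NA` where no genus rank is
#'   present (LCA above genus).
#' @export
lineageGenus <- function(lineage) {
  vapply(strsplit(lineage, ";", fixed = TRUE), function(parts) {
    hit <- grep("^genus:", parts, value = TRUE)
    if (length(hit)) sub("^genus:", "", hit[1L]) else NA_character_
  }, character(1))
}

#' Read a protein-groups table
#'
#' @param path TSV with columns `group_id`, `peptide_ids` (";"-joined),
#'   `intensity`, `ko`, `cog` (`ko`/`cog` may be empty).
#' @return data.frame with `peptide_ids` as a list-column of character
#'   vectors and `ko`/`cog` as `NA` when empty.
#' @export
readProteinTable <- function(path) {
  df <- .read_tsv(path, c("group_id", "peptide_ids", "intensity", "ko", "cog"))
  bad <- which(!nzchar(df$peptide_ids))
  if (length(bad))
    stop("validation error: empty peptide_ids at row ", bad[1L], call. = FALSE)
  out <- data.frame(group_id = df$group_id, stringsAsFactors = FALSE)
  out$peptide_ids <- strsplit(df$peptide_ids, ";", fixed = TRUE)
  out$intensity <- .parse_numeric(df$intensity, "intensity")
  out$ko <- ifelse(nzchar(df$ko), df$ko, NA_character_)
  out$cog <- ifelse(nzchar(df$cog), df$cog, NA_character_)
  if (anyDuplicated(out$group_id))
    stop("validation error: duplicated group_id", call. = FALSE)
  out
}

#' Read a gene table (GCN input)
#'
#' @param path TSV with columns `gene_id`, `taxon`, `function_id`,
#'   `read_count` (non-negative integers).
#' @return data.frame; `read_count` integer.
#' @export
readGeneTable <- function(path) {
  df <- .read_tsv(path, c("gene_id", "taxon", "function_id", "read_count"))
  v <- suppressWarnings(as.numeric(df$read_count))
  bad <- which(is.na(v) | v < 0 | v != round(v))
  if (length(bad))
    stop("validation error: read_count must be a non-negative integer at row ",
         bad[1L], " (value \"", df$read_count[bad[1L]], "\")", call. = FALSE)
  data.frame(gene_id = df$gene_id, taxon = df$taxon,
             function_id = df$function_id, read_count = as.integer(v),
             stringsAsFactors = FALSE)
}

## Full-precision numeric formatting so write/read round-trips are bit-exact.
.fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a network as long-format TSV
#'
#' `writeNetwork()` writes exactly the nonzero entries as rows
#' (taxon, function, weight), ordered lexicographically by taxon then
#' function; weights are written at full precision so a read-back
#' reconstructs the matrix bit-exactly. `readNetwork()` reverses it.
#'
#' @param net a [TaxonFunctionNetwork-class].
#' @param path output/input TSV path.
#' @param kind network kind for `readNetwork()`.
#' @return `writeNetwork()` returns `path` invisibly; `readNetwork()` a
#'   [TaxonFunctionNetwork-class] (not re-normalised: weights are taken as
#'   written).
#' @export
writeNetwork <- function(net, path) {
  stopifnot(is(net, "TaxonFunctionNetwork"))
  w <- networkWeights(net)
  idx <- which(w > 0, arr.ind = TRUE)
  df <- data.frame(taxon = as.character(rownames(w))[idx[, 1L]],
                   func = as.character(colnames(w))[idx[, 2L]],
                   weight = .fmt_num(w[idx]), stringsAsFactors = FALSE)
  df <- df[order(df$taxon, df$func, method = "radix"), , drop = FALSE]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("taxon\tfunction\tweight", con)
  if (nrow(df))
    writeLines(paste(df$taxon, df$func, df$weight, sep = "\t"), con)
  invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path, kind = c("pcn", "gcn")) {
  kind <- match.arg(kind)
  df <- .read_tsv(path, c("taxon", "function", "weight"))
  tx <- sort(unique(df$taxon), method = "radix")
  fn <- sort(unique(df$`function`), method = "radix")
  w <- matrix(0, length(tx), length(fn), dimnames = list(tx, fn))
  w[cbind(match(df$taxon, tx), match(df$`function`, fn))] <-
    .parse_numeric(df$weight, "weight")
  TaxonFunctionNetwork(w, kind, normalize = FALSE)
}

#' Write helper tables
#'
#' `writePeptideTable()`, `writeProteinTable()` and `writeGeneTable()` write
#' the TSV schemas consumed by the corresponding readers (used by the
#' synthetic-data generator and for round-trip testing);
#' `writeBiomassTable()` writes a two-column (genus, proportion) TSV;
#' `writeDiversityJSON()` exports a [DiversitySummary-class] as JSON.
#'
#' @param peptides,proteins,genes data.frames in reader format.
#' @param profile an [AbundanceProfile-class].
#' @param x a [DiversitySummary-class].
#' @param path output path.
#' @return the path, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
writePeptideTable <- function(peptides, path) {
  df <- peptides
  df$intensity <- .fmt_num(df$intensity)
  df$is_unique <- ifelse(df$is_unique, "TRUE", "FALSE")
  utils::write.table(
    df[, c("peptide_id", "sequence", "intensity", "is_unique", "lineage")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
writeProteinTable <- function(proteins, path) {
  df <- data.frame(
    group_id = proteins$group_id,
    peptide_ids = vapply(proteins$peptide_ids, paste, character(1),
                         collapse = ";"),
    intensity = .fmt_num(proteins$intensity),
    ko = ifelse(is.na(proteins$ko), "", proteins$ko),
    cog = ifelse(is.na(proteins$cog), "", proteins$cog),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
writeGeneTable <- function(genes, path) {
  utils::write.table(
    genes[, c("gene_id", "taxon", "function_id", "read_count")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
writeBiomassTable <- function(profile, path) {
  utils::write.table(
    data.frame(genus = taxa(profile), proportion = .fmt_num(proportions(profile))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
writeDiversityJSON <- function(x, path) {
  jsonlite::write_json(list(td = x@td, fd = x@fd, fr = x@fr, nfr = x@nfr),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
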