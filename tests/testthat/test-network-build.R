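mk_proteins <- function(...) {
  rows <- list(...)
  df <- data.frame(group_id = vapply(rows, `[[`, "", "group_id"),
                   stringsAsFactors = FALSE)
  df$peptide_ids <- lapply(rows, `[[`, "peptide_ids")
  df$intensity <- vapply(rows, `[[`, 0, "intensity")
  df$ko <- vapply(rows, function(r) r$ko %||% NA_character_, "")
  df$cog <- vapply(rows, function(r) r$cog %||% NA_character_, "")
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

mk_peptides <- function(ids, intensities, genera, unique = TRUE) {
  data.frame(peptide_id = ids, sequence = "AAK", intensity = intensities,
             is_unique = rep_len(unique, length(ids)),
             lineage = ifelse(is.na(genera), "superkingdom:Bacteria",
                              paste0("superkingdom:Bacteria;genus:", genera)),
             genus = genera, stringsAsFactors = FALSE)
}

test_that("KEGG annotation takes precedence over COG; unannotated excluded", {
  prot <- mk_proteins(
    list(group_id = "PG1", peptide_ids = "p1", intensity = 1,
         ko = "K00001", cog = "COG0001"),
    list(group_id = "PG2", peptide_ids = "p2", intensity = 1,
         cog = "COG0002"),
    list(group_id = "PG3", peptide_ids = "p3", intensity = 1))
  ann <- mergeAnnotations(prot)
  expect_equal(ann[["PG1"]], "K00001")
  expect_equal(ann[["PG2"]], "COG0002")
  expect_false("PG3" %in% names(ann))
})

test_that("bridge splits group intensity proportionally to unique-peptide intensity", {
  pep <- mk_peptides(c("p1", "p2", "p3"), c(30, 10, 99),
                     c("Bacteroides", "Blautia", NA))
  prot <- mk_proteins(list(group_id = "PG1",
                           peptide_ids = c("p1", "p2", "p3"),
                           intensity = 100, ko = "K00001"))
  br <- bridgeProteinsToTaxa(prot, pep)
  expect_equal(br$assigned_intensity[br$genus == "Bacteroides"], 75)
  expect_equal(br$assigned_intensity[br$genus == "Blautia"], 25)
  expect_equal(sum(br$assigned_intensity), 100)  # conservation
})

test_that("bridge excludes groups without genus-resolved unique peptides", {
  pep <- rbind(mk_peptides("p1", 5, NA),
               mk_peptides("p2", 5, "Blautia", unique = FALSE))
  prot <- mk_proteins(list(group_id = "PG1", peptide_ids = c("p1", "p2"),
                           intensity = 10, ko = "K1"))
  expect_equal(nrow(bridgeProteinsToTaxa(prot, pep)), 0L)
})

test_that("bridge reports dangling peptide references by group", {
  pep <- mk_peptides("p1", 5, "Blautia")
  prot <- mk_proteins(list(group_id = "PG9", peptide_ids = c("p1", "ghost"),
                           intensity = 10, ko = "K1"))
  expect_error(bridgeProteinsToTaxa(prot, pep), "PG9.*ghost")
})

test_that("PCN rows are normalized assigned intensities per function", {
  pep <- mk_peptides(c("p1", "p2"), c(1, 1), c("Bacteroides", "Bacteroides"))
  prot <- mk_proteins(
    list(group_id = "PG1", peptide_ids = "p1", intensity = 30, ko = "K00001"),
    list(group_id = "PG2", peptide_ids = "p2", intensity = 50, ko = "K00002"),
    list(group_id = "PG3", peptide_ids = "p2", intensity = 20, ko = "K00002"))
  pcn <- buildPCN(prot, pep)
  expect_equal(networkWeights(pcn)["Bacteroides", c("K00001", "K00002")],
               c(K00001 = 0.3, K00002 = 0.7))
  # two groups with the same function summed into one cell
  expect_equal(ncol(networkWeights(pcn)), 2L)
})

test_that("all-unannotated input raises an empty-network error", {
  pep <- mk_peptides("p1", 1, "Blautia")
  prot <- mk_proteins(list(group_id = "PG1", peptide_ids = "p1",
                           intensity = 10))
  expect_error(buildPCN(prot, pep), "empty network")
})

test_that("GCN aggregates and row-normalizes read counts, dropping empty taxa", {
  genes <- data.frame(
    gene_id = paste0("g", 1:5),
    taxon = c("T1", "T1", "T1", "T2", "T2"),
    function_id = c("K1", "K2", "K1", "K1", "K1"),
    read_count = c(5L, 2L, 3L, 0L, 0L), stringsAsFactors = FALSE)
  gcn <- buildGCN(genes[1:3, ])
  expect_equal(networkWeights(gcn)["T1", ], c(K1 = 0.8, K2 = 0.2))
  gcn2 <- buildGCN(genes)  # T2 rows all zero -> dropped
  expect_equal(taxa(gcn2), "T1")
})

test_that("built networks are row-stochastic for every retained taxon", {
  ds <- generateSyntheticDataset(syntheticSpec(nSamples = 2L, seed = 9))
  for (s in ds$samples) {
    for (net in list(buildPCN(s$proteins, s$peptides), buildGCN(s$genes))) {
      rs <- rowSums(networkWeights(net))
      expect_true(all(abs(rs - 1) < 1e-9))
    }
  }
})

test_that("biomass profile sums unique genus-resolved peptide intensities", {
  pep <- rbind(mk_peptides(c("p1", "p2"), c(60, 40),
                           c("Bacteroides", "Blautia")),
               mk_peptides("p3", 999, "Blautia", unique = FALSE),
               mk_peptides("p4", 999, NA))
  prof <- biomassProfile(pep)
  expect_equal(proportions(prof),
               c(Bacteroides = 0.6, Blautia = 0.4))
  expect_error(biomassProfile(mk_peptides("p1", 1, NA)),
               "no genus-resolved unique peptides")
})

test_that("top-biomass filter includes the genus crossing the threshold", {
  prof <- mk_profile(c(A = 0.6, B = 0.3, C = 0.1))
  expect_setequal(filterTopBiomass(prof, 0.95), c("A", "B", "C"))
  expect_setequal(filterTopBiomass(prof, 1.0), c("A", "B", "C"))
  expect_setequal(filterTopBiomass(prof, 0.85), c("A", "B"))
  prof2 <- mk_profile(c(A = 0.96, B = 0.04))
  expect_equal(filterTopBiomass(prof2, 0.95), "A")
  expect_error(filterTopBiomass(prof, 0), "fraction")
})

test_that("top-biomass selection is monotone in the fraction", {
  set.seed(42)
  for (rep in 1:20) {
    p <- stats::rlnorm(12)
    prof <- mk_profile(p / sum(p))
    fr <- sort(stats::runif(2))
    expect_true(all(filterTopBiomass(prof, fr[1]) %in%
                    filterTopBiomass(prof, fr[2])))
  }
})
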