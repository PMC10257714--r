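## shared fixture: nested-ish PCN inside a denser GCN
null_fixture <- function(seed = 21) {
  set.seed(seed)
  gcn_b <- matrix(stats::runif(8 * 12) < 0.7, 8, 12)
  gcn_b[, 1] <- TRUE
  pcn_b <- gcn_b & matrix(stats::runif(8 * 12) < 0.6, 8, 12)
  pcn_b[cbind(1:8, max.col(gcn_b))] <- TRUE  # no empty PCN rows
  dn <- list(sprintf("G%02d", 1:8), sprintf("K%05d", 1:12))
  gcn <- TaxonFunctionNetwork(matrix(as.numeric(gcn_b), 8, dimnames = dn), "gcn")
  w <- matrix(0, 8, 12, dimnames = dn)
  w[pcn_b] <- stats::rlnorm(sum(pcn_b))
  pcn <- TaxonFunctionNetwork(w, "pcn")
  list(pcn = pcn, gcn = gcn)
}

test_that("nullSpec derives the degree-preservation flags from the variant", {
  expect_false(nullSpec("null1")$preserve_taxon_degree)
  expect_true(nullSpec("null2")$preserve_taxon_degree)
  expect_false(nullSpec("null2")$preserve_function_degree)
  expect_true(nullSpec("null3")$preserve_function_degree)
  sp4 <- nullSpec("null4")
  expect_true(sp4$preserve_taxon_degree && sp4$preserve_function_degree)
  expect_error(nullSpec("null1", weightPolicy = "permute"), "permute")
})

test_that("every replicate's edges are GCN edges with the PCN's edge count", {
  fx <- null_fixture()
  bp <- networkWeights(fx$pcn) > 0
  bg <- networkWeights(fx$gcn) > 0
  for (v in c("null1", "null2", "null3", "null4")) {
    reps <- randomizeNetwork(fx$pcn, fx$gcn, nullSpec(v, 5, seed = 3))
    for (r in reps) {
      br <- networkWeights(r) > 0
      expect_true(all(bg[br]), info = v)          # edge-subset property
      expect_equal(sum(br), sum(bp), info = v)    # edge count conserved
    }
  }
})

test_that("degree sequences are preserved exactly per variant", {
  fx <- null_fixture()
  bp <- networkWeights(fx$pcn) > 0
  for (v in c("null2", "null4")) {
    for (r in randomizeNetwork(fx$pcn, fx$gcn, nullSpec(v, 5, seed = 4)))
      expect_equal(rowSums(networkWeights(r) > 0), rowSums(bp), info = v)
  }
  for (v in c("null3", "null4")) {
    for (r in randomizeNetwork(fx$pcn, fx$gcn, nullSpec(v, 5, seed = 4)))
      expect_equal(colSums(networkWeights(r) > 0), colSums(bp), info = v)
  }
})

test_that("identical seeds give identical replicate sequences", {
  fx <- null_fixture()
  for (v in c("null1", "null4")) {
    a <- randomizeNetwork(fx$pcn, fx$gcn, nullSpec(v, 3, seed = 11))
    b <- randomizeNetwork(fx$pcn, fx$gcn, nullSpec(v, 3, seed = 11))
    expect_identical(lapply(a, networkWeights), lapply(b, networkWeights))
    c_ <- randomizeNetwork(fx$pcn, fx$gcn, nullSpec(v, 3, seed = 12))
    expect_false(identical(lapply(a, networkWeights),
                           lapply(c_, networkWeights)))
  }
})

test_that("null4 with GCN equal to PCN returns the only configuration", {
  fx <- null_fixture()
  gcn_eq <- TaxonFunctionNetwork(networkWeights(fx$pcn), "gcn",
                                 normalize = FALSE)
  reps <- randomizeNetwork(fx$pcn, gcn_eq, nullSpec("null4", 3, seed = 5))
  bp <- networkWeights(fx$pcn) > 0
  for (r in reps) expect_equal(networkWeights(r) > 0, bp)
})

test_that("null2 samples per-taxon function subsets uniformly", {
  ## taxon degrees 2 and 1 inside GCN degrees 3 and 2:
  ## 3 subsets for the first taxon x 2 for the second = 6 configurations
  dn <- list(c("G01", "G02"), c("K1", "K2", "K3"))
  gcn <- TaxonFunctionNetwork(
    matrix(c(1, 1, 1, 1, 1, 0), 2, byrow = TRUE, dimnames = dn), "gcn")
  pcn <- TaxonFunctionNetwork(
    matrix(c(1, 1, 0, 1, 0, 0), 2, byrow = TRUE, dimnames = dn), "pcn")
  reps <- randomizeNetwork(pcn, gcn, nullSpec("null2", 3000L, seed = 1))
  keys <- vapply(reps, function(r)
    paste(which(networkWeights(r) > 0), collapse = ","), "")
  counts <- table(keys)
  expect_equal(length(counts), 6L)  # all feasible configurations visited
  chi <- stats::chisq.test(as.vector(counts), p = rep(1 / 6, 6))
  expect_gt(chi$p.value, 1e-4)
})

test_that("PCN edges outside the GCN are dropped with a message", {
  dn <- list(c("G01", "G02"), c("K1", "K2"))
  gcn <- TaxonFunctionNetwork(
    matrix(c(1, 0, 1, 1), 2, byrow = TRUE, dimnames = dn), "gcn")
  pcn <- TaxonFunctionNetwork(
    matrix(c(1, 1, 1, 0), 2, byrow = TRUE, dimnames = dn), "pcn")
  expect_message(
    reps <- randomizeNetwork(pcn, gcn, nullSpec("null1", 2, seed = 1)),
    "dropped")
  for (r in reps)
    expect_true(all((networkWeights(gcn) > 0)[networkWeights(r) > 0]))
  bad <- TaxonFunctionNetwork(
    matrix(1, 1, 1, dimnames = list("Other", "K1")), "pcn")
  expect_error(randomizeNetwork(bad, gcn, nullSpec("null1", 1)), "universe")
})

test_that("null comparison table is consistent with sampleSummary", {
  fx <- null_fixture()
  prof <- mk_profile(rep(1 / 8, 8), taxa = taxa(fx$pcn))
  tab <- nullFRComparison(fx$pcn, fx$gcn, prof, nReplicates = 3, seed = 2)
  nat <- tab[tab$variant == "natural", ]
  s <- sampleSummary(fx$pcn, prof)
  expect_equal(nat$fr, fr(s))
  expect_equal(nat$nodf, nodf(fx$pcn)$nodf)
  expect_equal(nrow(tab), 1L + 4L * 3L)
  expect_true(all(tab$nfr >= 0 & tab$nfr <= 1))
})

test_that("connectance of null replicates never exceeds the GCN's", {
  fx <- null_fixture()
  cg <- connectance(fx$gcn)
  for (v in c("null1", "null4")) {
    for (r in randomizeNetwork(fx$pcn, fx$gcn, nullSpec(v, 3, seed = 6)))
      expect_lte(connectance(r), cg)
  }
})

test_that("degree-preserving nulls lower FR on a strongly nested sample", {
  spec <- syntheticSpec(nestednessTarget = 0.9, seed = 11, nSamples = 1L)
  ds <- generateSyntheticDataset(spec)
  s1 <- ds$samples$S01
  pcn <- buildPCN(s1$proteins, s1$peptides)
  gcn <- buildGCN(s1$genes)
  prof <- biomassProfile(s1$peptides)
  tab <- nullFRComparison(pcn, gcn, prof, variants = "null4",
                          nReplicates = 10, seed = 3,
                          weightPolicy = "permute")
  expect_lt(mean(tab$fr[tab$variant == "null4"]),
            tab$fr[tab$variant == "natural"])
})
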