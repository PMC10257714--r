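test_that("weighted Jaccard hits the analytic extremes and hand value", {
  ident <- mk_net(rbind(c(0.5, 0.5), c(0.5, 0.5)))
  expect_equal(distances(weightedJaccard(ident))[1, 2], 0)
  disj <- mk_net(rbind(c(1, 0), c(0, 1)))
  expect_equal(distances(weightedJaccard(disj))[1, 2], 1)
  hand <- mk_net(rbind(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5)), normalize = FALSE)
  expect_equal(distances(weightedJaccard(hand))[1, 2], 2 / 3)
})

test_that("Gini-Simpson diversity matches direct evaluation", {
  expect_equal(taxonomicDiversity(mk_profile(1)), 0)
  expect_equal(taxonomicDiversity(mk_profile(c(0.5, 0.5))), 0.5)
  expect_equal(taxonomicDiversity(mk_profile(rep(0.25, 4))), 0.75)
})

test_that("Rao entropy reduces to the expected closed forms", {
  p <- mk_profile(c(0.5, 0.5))
  d0 <- new("FunctionalDistanceMatrix",
            d = matrix(0, 2, 2, dimnames = list(taxa(p), taxa(p))))
  expect_equal(functionalDiversity(p, d0), 0)
  d1 <- new("FunctionalDistanceMatrix",
            d = matrix(c(0, 1, 1, 0), 2, dimnames = list(taxa(p), taxa(p))))
  expect_equal(functionalDiversity(p, d1), taxonomicDiversity(p))
  d23 <- new("FunctionalDistanceMatrix",
             d = matrix(c(0, 2/3, 2/3, 0), 2,
                        dimnames = list(taxa(p), taxa(p))))
  expect_equal(functionalDiversity(p, d23), 1 / 3)
  s <- functionalRedundancy(p, d23)
  expect_equal(fr(s), 1 / 6)
  expect_equal(nfr(s), 1 / 3)
})

test_that("identical proteomes give nFR 1; disjoint proteomes give nFR 0", {
  p <- mk_profile(c(0.5, 0.5))
  same <- mk_net(rbind(c(0.3, 0.7), c(0.3, 0.7)))
  s1 <- functionalRedundancy(p, weightedJaccard(same))
  expect_equal(fr(s1), 0.5)
  expect_equal(nfr(s1), 1)
  disj <- mk_net(rbind(c(1, 0), c(0, 1)))
  s0 <- functionalRedundancy(p, weightedJaccard(disj))
  expect_equal(fr(s0), 0)
  expect_equal(nfr(s0), 0)
})

test_that("nFR at TD = 0 (single taxon) is defined as 0", {
  s <- functionalRedundancy(
    mk_profile(1),
    new("FunctionalDistanceMatrix",
        d = matrix(0, 1, 1, dimnames = list("G01", "G01"))))
  expect_equal(td(s), 0)
  expect_equal(nfr(s), 0)
})

test_that("metrics match an independent brute-force oracle on random instances", {
  for (seed in 1:200) {
    set.seed(seed)
    S <- sample(2:6, 1); F_ <- sample(2:10, 1)
    net <- random_network(S, F_, seed + 1000L)
    p <- stats::runif(S)
    p <- p / sum(p)
    prof <- mk_profile(p, taxa = taxa(net))
    w <- networkWeights(net)
    ref <- oracle_metrics(w, p)
    s <- functionalRedundancy(prof, weightedJaccard(net))
    expect_equal(td(s), ref$td, tolerance = 1e-12)
    expect_equal(fd(s), ref$fd, tolerance = 1e-12)
    expect_equal(fr(s), ref$fr, tolerance = 1e-12)
    expect_equal(nfr(s), ref$nfr, tolerance = 1e-12)
    expect_equal(max(abs(distances(weightedJaccard(net)) - oracle_jaccard(w))),
                 0, tolerance = 1e-12)
  }
})

test_that("FR + FD = TD identity and nFR bounds hold on random samples", {
  for (seed in 1:50) {
    net <- random_network(5, 8, seed)
    set.seed(seed)
    prof <- mk_profile(stats::runif(5), taxa = taxa(net))
    s <- functionalRedundancy(prof, weightedJaccard(net))
    expect_equal(fr(s) + fd(s), td(s), tolerance = 1e-12)
    expect_gte(nfr(s), 0)
    expect_lte(nfr(s), 1)
  }
})

test_that("nFR equals the p-weighted mean functional overlap over pairs", {
  net <- random_network(5, 8, 77)
  set.seed(77)
  p <- stats::runif(5); p <- p / sum(p)
  prof <- mk_profile(p, taxa = taxa(net))
  d <- distances(weightedJaccard(net))
  num <- 0; den <- 0
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    num <- num + (1 - d[i, j]) * p[i] * p[j]
    den <- den + p[i] * p[j]
  }
  s <- functionalRedundancy(prof, weightedJaccard(net))
  expect_equal(nfr(s), num / den, tolerance = 1e-12)
})

test_that("relabeling taxa leaves all four indices unchanged", {
  net <- random_network(6, 9, 5)
  set.seed(5)
  p <- stats::runif(6); p <- p / sum(p)
  s1 <- functionalRedundancy(mk_profile(p, taxa = taxa(net)),
                             weightedJaccard(net))
  perm <- sample(6)
  w2 <- networkWeights(net)[perm, ]
  s2 <- functionalRedundancy(mk_profile(p[perm], taxa = rownames(w2)),
                             weightedJaccard(mk_net(w2, normalize = FALSE)))
  expect_equal(td(s2), td(s1), tolerance = 1e-12)
  expect_equal(fd(s2), fd(s1), tolerance = 1e-12)
  expect_equal(fr(s2), fr(s1), tolerance = 1e-12)
  expect_equal(nfr(s2), nfr(s1), tolerance = 1e-12)
})

test_that("sampleSummary aligns, renormalizes and matches manual composition", {
  net <- random_network(4, 6, 8)
  set.seed(8)
  p_all <- c(stats::runif(4), 0.2)
  names(p_all) <- c(taxa(net), "GhostGenus")
  prof <- AbundanceProfile(p_all)
  s <- sampleSummary(net, prof)
  p_kept <- proportions(prof)[taxa(net)]
  manual <- functionalRedundancy(AbundanceProfile(p_kept),
                                 weightedJaccard(net))
  expect_equal(td(s), td(manual))
  expect_equal(fr(s), fr(manual))
  expect_error(sampleSummary(net, mk_profile(1, taxa = "Nope")),
               "no taxa shared")
})

test_that("alignment errors are raised for mismatched taxa", {
  net <- random_network(3, 4, 2)
  d <- weightedJaccard(net)
  wrong <- mk_profile(c(0.5, 0.3, 0.2), taxa = c("X", "Y", "Z"))
  expect_error(functionalDiversity(wrong, d), "alignment")
  expect_error(functionalRedundancy(wrong, d), "alignment")
})
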