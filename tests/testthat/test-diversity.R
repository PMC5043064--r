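test_that("observed and effective allele counts match direct evaluation", {
  ds <- make_ds(list(list(c(100, 100), c(100, 102)),
                     list(c(100, 100), c(100, 100)),
                     list(c(100, 100), c(102, 104))),
                rep("P1", 3))
  ft <- allele_freqs(ds)
  oa <- observed_alleles(ft, "P1")
  expect_equal(unname(oa$by_locus), c(1, 3))
  expect_equal(oa$mean, 2)
  expect_equal(effective_alleles(c(1)), 1)
  expect_equal(effective_alleles(c(0.5, 0.5)), 2)
  expect_equal(effective_alleles(c(0.7, 0.2, 0.1)), 1 / 0.54)
  expect_true(is.na(effective_alleles(numeric(0))))
  # A_E in [1, A], equality iff uniform
  for (seed in 1:10) {
    set.seed(seed)
    k <- sample(2:6, 1)
    p <- as.vector(stats::rmultinom(1, 50, rep(1, k))) / 50
    p <- p[p > 0]
    ae <- effective_alleles(p)
    expect_gte(ae, 1 - 1e-12)
    expect_lte(ae, length(p) + 1e-12)
  }
})

test_that("rarefied allelic richness equals the exhaustive subsampling mean", {
  # counts {14, 10}: all choose(24, 20) draws of 20 gene copies
  counts <- c(14L, 10L)
  copies <- rep(1:2, counts)
  drop4 <- utils::combn(24, 4)
  vals <- apply(drop4, 2, function(out)
    length(unique(copies[-out])))
  expect_equal(rarefied_allelic_richness(counts, g = 10),
               mean(vals), tolerance = 1e-9)
  # second case with three alleles and a rarer one
  counts2 <- c(11L, 6L, 3L)
  copies2 <- rep(1:3, counts2)
  # 2g = 16 from N = 20 gene copies
  keep <- utils::combn(20, 4)
  vals2 <- apply(keep, 2, function(out) length(unique(copies2[-out])))
  expect_equal(rarefied_allelic_richness(counts2, g = 8),
               mean(vals2), tolerance = 1e-9)
  # monomorphic locus gives exactly 1; undersized sample is undefined
  expect_equal(rarefied_allelic_richness(c(40L), g = 10), 1)
  expect_true(is.na(rarefied_allelic_richness(c(10L, 9L), g = 10)))
  expect_error(rarefied_allelic_richness(c(-1L, 10L)), "negative")
  # A_R <= A and monotone non-decreasing in g
  set.seed(3)
  for (i in 1:10) {
    cnt <- as.vector(stats::rmultinom(1, 60, runif(5) + 0.1))
    cnt <- cnt[cnt > 0]
    ar5 <- rarefied_allelic_richness(cnt, 5)
    ar10 <- rarefied_allelic_richness(cnt, 10)
    expect_lte(ar5, ar10)
    expect_lte(ar10, length(cnt))
  }
})

test_that("heterozygosity estimators handle the small-sample corrections", {
  # all homozygotes
  hom <- make_ds(list(list(c(100, 100)), list(c(102, 102))), rep("P1", 2))
  h <- heterozygosities(hom, "P1")
  expect_equal(unname(h$H_O["L1"]), 0)
  # a single heterozygote individual: unbiased H_E is 1, plug-in is 0.5
  one <- make_ds(list(list(c(100, 102))), "P1")
  h1 <- heterozygosities(one, "P1")
  expect_equal(unname(h1$H_O["L1"]), 1)
  expect_equal(unname(h1$H_E["L1"]), 1)
  expect_equal(unname(h1$H_E_plugin["L1"]), 0.5)
  # direct-count oracle on a simulated population
  ds <- simulate_genotypes(sim_config(K = 1, N = 40, generations = 30,
                                      sample_n = 20, L = 5,
                                      seed = 9))$dataset
  h2 <- heterozygosities(ds, "POP01")
  for (j in seq_along(ds$loci)) {
    het <- mean(ds$a1[, j] != ds$a2[, j])
    expect_equal(unname(h2$H_O[j]), het)
    p <- table(c(ds$a1[, j], ds$a2[, j])) / 40
    expect_equal(unname(h2$H_E_plugin[j]), 1 - sum(p^2))
  }
})

test_that("F_IS estimators agree with their definitions", {
  # H_O == H_E at every locus -> Nei F_IS 0
  ds <- make_ds(list(list(c(100, 102)), list(c(100, 100)),
                     list(c(102, 102)), list(c(100, 102))),
                rep("P1", 4))
  h <- heterozygosities(ds, "P1")
  fis_nei <- f_is(ds, "P1", "nei")
  expect_equal(fis_nei, 1 - h$mean_H_O / h$mean_H_E)
  # all homozygous but polymorphic -> Nei F_IS = 1
  hom <- make_ds(list(list(c(100, 100)), list(c(102, 102))), rep("P1", 2))
  expect_equal(f_is(hom, "P1", "nei"), 1)
  # monomorphic everywhere -> undefined
  mono <- make_ds(list(list(c(100, 100)), list(c(100, 100))), rep("P1", 2))
  expect_true(is.na(f_is(mono, "P1", "nei")))
  expect_true(is.na(f_is(mono, "P1", "weir_cockerham")))
})

test_that("outcrossing transform and its identity hold", {
  expect_equal(round(outcrossing_rate(0.173), 3), 0.705)
  expect_equal(round(outcrossing_rate(-0.309), 3), 1.894)
  expect_equal(outcrossing_rate(0), 1)
  expect_error(outcrossing_rate(-1), "undefined")
  set.seed(1)
  fis <- runif(50, -0.9, 0.9)
  t <- outcrossing_rate(fis)
  expect_equal(t * (1 + fis), 1 - fis, tolerance = 1e-12)
})

test_that("the per-population diversity table obeys its invariants", {
  ds <- simulate_genotypes(scenario_presets(seed = 4)$fragmented_drift)
  div <- pop_diversity(ds$dataset)
  expect_true(all(div$H_O >= 0 & div$H_O <= 1))
  expect_true(all(div$H_E >= 0 & div$H_E <= 1))
  expect_true(all(div$A_E <= div$A + 1e-9))
  expect_true(all(is.na(div$A_R) | div$A_R <= div$A + 1e-9))
  expect_equal(div$t * (1 + div$F_IS), 1 - div$F_IS, tolerance = 1e-12)
  # A_R = A when N equals the rarefaction size and nothing is missing
  sub <- subset_individuals(ds$dataset,
                            which(ds$dataset$population == "POP01")[1:10])
  div10 <- pop_diversity(sub, g = 10)
  expect_equal(div10$A_R, div10$A, tolerance = 1e-12)
})

test_that("species summary reproduces the gene-diversity decomposition", {
  # identical frequencies across populations -> F_ST(nei) = 0
  geno <- list(list(c(100, 102)), list(c(100, 100)), list(c(102, 102)),
               list(c(100, 102)))
  ds_same <- make_ds(c(geno, geno), rep(c("P1", "P2"), each = 4))
  ss <- species_summary(ds_same, "sp1")
  expect_equal(ss$F_ST_nei, 0, tolerance = 1e-12)
  # fixed alternate alleles -> F_ST 1
  ds_fix <- make_ds(list(list(c(100, 100)), list(c(100, 100)),
                         list(c(104, 104)), list(c(104, 104))),
                    rep(c("P1", "P2"), each = 2))
  sf <- species_summary(ds_fix, "sp1")
  expect_equal(sf$F_ST_nei, 1, tolerance = 1e-12)
  expect_equal(sf$F_ST_wc, 1, tolerance = 1e-12)
  # H_T >= plug-in H_S on random simulated data; N_ind bookkeeping
  for (seed in 1:3) {
    sim <- simulate_genotypes(sim_config(K = 3, N = 30, m = 0.05,
                                         generations = 60, sample_n = 10,
                                         L = 5, seed = seed))
    s <- species_summary(sim$dataset, "sim")
    expect_gte(s$H_T, s$H_S_plugin - 1e-12)
    expect_equal(s$N_ind, 30L)
    expect_true(s$F_ST_nei >= 0 && s$F_ST_nei <= 1)
  }
})

test_that("private alleles match a brute-force set difference", {
  ds <- random_ds(11, n_pop = 3, n_per = 8, L = 4, miss_rate = 0.05)
  ft <- allele_freqs(ds)
  pa <- private_alleles(ft)
  pops <- attr(ft, "pops")
  for (l in attr(ft, "loci")) {
    sets <- lapply(pops, function(p) names(ft[[p]][[l]]$freq))
    names(sets) <- pops
    for (p in pops) {
      expected <- setdiff(sets[[p]], unlist(sets[setdiff(pops, p)]))
      got <- pa$allele[pa$population == p & pa$locus == l]
      expect_setequal(as.character(got), expected)
    }
  }
  # an allele in two populations is never private
  ds2 <- make_ds(list(list(c(100, 102)), list(c(100, 100)),
                      list(c(100, 104))),
                 c("P1", "P2", "P3"))
  pa2 <- private_alleles(allele_freqs(ds2))
  expect_false(100 %in% pa2$allele)
  expect_setequal(pa2$allele, c(102L, 104L))
  expect_equal(pa2$freq[pa2$allele == 102], 0.5)
})
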