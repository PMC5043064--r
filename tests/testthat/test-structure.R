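test_that("Weir-Cockerham theta matches the algebraic oracle", {
  # 2 populations, 1 locus, explicit genotype lists
  ds <- make_ds(list(list(c(100, 100)), list(c(100, 102)),
                     list(c(100, 102)), list(c(102, 102)),
                     list(c(102, 102)), list(c(100, 102)),
                     list(c(102, 102)), list(c(102, 104))),
                rep(c("P1", "P2"), each = 4))
  inp <- msatpop:::locus_wc_input(ds, c("P1", "P2"), 1L)
  oracle <- wc_oracle_theta(inp$nvec, inp$pmat, inp$hmat)
  expect_equal(wc_fstats(ds)$theta, oracle, tolerance = 1e-12)
  # fixed alternate alleles give theta = 1
  fix <- make_ds(list(list(c(100, 100)), list(c(100, 100)),
                      list(c(104, 104)), list(c(104, 104))),
                 rep(c("P1", "P2"), each = 2))
  expect_equal(wc_fstats(fix)$theta, 1)
  # duplicated populations give theta near zero and permutation p near 1
  ds0 <- random_ds(3, n_pop = 1, n_per = 10, L = 4, miss_rate = 0)
  dup <- genotype_dataset(rbind(ds0$a1, ds0$a1), rbind(ds0$a2, ds0$a2),
                          paste0("i", 1:20),
                          rep(c("P1", "P2"), each = 10), loci = ds0$loci)
  pw <- pairwise_fst(dup, n_perm = 200, seed = 2)
  expect_lt(abs(pw$value["P1", "P2"]), 0.1)
  expect_gt(pw$p_value["P1", "P2"], 0.5)
  # theta invariant to allele relabelling
  relab <- genotype_dataset(ds$a1 + 40L, ds$a2 + 40L, ds$individuals,
                            ds$population, ds$species, ds$loci)
  expect_equal(wc_fstats(relab)$theta, wc_fstats(ds)$theta)
})

test_that("R_ST matches a hand ANOVA and its invariances", {
  # 6 individuals, 2 populations, 1 locus
  ds <- make_ds(list(list(c(100, 102)), list(c(102, 102)),
                     list(c(100, 104)), list(c(108, 110)),
                     list(c(110, 110)), list(c(108, 112))),
                rep(c("P1", "P2"), each = 3))
  sizes <- list(P1 = c(100, 102, 102, 102, 100, 104),
                P2 = c(108, 110, 110, 110, 108, 112))
  y <- unlist(sizes); grp <- rep(c(1, 2), each = 6)
  N <- 12; r <- 2; n_i <- c(6, 6)
  means <- tapply(y, grp, mean)
  ssb <- sum(n_i * (means - mean(y))^2)
  ssw <- sum((y - means[grp])^2)
  msb <- ssb / (r - 1); msw <- ssw / (N - r)
  nc <- (N - sum(n_i^2) / N) / (r - 1)
  sa <- (msb - msw) / nc
  expect_equal(r_st(ds)$rst, sa / (sa + msw), tolerance = 1e-12)
  # fixed distinct sizes give R_ST = 1; shifting a locus changes nothing
  fix <- make_ds(list(list(c(100, 100)), list(c(100, 100)),
                      list(c(120, 120)), list(c(120, 120))),
                 rep(c("P1", "P2"), each = 2))
  expect_equal(r_st(fix)$rst, 1)
  shifted <- genotype_dataset(ds$a1 + 50L, ds$a2 + 50L, ds$individuals,
                              ds$population, ds$species, ds$loci)
  expect_equal(r_st(shifted)$rst, r_st(ds)$rst, tolerance = 1e-12)
  # identical size distributions across populations: R_ST near zero
  ds0 <- random_ds(5, n_pop = 1, n_per = 12, L = 3, miss_rate = 0)
  dup <- genotype_dataset(rbind(ds0$a1, ds0$a1), rbind(ds0$a2, ds0$a2),
                          paste0("i", 1:24),
                          rep(c("P1", "P2"), each = 12), loci = ds0$loci)
  expect_lt(abs(r_st(dup)$rst), 0.1)
})

test_that("allele-size permutation test follows the add-one rule", {
  sim <- simulate_genotypes(sim_config(K = 3, N = 40, m = 0.02,
                                       generations = 80, sample_n = 15,
                                       L = 5, seed = 6))
  ds <- sim$dataset
  res <- allele_size_permutation_test(ds, n_perm = 99, seed = 4)
  expect_gte(res$p_value, 1 / 100)
  expect_lte(res$p_value, 1)
  # the permutational null is a size-blind (F_ST-like) quantity
  res2 <- allele_size_permutation_test(ds, n_perm = 300, seed = 9)
  theta <- wc_fstats(ds)$theta
  expect_lt(abs(res2$prst_mean - theta), 0.06)
  expect_error(allele_size_permutation_test(ds, n_perm = 0), ">= 1")
  # fully monomorphic data: no test
  mono <- make_ds(list(list(c(100, 100)), list(c(100, 100))),
                  c("P1", "P2"))
  expect_true(is.na(allele_size_permutation_test(mono, 10)$p_value))
})

test_that("Nei distances match direct formula evaluation", {
  ds <- make_ds(list(list(c(100, 100), c(200, 202)),
                     list(c(100, 102), c(200, 200)),
                     list(c(100, 102), c(202, 202)),
                     list(c(102, 102), c(202, 204))),
                rep(c("P1", "P2"), each = 2))
  ft <- allele_freqs(ds)
  # hand evaluation, locus by locus
  x1 <- c(`100` = 0.75, `102` = 0.25); y1 <- c(`100` = 0.25, `102` = 0.75)
  x2 <- c(`200` = 0.75, `202` = 0.25); y2 <- c(`202` = 0.75, `204` = 0.25)
  da_hand <- 1 - mean(c(sum(sqrt(x1 * y1)),
                        sqrt(x2[["202"]] * y2[["202"]])))
  expect_equal(nei_distance(ft, "P1", "P2", "DA"), da_hand,
               tolerance = 1e-12)
  jxy <- mean(c(sum(x1 * y1), x2[["202"]] * y2[["202"]]))
  jx <- mean(c(sum(x1^2), sum(x2^2))); jy <- mean(c(sum(y1^2), sum(y2^2)))
  expect_equal(nei_distance(ft, "P1", "P2", "standard"),
               -log(jxy / sqrt(jx * jy)), tolerance = 1e-12)
  # identical populations at distance zero; disjoint alleles at DA = 1
  same <- make_ds(list(list(c(100, 102)), list(c(100, 102))),
                  c("P1", "P2"))
  fts <- allele_freqs(same)
  expect_equal(nei_distance(fts, "P1", "P2", "DA"), 0)
  expect_equal(nei_distance(fts, "P1", "P2", "standard"), 0)
  disj <- make_ds(list(list(c(100, 100)), list(c(120, 120))),
                  c("P1", "P2"))
  expect_equal(nei_distance(allele_freqs(disj), "P1", "P2", "DA"), 1)
})

test_that("neighbor joining is exact on additive matrices", {
  # 3 taxa: closed-form branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- neighbor_joining(d3)
  expect_equal(sort(tr3$edge.length), sort(c(1, 2, 3)))
  # additive matrices on 4..8 taxa: recovered path metric equals input
  for (k in 4:8) {
    add <- random_additive(100 + k, k)
    tr <- neighbor_joining(add$d)
    path <- cophenetic(tr)[rownames(add$d), colnames(add$d)]
    expect_equal(path, add$d, tolerance = 1e-9)
    # topology agrees with the independent implementation in ape
    expect_equal(ape::dist.topo(ape::unroot(tr),
                                ape::unroot(ape::nj(as.dist(add$d)))),
                 structure(0, names = "PH85"), ignore_attr = TRUE)
  }
  # small perturbation below the additivity margin keeps the topology
  add <- random_additive(7, 6)
  set.seed(1)
  pert <- add$d + matrix(runif(36, -0.01, 0.01), 6, 6)
  pert <- (pert + t(pert)) / 2; diag(pert) <- 0
  expect_equal(ape::dist.topo(ape::unroot(neighbor_joining(pert)),
                              ape::unroot(neighbor_joining(add$d))),
               structure(0, names = "PH85"), ignore_attr = TRUE)
  expect_error(neighbor_joining(matrix(c(0, NA, NA, 0), 2, 2)),
               "at least three")
})

test_that("negative NJ branches are clamped with raw lengths kept", {
  d <- matrix(c(0, 2, 2, 2.5,
                2, 0, 0.1, 2.5,
                2, 0.1, 0, 2.5,
                2.5, 2.5, 2.5, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
  expect_length(attr(tr, "raw_edge_length"), length(tr$edge.length))
})

test_that("locus bootstrap supports behave at the extremes", {
  # two well-separated simulated clusters: 100% support for the split
  base <- simulate_genotypes(sim_config(K = 2, N = 50, m = 0.1,
                                        generations = 60, sample_n = 15,
                                        L = 6, seed = 21))$dataset
  far <- simulate_genotypes(sim_config(K = 2, N = 50, m = 0.1,
                                       generations = 60, sample_n = 15,
                                       L = 6, seed = 22))$dataset
  far_shift <- genotype_dataset(far$a1 + 100L, far$a2 + 100L,
                                paste0("x", seq_along(far$individuals)),
                                c("P3", "P4")[match(far$population,
                                                    c("POP01", "POP02"))],
                                far$species, far$loci)
  base2 <- genotype_dataset(base$a1, base$a2, base$individuals,
                            c("P1", "P2")[match(base$population,
                                                c("POP01", "POP02"))],
                            base$species, base$loci)
  comb <- genotype_dataset(rbind(base2$a1, far_shift$a1),
                           rbind(base2$a2, far_shift$a2),
                           c(base2$individuals, far_shift$individuals),
                           c(base2$population, far_shift$population),
                           c(base2$species, far_shift$species), base$loci)
  bt <- bootstrap_tree(comb, B = 60, seed = 5)
  supp <- attr(bt, "split_support")
  sep <- paste(sort(c("P3", "P4")), collapse = "\r")
  expect_gte(supp[[sep]], 95)
  # B = 1 gives supports in {0, 100}; input order does not matter
  b1 <- bootstrap_tree(comb, B = 1, seed = 9)
  expect_true(all(attr(b1, "split_support") %in% c(0, 100)))
  perm <- sample(length(comb$individuals))
  bt2 <- bootstrap_tree(subset_individuals(comb, perm), B = 60, seed = 5)
  expect_equal(attr(bt2, "split_support")[names(supp)], supp)
  one_locus <- genotype_dataset(comb$a1[, 1, drop = FALSE],
                                comb$a2[, 1, drop = FALSE],
                                comb$individuals, comb$population,
                                comb$species, comb$loci[1])
  expect_error(bootstrap_tree(one_locus, B = 10), "at least 2 loci")
})
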