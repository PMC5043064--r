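test_that("EM returns zero null frequency at Hardy-Weinberg proportions", {
  # exact HW counts for p = (0.5, 0.5), n = 16: 4 / 8 / 4, no blanks
  cnt <- counts_from_pairs(c(rep(100, 12), rep(102, 4)),
                           c(rep(100, 4), rep(102, 12)))
  est <- em_null_frequency(cnt)
  expect_true(est$converged)
  expect_lt(est$r_hat, 1e-3)
  # likelihood trace is non-decreasing
  expect_true(all(diff(est$loglik) >= -1e-9))
})

test_that("EM equals a grid-search maximiser of the same likelihood", {
  # apparent counts with a clear homozygote excess plus blanks
  cases <- list(
    list(hom = c(10L, 6L), het = 2L, blank = 2L),
    list(hom = c(8L, 2L), het = 6L, blank = 0L),
    list(hom = c(12L, 9L), het = 1L, blank = 3L))
  for (cs in cases) {
    cnt <- matrix(c(cs$hom[1], cs$het, 0, cs$hom[2]), 2, 2,
                  dimnames = list(c(100, 102), c(100, 102)))
    est <- em_null_frequency(cnt, n_blank = cs$blank)
    loglik <- function(r, q) {
      p1 <- (1 - r) * q; p2 <- (1 - r) * (1 - q)
      v <- cs$het * log(2 * p1 * p2) +
        cs$hom[1] * log(p1^2 + 2 * p1 * r) +
        cs$hom[2] * log(p2^2 + 2 * p2 * r)
      if (cs$blank > 0) v <- v + cs$blank * log(r^2)
      v
    }
    rs <- seq(1e-4, 0.9, by = 1e-4)
    prof <- vapply(rs, function(r)
      stats::optimize(function(q) loglik(r, q), c(1e-6, 1 - 1e-6),
                      maximum = TRUE)$objective, numeric(1))
    r_grid <- rs[which.max(prof)]
    expect_equal(est$r_hat, r_grid, tolerance = 1e-3)
  }
})

test_that("null frequency estimates are label-free and recover injections", {
  # relabelling allele sizes leaves r_hat unchanged
  cnt <- counts_from_pairs(c(rep(100, 9), rep(104, 3)),
                           c(rep(100, 5), rep(104, 7)))
  shifted <- counts_from_pairs(c(rep(222, 9), rep(318, 3)),
                               c(rep(222, 5), rep(318, 7)))
  expect_equal(em_null_frequency(cnt, 1)$r_hat,
               em_null_frequency(shifted, 1)$r_hat)
  # parameter recovery across simulated replicates
  err <- numeric(0)
  for (b in 1:10) {
    sim <- simulate_genotypes(sim_config(
      K = 2, N = 100, m = 0.05, generations = 80, sample_n = 30, L = 4,
      null_spec = c(0.2, 0, 0, 0), seed = 500 + b))
    nt <- null_allele_table(sim$dataset)
    m <- merge(nt, sim$truth$null_info, by = c("population", "locus"))
    err <- c(err, m$r_hat - m$realized_r)
  }
  expect_lt(abs(mean(err)), 3 * stats::sd(err) / sqrt(length(err)) + 0.02)
})

test_that("ENA correction is the identity without nulls and reduces bias", {
  # no blanks, no homozygote excess anywhere: r_hat is 0, theta untouched
  geno <- function(po) list(
    list(c(100, 102), c(100, 104)), list(c(100, 100), c(100, 104)),
    list(c(102, 102), c(104, 104)), list(c(100, 102), c(104, 104)))
  ds <- make_ds(c(geno("a"), geno("b")), rep(c("P1", "P2"), each = 4))
  # make the populations differ at locus 1 to have positive theta
  ds$a1[5:8, 1] <- 106L; ds$a2[5:8, 1] <- 106L
  ds <- genotype_dataset(ds$a1, ds$a2, ds$individuals, ds$population,
                         ds$species, ds$loci)
  nt <- null_allele_table(ds)
  en <- ena_corrected_fst(ds, null_table = nt)
  if (max(nt$r_hat, na.rm = TRUE) < 1e-9)
    expect_identical(en$theta_corrected, en$theta_uncorrected)
  # injected nulls: corrected theta closer to the clean-data theta
  closer <- 0L; reps <- 10L
  for (b in seq_len(reps)) {
    # strongly drift-structured pair, the regime where null bias matters
    sim <- simulate_genotypes(sim_config(
      K = 2, N = 50, m = 0.004, generations = 250, sample_n = 25, L = 8,
      null_spec = c(rep(0.25, 3), rep(0, 5)), seed = 800 + b))
    truth <- wc_fstats(sim$clean_dataset)$theta
    en2 <- ena_corrected_fst(sim$dataset)
    if (abs(en2$theta_corrected - truth) <=
        abs(en2$theta_uncorrected - truth)) closer <- closer + 1L
  }
  expect_gte(closer / reps, 0.8)
})

test_that("loci without nulls keep their uncorrected components", {
  sim <- simulate_genotypes(sim_config(
    K = 2, N = 60, m = 0.02, generations = 80, sample_n = 25, L = 4,
    null_spec = c(0.3, 0, 0, 0), seed = 42))
  ds <- sim$dataset
  nt <- null_allele_table(ds)
  # force the decision rule: mark clean loci as exactly zero
  nt$r_hat[nt$locus != "L01"] <- 0
  en <- ena_corrected_fst(ds, null_table = nt)
  un <- wc_fstats(ds)
  for (l in c("L02", "L03", "L04"))
    expect_equal(en$theta_by_locus_corrected[[l]],
                 un$theta_by_locus[[l]])
})

test_that("the F_IS / null-frequency regression behaves on edge cases", {
  pts <- data.frame(r_hat = c(0.1, 0.2, 0.3, 0.4),
                    fis = c(0.2, 0.4, 0.6, 0.8))
  fit <- fis_null_regression(pts)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  flat <- data.frame(r_hat = rep(0, 5), fis = runif(5))
  expect_true(is.na(fis_null_regression(flat)$slope))
  expect_error(fis_null_regression(pts[1:2, ]), "at least 3")
})

test_that("the heterogeneity screen separates inbreeding from artifacts", {
  fis_all <- stats::setNames(rep(0.3, 6), paste0("L", 1:6))
  r_zero <- stats::setNames(rep(0, 6), paste0("L", 1:6))
  expect_equal(fis_heterogeneity_screen(fis_all, r_zero),
               "inbreeding-like")
  fis_mix <- stats::setNames(c(0.5, 0.4, -0.02, 0, -0.05, 0.01),
                             paste0("L", 1:6))
  r_mix <- stats::setNames(c(0.25, 0.3, 0, 0, 0.01, 0), paste0("L", 1:6))
  expect_equal(fis_heterogeneity_screen(fis_mix, r_mix),
               "null-artifact-like")
  expect_equal(fis_heterogeneity_screen(fis_all[1:2], r_zero[1:2]),
               "inconclusive")
  # truth-labelled simulations
  lab <- function(cfg) {
    sim <- simulate_genotypes(cfg)
    pts <- fis_null_points(sim$dataset)
    p1 <- pts[pts$population == "POP01", ]
    fis_heterogeneity_screen(stats::setNames(p1$fis, p1$locus),
                             stats::setNames(p1$r_hat, p1$locus))
  }
  self_hits <- sum(vapply(1:10, function(b) lab(sim_config(
    K = 1, N = 100, s = 0.5, mu = 1e-3, generations = 60, sample_n = 30,
    L = 13, seed = 900 + b)) == "inbreeding-like", logical(1)))
  null_hits <- sum(vapply(1:10, function(b) lab(sim_config(
    K = 1, N = 100, s = 0, mu = 1e-3, generations = 60, sample_n = 30,
    L = 13, null_spec = c(rep(0.25, 4), rep(0, 9)),
    seed = 950 + b)) == "null-artifact-like", logical(1)))
  expect_gte(self_hits, 9L)
  expect_gte(null_hits, 9L)
})
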