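# Builders for small datasets used across the suite.

# dataset from an explicit list of genotype rows:
# pops: character vector; geno: list of individuals, each a list of
# c(a1, a2) per locus (NA, NA for missing)
make_ds <- function(geno, pops, loci = NULL,
                    species = rep("sp1", length(pops))) {
  n <- length(geno)
  L <- length(geno[[1]])
  a1 <- t(vapply(geno, function(g) vapply(g, `[`, numeric(1), 1), numeric(L)))
  a2 <- t(vapply(geno, function(g) vapply(g, `[`, numeric(1), 2), numeric(L)))
  if (L == 1L) { a1 <- matrix(a1, ncol = 1); a2 <- matrix(a2, ncol = 1) }
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  genotype_dataset(a1, a2, paste0("ind", seq_len(n)), pops, species, loci)
}

# random valid dataset for round-trip / property tests
random_ds <- function(seed, n_pop = 2, n_per = 4, L = 3, miss_rate = 0.1) {
  set.seed(seed)
  n <- n_pop * n_per
  sizes <- seq(100, 140, by = 2)
  a1 <- matrix(sample(sizes, n * L, TRUE), n, L)
  a2 <- matrix(sample(sizes, n * L, TRUE), n, L)
  miss <- matrix(runif(n * L) < miss_rate, n, L)
  a1[miss] <- NA; a2[miss] <- NA
  genotype_dataset(a1, a2, paste0("i", seq_len(n)),
                   rep(paste0("P", seq_len(n_pop)), each = n_per),
                   rep("sp1", n), paste0("L", seq_len(L)))
}

# genotype count matrix directly from vectors of allele pairs
counts_from_pairs <- function(a, b) {
  ds <- make_ds(Map(function(x, y) list(c(x, y)), a, b),
                rep("P", length(a)))
  genotype_counts(ds, "P", "L1")
}

# independent transcription of the Weir-Cockerham component formulas for a
# single locus, loop-based, used as the algebraic oracle
wc_oracle_theta <- function(n_i, p_mat, h_mat) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  A <- ncol(p_mat)
  a_sum <- b_sum <- c_sum <- 0
  for (al in seq_len(A)) {
    p <- p_mat[, al]; hh <- h_mat[, al]
    pbar <- sum(n_i * p) / (r * nbar)
    s2 <- sum(n_i * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * hh) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_sum <- a_sum + a; b_sum <- b_sum + b; c_sum <- c_sum + cc
  }
  a_sum / (a_sum + b_sum + c_sum)
}

# random additive (tree) distance matrix on k taxa, built from a random
# unrooted topology with strictly positive branch lengths
random_additive <- function(seed, k) {
  set.seed(seed)
  tr <- ape::rtree(k, rooted = FALSE,
                   br = function(n) runif(n, 0.2, 1.5))
  tr$tip.label <- sprintf("T%02d", seq_len(k))
  d <- cophenetic(tr)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tr, d = d)
}
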