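# Weir & Cockerham variance components.
#
# wc_abc() is the algebraic core shared by every theta/f estimator in the
# package (multilocus theta, pairwise theta, the single-population f, and
# the ENA-corrected theta): given per-population sample sizes, allele
# frequencies and heterozygote proportions at ONE locus it returns the
# among-population (a), among-individual (b) and within-individual (c)
# components, one value per allele.

wc_abc <- function(nvec, pmat, hmat) {
  r <- length(nvec)
  nbar <- mean(nvec)
  if (nbar <= 1) return(NULL)
  pbar <- colSums(nvec * pmat) / (r * nbar)
  hbar <- colSums(nvec * hmat) / (r * nbar)
  if (r >= 2) {
    nc <- (r * nbar - sum(nvec^2) / (r * nbar)) / (r - 1)
    s2 <- colSums(nvec * sweep(pmat, 2, pbar)^2) / ((r - 1) * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  } else {
    a <- rep(0, ncol(pmat))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (2 * nbar - 1) / (4 * nbar) * hbar)
  }
  c_ <- hbar / 2
  list(a = a, b = b, c = c_)
}

# Per-population allele frequencies and heterozygote proportions at one
# locus, restricted to populations with >= 2 typed individuals (the
# estimator needs nbar > 1). Returns NULL when fewer than `min_pops`
# populations qualify or the locus is monomorphic across them.
locus_wc_input <- function(ds, pops, locus_j, min_pops = 1L,
                           require_polymorphic = TRUE) {
  nvec <- integer(0); rows_list <- list()
  for (p in pops) {
    rows <- which(ds$population == p)
    typed <- rows[!is.na(ds$a1[rows, locus_j])]
    if (length(typed) >= 2L) {
      nvec <- c(nvec, length(typed))
      rows_list[[length(rows_list) + 1L]] <- typed
    }
  }
  if (length(nvec) < min_pops) return(NULL)
  alleles <- sort(unique(c(
    unlist(lapply(rows_list, function(rw) ds$a1[rw, locus_j])),
    unlist(lapply(rows_list, function(rw) ds$a2[rw, locus_j])))))
  if (require_polymorphic && length(alleles) < 2L) return(NULL)
  r <- length(nvec); A <- length(alleles)
  pmat <- matrix(0, r, A); hmat <- matrix(0, r, A)
  for (i in seq_len(r)) {
    rw <- rows_list[[i]]
    g1 <- ds$a1[rw, locus_j]; g2 <- ds$a2[rw, locus_j]
    cnt <- tabulate(match(c(g1, g2), alleles), nbins = A)
    pmat[i, ] <- cnt / (2 * nvec[i])
    het <- g1 != g2
    for (aa in seq_len(A)) {
      al <- alleles[aa]
      hmat[i, aa] <- sum(het & (g1 == al | g2 == al)) / nvec[i]
    }
  }
  list(nvec = nvec, pmat = pmat, hmat = hmat, alleles = alleles)
}

#' Weir-Cockerham F-statistics
#'
#' Multilocus variance-components estimators: theta (F_ST analogue), f
#' (F_IS analogue) and F_IT, obtained by summing the among-population,
#' among-individual and within-individual components over all alleles and
#' loci (the "ratio of sums" estimator). Populations contribute to a locus
#' only when at least two individuals are typed there; monomorphic loci
#' carry no information and are skipped.
#'
#' @param ds a [genotype_dataset()].
#' @param pops populations to include (default all).
#' @param loci locus names to include (default all).
#' @return list with `theta`, `f`, `Fit`, per-locus `theta_by_locus`, and
#'   the summed components `a`, `b`, `c`.
#' @references Weir BS, Cockerham CC (1984) Estimating F-statistics for the
#'   analysis of population structure. Evolution 38:1358-1370.
#' @export
wc_fstats <- function(ds, pops = unique(ds$population), loci = ds$loci) {
  sa <- sb <- sc <- 0        # theta sums: loci with >= 2 populations
  fb <- fc <- 0              # f sums: every polymorphic locus
  multi <- FALSE
  theta_l <- stats::setNames(rep(NA_real_, length(loci)), loci)
  for (l in loci) {
    j <- match(l, ds$loci)
    inp <- locus_wc_input(ds, pops, j, min_pops = 1L)
    if (is.null(inp)) next
    comp <- wc_abc(inp$nvec, inp$pmat, inp$hmat)
    if (is.null(comp)) next
    fb <- fb + sum(comp$b); fc <- fc + sum(comp$c)
    if (length(inp$nvec) >= 2L) {
      multi <- TRUE
      al <- sum(comp$a); bl <- sum(comp$b); cl <- sum(comp$c)
      if (al + bl + cl > 0) theta_l[l] <- al / (al + bl + cl)
      sa <- sa + al; sb <- sb + bl; sc <- sc + cl
    }
  }
  tot <- sa + sb + sc
  list(theta = if (multi && tot > 0) sa / tot else NA_real_,
       f = if (fb + fc > 0) 1 - fc / (fb + fc) else NA_real_,
       Fit = if (multi && tot > 0) 1 - sc / tot else NA_real_,
       theta_by_locus = theta_l, a = sa, b = sb, c = sc)
}

#' Pairwise Weir-Cockerham theta with permutation significance
#'
#' Computes multilocus theta for every pair of populations and, optionally,
#' a permutation p-value obtained by reallocating whole multilocus genotypes
#' among the two populations (sample sizes held fixed) and recomputing
#' theta. The p-value follows the add-one rule
#' `p = (1 + #permuted >= observed) / (1 + n_perm)`.
#'
#' @param ds a [genotype_dataset()].
#' @param pops populations (default all in `ds`).
#' @param n_perm permutations per pair; 0 skips the test.
#' @param seed integer RNG seed.
#' @return list of class `"pairwise_stat"` with `pops`, symmetric matrices
#'   `value` (diagonal `NA`) and `p_value`, and `statistic = "theta"`.
#' @export
pairwise_fst <- function(ds, pops = unique(ds$population), n_perm = 0L,
                         seed = 1L) {
  k <- length(pops)
  if (k < 2L) stop("need at least two populations")
  v <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pv <- if (n_perm > 0L) v else NULL
  set.seed(seed)
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    rows <- which(ds$population %in% c(pops[i], pops[j]))
    sub <- subset_individuals(ds, rows)
    obs <- wc_fstats(sub)$theta
    v[i, j] <- v[j, i] <- obs
    if (n_perm > 0L && is.finite(obs)) {
      hits <- 0L
      labs <- sub$population
      for (b in seq_len(n_perm)) {
        perm <- sub
        perm$population <- sample(labs)
        th <- wc_fstats(perm)$theta
        if (is.finite(th) && th >= obs) hits <- hits + 1L
      }
      pv[i, j] <- pv[j, i] <- (1 + hits) / (1 + n_perm)
    }
  }
  structure(list(pops = pops, value = v, p_value = pv, statistic = "theta"),
            class = "pairwise_stat")
}

#' @export
print.pairwise_stat <- function(x, digits = 3, ...) {
  cat("pairwise", x$statistic, "over", length(x$pops), "populations\n")
  print(round(x$value, digits))
  invisible(x)
}
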