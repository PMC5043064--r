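#' Observed number of alleles per locus
#'
#' @param ft an [allele_freqs()] table.
#' @param population population code.
#' @return list with `by_locus` (named vector; `NA` where no individual is
#'   typed) and `mean` over typed loci (`NA` if none).
#' @export
observed_alleles <- function(ft, population) {
  entry <- ft[[population]]
  if (is.null(entry)) stop("unknown population: ", population)
  by_locus <- vapply(entry, function(e)
    if (e$gene_count > 0L) length(e$freq) else NA_real_, numeric(1))
  list(by_locus = by_locus,
       mean = if (all(is.na(by_locus))) NA_real_ else
         mean(by_locus, na.rm = TRUE))
}

#' Rarefied allelic richness at one locus
#'
#' Expected number of distinct alleles in a random draw of `2g` gene copies
#' without replacement from the sampled copies (hypergeometric rarefaction):
#' `A_R = sum_i [1 - choose(N - n_i, 2g) / choose(N, 2g)]` where `n_i` are
#' the allele gene counts and `N` their total. Undefined (`NA`) when fewer
#' than `2g` copies were sampled.
#'
#' @param counts integer vector of allele gene counts at the locus.
#' @param g standardised number of diploid individuals (so `2g` gene
#'   copies are drawn); default 10.
#' @return `A_R`, or `NA` when `sum(counts) < 2g`.
#' @references Petit RJ, El Mousadik A, Pons O (1998) Identifying
#'   populations for conservation on the basis of genetic markers.
#'   Conserv Biol 12:844-855.
#' @export
rarefied_allelic_richness <- function(counts, g = 10L) {
  if (any(counts < 0)) stop("negative allele counts")
  counts <- counts[counts > 0]
  if (g < 2L) stop("rarefaction size g must be >= 2")
  N <- sum(counts); k <- 2L * g
  if (N < k) return(NA_real_)
  # log-scale hypergeometric tail: P(allele i absent from the draw)
  p_absent <- exp(lchoose(N - counts, k) - lchoose(N, k))
  p_absent[N - counts < k] <- 0
  sum(1 - p_absent)
}

#' Effective number of alleles at one locus
#'
#' `A_E = 1 / sum(p^2)`: the allele count of a hypothetical locus with
#' equally frequent alleles and the same expected homozygosity.
#'
#' @param freqs numeric vector of allele frequencies (sums to 1).
#' @return `A_E`, or `NA` for an empty frequency vector.
#' @export
effective_alleles <- function(freqs) {
  if (length(freqs) == 0L) return(NA_real_)
  1 / sum(freqs^2)
}

#' Observed and expected heterozygosity within one population
#'
#' Per locus: `H_O` is the fraction of typed individuals that are
#' heterozygous; `H_E` is reported in two variants, the plug-in gene
#' diversity `1 - sum(p^2)` and Nei's small-sample unbiased estimator
#' `2n/(2n - 1) * (1 - sum(p^2))` with `n` typed individuals. Loci with no
#' typed individuals are skipped from the means; standard errors are over
#' loci.
#'
#' @param ds a [genotype_dataset()].
#' @param population population code.
#' @return list with per-locus vectors `H_O`, `H_E` (unbiased),
#'   `H_E_plugin`, `typed_n`, and `mean_H_O`, `mean_H_E`,
#'   `mean_H_E_plugin`, `se_H_O`, `se_H_E`.
#' @export
heterozygosities <- function(ds, population) {
  rows <- which(ds$population == population)
  if (length(rows) == 0L) stop("unknown population: ", population)
  L <- length(ds$loci)
  H_O <- H_E <- H_Ep <- rep(NA_real_, L)
  typed_n <- integer(L)
  for (j in seq_len(L)) {
    g1 <- ds$a1[rows, j]; g2 <- ds$a2[rows, j]
    ok <- !is.na(g1)
    n <- sum(ok); typed_n[j] <- n
    if (n == 0L) next
    H_O[j] <- mean(g1[ok] != g2[ok])
    p <- as.numeric(table(c(g1[ok], g2[ok]))) / (2 * n)
    H_Ep[j] <- 1 - sum(p^2)
    H_E[j] <- if (2 * n > 1) (2 * n) / (2 * n - 1) * H_Ep[j] else H_Ep[j]
  }
  names(H_O) <- names(H_E) <- names(H_Ep) <- names(typed_n) <- ds$loci
  se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  list(H_O = H_O, H_E = H_E, H_E_plugin = H_Ep, typed_n = typed_n,
       mean_H_O = mean(H_O, na.rm = TRUE), mean_H_E = mean(H_E, na.rm = TRUE),
       mean_H_E_plugin = mean(H_Ep, na.rm = TRUE),
       se_H_O = se(H_O), se_H_E = se(H_E))
}

#' Multilocus inbreeding coefficient within one population
#'
#' Two estimators are exposed. `"weir_cockerham"` (default) is the
#' small-sample variance-components f: `1 - sum(c) / sum(b + c)` with the
#' within/among-individual components summed over alleles and polymorphic
#' loci. `"nei"` is the ratio of multilocus means,
#' `1 - mean(H_O) / mean(H_E)` with the unbiased `H_E`.
#'
#' @param ds a [genotype_dataset()].
#' @param population population code.
#' @param estimator `"weir_cockerham"` or `"nei"`.
#' @return F_IS, or `NA` when all loci are monomorphic.
#' @export
f_is <- function(ds, population, estimator = c("weir_cockerham", "nei")) {
  estimator <- match.arg(estimator)
  if (estimator == "nei") {
    h <- heterozygosities(ds, population)
    if (!is.finite(h$mean_H_E) || h$mean_H_E <= 0) return(NA_real_)
    return(1 - h$mean_H_O / h$mean_H_E)
  }
  sb <- sc <- 0
  for (j in seq_along(ds$loci)) {
    inp <- locus_wc_input(ds, population, j, min_pops = 1L)
    if (is.null(inp)) next
    comp <- wc_abc(inp$nvec, inp$pmat, inp$hmat)
    if (is.null(comp)) next
    sb <- sb + sum(comp$b); sc <- sc + sum(comp$c)
  }
  if (sb + sc <= 0) return(NA_real_)
  1 - sc / (sb + sc)
}

#' Multilocus outcrossing rate from F_IS
#'
#' At inbreeding equilibrium the outcrossing proportion satisfies
#' `t = (1 - F_IS) / (1 + F_IS)`; estimates exceed 1 when F_IS is negative
#' (heterozygote excess relative to random mating).
#'
#' @param fis inbreeding coefficient, must be > -1.
#' @return t (dimensionless proportion; may exceed 1). `NA` input gives
#'   `NA`.
#' @export
outcrossing_rate <- function(fis) {
  out <- rep(NA_real_, length(fis))
  ok <- !is.na(fis)
  if (any(fis[ok] <= -1)) stop("outcrossing rate undefined for F_IS <= -1")
  out[ok] <- (1 - fis[ok]) / (1 + fis[ok])
  out
}

#' Per-population diversity table
#'
#' One row per population: sample size N, mean observed alleles per locus
#' (A), rarefied allelic richness at `g` diploids (A_R, `NA` when any typed
#' locus has fewer than `2g` gene copies), mean effective alleles (A_E),
#' observed and unbiased expected heterozygosity with standard errors over
#' loci, multilocus F_IS and the derived outcrossing rate t.
#'
#' @param ds a [genotype_dataset()].
#' @param g rarefaction standard size (diploid individuals); default 10.
#' @param fis_estimator passed to [f_is()].
#' @return data.frame of class `"pop_diversity"`.
#' @export
pop_diversity <- function(ds, g = 10L,
                          fis_estimator = c("weir_cockerham", "nei")) {
  fis_estimator <- match.arg(fis_estimator)
  ft <- allele_freqs(ds)
  pops <- unique(ds$population)
  rows <- lapply(pops, function(p) {
    entry <- ft[[p]]
    N <- sum(ds$population == p)
    A <- observed_alleles(ft, p)$mean
    ar_l <- vapply(entry, function(e) {
      if (e$gene_count == 0L) return(NA_real_)
      rarefied_allelic_richness(round(e$freq * e$gene_count), g)
    }, numeric(1))
    typed <- vapply(entry, function(e) e$gene_count > 0L, logical(1))
    A_R <- if (any(typed) && !anyNA(ar_l[typed])) mean(ar_l[typed])
           else NA_real_
    ae_l <- vapply(entry, function(e) effective_alleles(e$freq), numeric(1))
    A_E <- if (all(is.na(ae_l))) NA_real_ else mean(ae_l, na.rm = TRUE)
    h <- heterozygosities(ds, p)
    fis <- f_is(ds, p, fis_estimator)
    data.frame(population = p, species = ds$species[ds$population == p][1L],
               N = N, A = A, A_R = A_R, A_E = A_E,
               H_O = h$mean_H_O, H_O_se = h$se_H_O,
               H_E = h$mean_H_E, H_E_se = h$se_H_E,
               F_IS = fis, t = outcrossing_rate(fis),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pop_diversity", "data.frame")
  out
}

#' Species-level diversity summary
#'
#' Pools all populations of one species: `A` and `A_E` are per-locus means
#' on the pooled sample; `H_O` is the mean over populations of the
#' population means; `H_S` is the mean over populations of the unbiased
#' within-population gene diversity (per-locus means first, then over
#' loci); `H_T` is the gene diversity of the unweighted mean allele
#' frequencies across populations. The Nei decomposition F_ST
#' `(H_T - H_S) / H_T` uses the plug-in `H_S`/`H_T` pair, which keeps
#' `H_S <= H_T` for any input; the multilocus Weir-Cockerham theta is
#' reported alongside.
#'
#' @param ds a [genotype_dataset()].
#' @param species species label.
#' @return list with `N_ind`, `N_pop`, `A`, `A_E`, `H_O`, `H_S`, `H_T`,
#'   `F_IS` (Weir-Cockerham f over the species' populations), `F_ST_nei`,
#'   `F_ST_wc`, and standard errors over loci for A, A_E, H_O, H_S, H_T.
#' @export
species_summary <- function(ds, species) {
  rows <- which(ds$species == species)
  if (length(rows) == 0L) stop("unknown species: ", species)
  sub <- subset_individuals(ds, rows)
  pops <- unique(sub$population)
  if (length(pops) < 2L)
    stop("species-level summary needs at least two populations")
  ft <- allele_freqs(sub)

  # pooled per-locus A and A_E
  pooled <- allele_freqs(genotype_dataset(
    sub$a1, sub$a2, sub$individuals, rep("pooled", length(rows)),
    sub$species, sub$loci))[["pooled"]]
  A_l <- vapply(pooled, function(e)
    if (e$gene_count > 0L) length(e$freq) else NA_real_, numeric(1))
  AE_l <- vapply(pooled, function(e) effective_alleles(e$freq), numeric(1))

  het <- lapply(pops, function(p) heterozygosities(sub, p))
  HO_l <- rowMeans(do.call(cbind, lapply(het, `[[`, "H_O")), na.rm = TRUE)
  HS_l <- rowMeans(do.call(cbind, lapply(het, `[[`, "H_E")), na.rm = TRUE)
  HSp_l <- rowMeans(do.call(cbind, lapply(het, `[[`, "H_E_plugin")),
                    na.rm = TRUE)
  pbar <- mean_freqs_across_pops(ft, pops)
  HT_l <- vapply(pbar, function(p)
    if (length(p) == 0L) NA_real_ else 1 - sum(p^2), numeric(1))

  fst_nei_l <- ifelse(HT_l > 0, (HT_l - HSp_l) / HT_l, NA_real_)
  wc <- wc_fstats(sub, pops)
  se <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  list(species = species, N_ind = length(rows), N_pop = length(pops),
       A = mean(A_l, na.rm = TRUE), A_se = se(A_l),
       A_E = mean(AE_l, na.rm = TRUE), A_E_se = se(AE_l),
       H_O = mean(HO_l, na.rm = TRUE), H_O_se = se(HO_l),
       H_S = mean(HS_l, na.rm = TRUE), H_S_se = se(HS_l),
       H_S_plugin = mean(HSp_l, na.rm = TRUE),
       H_T = mean(HT_l, na.rm = TRUE), H_T_se = se(HT_l),
       F_IS = wc$f,
       F_ST_nei = {
         num <- sum(HT_l - HSp_l, na.rm = TRUE)
         den <- sum(HT_l, na.rm = TRUE)
         if (den > 0) num / den else NA_real_
       },
       F_ST_nei_by_locus = fst_nei_l,
       F_ST_wc = wc$theta)
}

#' Private alleles per population within a species
#'
#' An allele is private to a population when it segregates there and is
#' absent from every conspecific population.
#'
#' @param ft an [allele_freqs()] table (built on one species' data).
#' @param pops populations forming the comparison set (default: all in
#'   `ft`).
#' @return data.frame with one row per (population, locus, allele) private
#'   record: `population`, `locus`, `allele`, `freq`; zero rows when there
#'   are none.
#' @export
private_alleles <- function(ft, pops = attr(ft, "pops")) {
  if (length(pops) < 2L) stop("need at least two populations")
  loci <- attr(ft, "loci")
  recs <- list()
  for (l in loci) {
    present <- lapply(pops, function(p) names(ft[[p]][[l]]$freq))
    names(present) <- pops
    all_alleles <- unlist(present)
    counts <- table(all_alleles)
    priv <- names(counts)[counts == 1L]
    for (p in pops) {
      mine <- intersect(present[[p]], priv)
      for (al in mine)
        recs[[length(recs) + 1L]] <- data.frame(
          population = p, locus = l, allele = as.integer(al),
          freq = unname(ft[[p]][[l]]$freq[al]), stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0L)
    return(data.frame(population = character(0), locus = character(0),
                      allele = integer(0), freq = numeric(0)))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
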