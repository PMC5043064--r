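#' Markov chain parameters for exact HWE testing
#'
#' Defaults are 10,000 dememorization steps and 1,000 batches of 10,000
#' iterations each; the batch means of the indicator give the p-value and
#' its Monte-Carlo standard error.
#'
#' @param dememorization burn-in switches before sampling.
#' @param batches number of batches.
#' @param iterations_per_batch chain steps per batch.
#' @param seed integer RNG seed.
#' @return list of class `"mc_params"`.
#' @export
mc_params <- function(dememorization = 10000L, batches = 1000L,
                      iterations_per_batch = 10000L, seed = 1L) {
  stopifnot(dememorization > 0, batches > 0, iterations_per_batch > 0)
  structure(list(dememorization = as.integer(dememorization),
                 batches = as.integer(batches),
                 iterations_per_batch = as.integer(iterations_per_batch),
                 seed = as.integer(seed)),
            class = "mc_params")
}

#' Genotype count matrix at one population x locus
#'
#' @param ds a [genotype_dataset()].
#' @param population population code.
#' @param locus locus name.
#' @return k x k lower-triangular integer matrix of genotype counts
#'   (`counts[i, j]`, `i >= j`), with allele sizes as dimnames; `NULL`
#'   when no individual is typed.
#' @export
genotype_counts <- function(ds, population, locus) {
  rows <- which(ds$population == population)
  j <- match(locus, ds$loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  g1 <- ds$a1[rows, j]; g2 <- ds$a2[rows, j]
  ok <- !is.na(g1)
  if (!any(ok)) return(NULL)
  alleles <- sort(unique(c(g1[ok], g2[ok])))
  k <- length(alleles)
  m <- matrix(0L, k, k, dimnames = list(alleles, alleles))
  i1 <- match(g2[ok], alleles)  # a2 >= a1, so a2 indexes the row
  i2 <- match(g1[ok], alleles)
  for (t in seq_along(i1)) m[i1[t], i2[t]] <- m[i1[t], i2[t]] + 1L
  m
}

# Levene log-probability of a genotype table (full constant included).
levene_logprob <- function(counts) {
  k <- nrow(counts)
  cells <- counts[lower.tri(counts, diag = TRUE)]
  m <- integer(k)
  for (i in seq_len(k)) for (j in seq_len(i)) {
    m[i] <- m[i] + counts[i, j]
    m[j] <- m[j] + counts[i, j]
  }
  n <- sum(cells)
  h <- sum(counts) - sum(diag(counts))
  lgamma(n + 1) + sum(lgamma(m + 1)) + h * log(2) -
    lgamma(2 * n + 1) - sum(lgamma(cells + 1))
}

# Enumerate all genotype tables conditional on allele gene counts `m`.
# Returns NULL when more than `cap` tables exist. Each table is summarised
# by its Levene log-probability and heterozygote count.
enumerate_tables <- function(m, cap = 1e5) {
  k <- length(m)
  n <- sum(m) / 2
  pairs <- if (k >= 2) utils::combn(k, 2) else matrix(integer(0), 2, 0)
  np <- ncol(pairs)
  logp <- numeric(0); hets <- integer(0)
  count <- 0L; bail <- FALSE
  lg2 <- log(2)
  const <- lgamma(n + 1) + sum(lgamma(m + 1)) - lgamma(2 * n + 1)
  het <- integer(np)
  rec <- function(q, used) {
    if (bail) return()
    if (q > np) {
      rem <- m - used
      if (any(rem %% 2L != 0L)) return()
      hom <- rem %/% 2L
      h <- sum(het)
      lp <- const + h * lg2 - sum(lgamma(het + 1)) - sum(lgamma(hom + 1))
      count <<- count + 1L
      if (count > cap) { bail <<- TRUE; return() }
      logp[count] <<- lp
      hets[count] <<- h
      return()
    }
    i <- pairs[1L, q]; j <- pairs[2L, q]
    hi <- min(m[i] - used[i], m[j] - used[j])
    if (hi < 0L) return()
    for (v in 0:hi) {
      het[q] <<- v
      u <- used; u[i] <- u[i] + v; u[j] <- u[j] + v
      rec(q + 1L, u)
      if (bail) return()
    }
  }
  rec(1L, integer(k))
  if (bail) return(NULL)
  list(logp = logp[seq_len(count)], het = hets[seq_len(count)])
}

#' Exact Hardy-Weinberg test at one locus
#'
#' Probability-based exact test conditional on the allele counts (Levene
#' distribution). When the conditional table space has at most `enum_cap`
#' tables the p-value is computed by complete enumeration; otherwise a
#' Guo-Thompson Markov chain of genotype switches is run with `params`.
#' `direction = "two_sided"` orders tables by conditional probability
#' (smaller or equal to the observed is "as or more extreme");
#' `"deficiency"` is the one-sided ordering by heterozygote count (fewer
#' heterozygotes than observed).
#'
#' @param counts genotype count matrix from [genotype_counts()].
#' @param params an [mc_params()] object.
#' @param direction `"two_sided"` or `"deficiency"`.
#' @param enum_cap maximum table count for complete enumeration.
#' @return list of class `"hwe_result"`: `p_value`, `se_p` (0 for
#'   enumeration), `method`, `direction`, `n_typed`, `n_alleles`.
#'   Monomorphic input returns `p_value = NA` with method `"undefined"`.
#' @references Guo SW, Thompson EA (1992) Performing the exact test of
#'   Hardy-Weinberg proportion for multiple alleles. Biometrics 48:361-372.
#' @export
hwe_exact <- function(counts, params = mc_params(),
                      direction = c("two_sided", "deficiency"),
                      enum_cap = 1e5) {
  direction <- match.arg(direction)
  if (is.null(counts) || nrow(counts) < 2L)
    return(structure(list(p_value = NA_real_, se_p = NA_real_,
                          method = "undefined", direction = direction,
                          n_typed = if (is.null(counts)) 0L else sum(counts),
                          n_alleles = if (is.null(counts)) 0L else 1L),
                     class = "hwe_result"))
  k <- nrow(counts)
  m <- integer(k)
  for (i in seq_len(k)) for (j in seq_len(i)) {
    m[i] <- m[i] + counts[i, j]; m[j] <- m[j] + counts[i, j]
  }
  obs_lp <- levene_logprob(counts)
  obs_h <- sum(counts) - sum(diag(counts))
  enum <- enumerate_tables(m, cap = enum_cap)
  if (!is.null(enum)) {
    pr <- exp(enum$logp)
    pr <- pr / sum(pr)  # guard against rounding; sums to 1 analytically
    p <- if (direction == "two_sided")
      sum(pr[enum$logp <= obs_lp + 1e-9]) else sum(pr[enum$het <= obs_h])
    return(structure(list(p_value = p, se_p = 0,
                          method = "exact_enumeration",
                          direction = direction, n_typed = sum(counts),
                          n_alleles = k),
                     class = "hwe_result"))
  }
  set.seed(params$seed)
  res <- .gt_chain(counts, params$dememorization, params$batches,
                   params$iterations_per_batch)
  bp <- if (direction == "two_sided") res$batch_prob else res$batch_def
  structure(list(p_value = mean(bp),
                 se_p = stats::sd(bp) / sqrt(length(bp)),
                 method = "markov_chain", direction = direction,
                 n_typed = sum(counts), n_alleles = k),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE %s test (%s): p = %s%s\n", x$direction, x$method,
              format(x$p_value, digits = 4),
              if (x$method == "markov_chain")
                sprintf(" (MC se %.2g)", x$se_p) else ""))
  invisible(x)
}

#' Global heterozygote-deficiency test for one population
#'
#' Multilocus one-sided test: per-locus Guo-Thompson chains are advanced in
#' lock step and the summed heterozygote count across polymorphic loci is
#' compared with its conditional null distribution (fewer heterozygotes
#' than observed is extreme). With a single polymorphic locus this equals
#' the per-locus deficiency test.
#'
#' @param ds a [genotype_dataset()].
#' @param population population code.
#' @param params an [mc_params()] object.
#' @return an `"hwe_result"` with `method = "markov_chain"`; `NA` p-value
#'   when no polymorphic locus exists.
#' @export
global_heterozygote_deficiency <- function(ds, population,
                                           params = mc_params()) {
  counts <- lapply(ds$loci, function(l) genotype_counts(ds, population, l))
  counts <- Filter(function(m) !is.null(m) && nrow(m) >= 2L, counts)
  if (length(counts) == 0L)
    return(structure(list(p_value = NA_real_, se_p = NA_real_,
                          method = "undefined", direction = "deficiency",
                          n_typed = 0L, n_alleles = 0L),
                     class = "hwe_result"))
  set.seed(params$seed)
  res <- .gt_chain_global(counts, params$dememorization, params$batches,
                          params$iterations_per_batch)
  bp <- res$batch_def
  structure(list(p_value = mean(bp),
                 se_p = stats::sd(bp) / sqrt(length(bp)),
                 method = "markov_chain", direction = "deficiency",
                 n_typed = sum(vapply(counts, sum, numeric(1))),
                 n_alleles = NA_integer_, n_loci = length(counts)),
            class = "hwe_result")
}

#' Sequential Bonferroni (Holm) correction
#'
#' Step-down Holm adjustment (via [stats::p.adjust()]) with rejection flags
#' at level `alpha`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   preserved).
#' @param alpha family-wise error level.
#' @return list with `adjusted` (monotone in rank order) and `reject`
#'   (logical).
#' @export
holm_correction <- function(p, alpha = 0.05) {
  if (length(p) == 0L) return(list(adjusted = numeric(0),
                                   reject = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  adj[ok] <- stats::p.adjust(p[ok], method = "holm")
  list(adjusted = adj, reject = !is.na(adj) & adj < alpha)
}

#' HWE tests over all population x locus combinations
#'
#' Runs [hwe_exact()] for every combination with at least two alleles and
#' appends Holm-adjusted p-values across the whole family of performed
#' tests.
#'
#' @param ds a [genotype_dataset()].
#' @param params an [mc_params()] object; each test derives its own seed
#'   from `params$seed` so results do not depend on traversal order.
#' @param direction test direction, see [hwe_exact()].
#' @param enum_cap see [hwe_exact()].
#' @param alpha level for the Holm rejection flags.
#' @return data.frame with one row per combination: population, locus,
#'   n_alleles, method, p_value, se_p, p_holm, significant.
#' @export
hwe_table <- function(ds, params = mc_params(),
                      direction = c("two_sided", "deficiency"),
                      enum_cap = 1e5, alpha = 0.05) {
  direction <- match.arg(direction)
  pops <- unique(ds$population)
  rows <- list()
  idx <- 0L
  for (p in pops) for (l in ds$loci) {
    idx <- idx + 1L
    cnt <- genotype_counts(ds, p, l)
    par_i <- params; par_i$seed <- params$seed + idx
    res <- hwe_exact(cnt, par_i, direction, enum_cap)
    rows[[idx]] <- data.frame(population = p, locus = l,
                              n_alleles = res$n_alleles,
                              method = res$method, p_value = res$p_value,
                              se_p = res$se_p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  hc <- holm_correction(out$p_value, alpha)
  out$p_holm <- hc$adjusted
  out$significant <- hc$reject
  rownames(out) <- NULL
  out
}
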