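#' EM estimate of the null-allele frequency at one population x locus
#'
#' Maximum-likelihood estimation under the classic one-null-allele model:
#' visible/null heterozygotes are scored as visible homozygotes and
#' null/null homozygotes come out blank. The E-step allocates apparent
#' homozygotes between true homozygote and visible/null classes and the
#' M-step re-estimates all allele frequencies including the null frequency
#' r (Dempster-style EM, as used for genotyping-failure correction of
#' microsatellite data).
#'
#' @param counts apparent genotype count matrix (lower triangular, as from
#'   [genotype_counts()]); may be `NULL` when only blanks were observed.
#' @param n_blank number of all-missing individuals at this locus.
#' @param failure_mix proportion of blanks attributed to technical failure
#'   rather than null homozygosity; default 0 (all blanks are null/null).
#' @param tol convergence tolerance on successive iterates of r and the
#'   visible frequencies.
#' @param max_iter iteration cap.
#' @return list of class `"null_estimate"`: `r_hat`, `p` (visible allele
#'   frequencies, named; sums to `1 - r_hat`), `iterations`, `converged`,
#'   `loglik` (trace, non-decreasing).
#' @references Dempster AP, Laird NM, Rubin DB (1977) Maximum likelihood
#'   from incomplete data via the EM algorithm. JRSS B 39:1-38.
#' @export
em_null_frequency <- function(counts, n_blank = 0L, failure_mix = 0,
                              tol = 1e-6, max_iter = 2000L) {
  n0 <- (1 - failure_mix) * n_blank
  if (is.null(counts) || sum(counts) == 0L) {
    # only blanks: r is 1 when any are attributed to nulls
    r <- if (n0 > 0) 1 else NA_real_
    return(structure(list(r_hat = r, p = numeric(0), iterations = 0L,
                          converged = TRUE, loglik = numeric(0)),
                     class = "null_estimate"))
  }
  k <- nrow(counts)
  alleles <- rownames(counts)
  hom <- diag(counts)
  het_a <- integer(k)  # heterozygote gene-copy count per visible allele
  n_het <- 0L
  for (i in seq_len(k)) for (j in seq_len(i)) if (i != j) {
    het_a[i] <- het_a[i] + counts[i, j]
    het_a[j] <- het_a[j] + counts[i, j]
    n_het <- n_het + counts[i, j]
  }
  n <- sum(counts) + n0
  # init: apparent frequencies scaled by a small starting null mass
  r <- if (n0 > 0 || sum(hom) > 0) 0.05 else 0
  obs <- (2 * hom + het_a) / (2 * sum(counts))
  p <- obs * (1 - r)
  loglik_of <- function(p, r) {
    v <- 0
    for (i in seq_len(k)) for (j in seq_len(i)) if (i != j && counts[i, j] > 0)
      v <- v + counts[i, j] * log(2 * p[i] * p[j])
    hz <- hom > 0
    v <- v + sum(hom[hz] * log(p[hz]^2 + 2 * p[hz] * r))
    if (n0 > 0) v <- v + n0 * log(r^2)
    v
  }
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    denom <- p + 2 * r
    e_null <- ifelse(hom > 0, hom * 2 * r / denom, 0)  # i/null individuals
    e_hom <- hom - e_null
    p_new <- (2 * e_hom + het_a + e_null) / (2 * n)
    r_new <- (sum(e_null) + 2 * n0) / (2 * n)
    delta <- abs(r_new - r) + sum(abs(p_new - p))
    trace[it] <- loglik_of(p_new, max(r_new, .Machine$double.xmin))
    p <- p_new; r <- r_new
    if (delta < tol) { converged <- TRUE; break }
  }
  names(p) <- alleles
  structure(list(r_hat = r, p = p, iterations = it, converged = converged,
                 loglik = trace),
            class = "null_estimate")
}

#' @export
print.null_estimate <- function(x, ...) {
  cat(sprintf("null-allele EM: r_hat = %.4f (%d iterations%s)\n", x$r_hat,
              x$iterations, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Null-allele frequencies over all population x locus combinations
#'
#' @param ds a [genotype_dataset()].
#' @param failure_mix,tol,max_iter passed to [em_null_frequency()].
#' @return data.frame: population, locus, r_hat, n_typed, n_blank,
#'   converged. Combinations with no observations at all get `NA`.
#' @export
null_allele_table <- function(ds, failure_mix = 0, tol = 1e-6,
                              max_iter = 2000L) {
  pops <- unique(ds$population)
  rows <- list()
  for (p in pops) {
    prow <- which(ds$population == p)
    for (l in ds$loci) {
      j <- match(l, ds$loci)
      blanks <- sum(is.na(ds$a1[prow, j]))
      cnt <- genotype_counts(ds, p, l)
      est <- em_null_frequency(cnt, blanks, failure_mix, tol, max_iter)
      rows[[length(rows) + 1L]] <- data.frame(
        population = p, locus = l, r_hat = est$r_hat,
        n_typed = if (is.null(cnt)) 0L else sum(cnt), n_blank = blanks,
        converged = est$converged, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Corrected per-locus Weir-Cockerham input under the null-allele model:
# visible frequencies from the EM fit, the null state appended as an extra
# allele, heterozygote proportions augmented with the expected visible/null
# heterozygotes hidden among the apparent homozygotes.
ena_locus_input <- function(ds, pops, locus, failure_mix = 0) {
  j <- match(locus, ds$loci)
  nvec <- numeric(0); plist <- list(); hlist <- list(); rvec <- numeric(0)
  for (p in pops) {
    prow <- which(ds$population == p)
    blanks <- sum(is.na(ds$a1[prow, j]))
    cnt <- genotype_counts(ds, p, locus)
    if (is.null(cnt)) next
    est <- em_null_frequency(cnt, blanks, failure_mix)
    if (est$r_hat >= 1 - 1e-9) return("drop")
    n_tot <- sum(cnt) + (1 - failure_mix) * blanks
    if (n_tot < 2) next
    k <- nrow(cnt)
    hom <- diag(cnt)
    # observed heterozygote counts per visible allele
    het_a <- numeric(k)
    for (a in seq_len(k)) for (b in seq_len(a)) if (a != b) {
      het_a[a] <- het_a[a] + cnt[a, b]; het_a[b] <- het_a[b] + cnt[a, b]
    }
    e_null <- ifelse(hom > 0,
                     hom * 2 * est$r_hat / (est$p + 2 * est$r_hat), 0)
    h_vis <- (het_a + e_null) / n_tot
    h_null <- sum(e_null) / n_tot
    freq <- c(est$p, null = est$r_hat)
    names(freq) <- c(rownames(cnt), ".null")
    nvec <- c(nvec, n_tot)
    plist[[length(plist) + 1L]] <- freq
    hlist[[length(hlist) + 1L]] <- stats::setNames(c(h_vis, h_null),
                                                   names(freq))
    rvec <- c(rvec, est$r_hat)
  }
  if (length(nvec) < 2L) return(NULL)
  alleles <- sort(unique(unlist(lapply(plist, names))))
  alleles <- c(setdiff(alleles, ".null"), ".null")
  pmat <- matrix(0, length(nvec), length(alleles),
                 dimnames = list(NULL, alleles))
  hmat <- pmat
  for (i in seq_along(plist)) {
    pmat[i, names(plist[[i]])] <- plist[[i]]
    hmat[i, names(hlist[[i]])] <- hlist[[i]]
  }
  list(nvec = nvec, pmat = pmat, hmat = hmat, r = rvec)
}

#' ENA-corrected multilocus theta
#'
#' Recomputes the Weir-Cockerham theta with null-allele bias excluded: at
#' loci where the EM estimates a positive null frequency, per-population
#' allele frequencies are replaced by the EM-corrected frequencies with the
#' null state carried as an additional allele, and the null state's
#' variance components are excluded from the numerator and denominator
#' sums. Loci with all null frequencies (numerically) zero take the
#' uncorrected code path, so the correction is exactly the identity there.
#' Loci where `r_hat` reaches 1 in any population are dropped with a
#' warning.
#'
#' @param ds a [genotype_dataset()].
#' @param pops populations (default all).
#' @param null_table optional result of [null_allele_table()] (used to
#'   decide which loci need correction; estimates are refit per locus).
#' @param failure_mix passed to the EM.
#' @return list with `theta_corrected`, `theta_uncorrected`, per-locus
#'   vectors, and `loci_corrected`.
#' @references Chapuis M-P, Estoup A (2007) Microsatellite null alleles
#'   and estimation of population differentiation. Mol Biol Evol
#'   24:621-631.
#' @export
ena_corrected_fst <- function(ds, pops = unique(ds$population),
                              null_table = NULL, failure_mix = 0) {
  if (is.null(null_table)) null_table <- null_allele_table(ds, failure_mix)
  null_table <- null_table[null_table$population %in% pops, , drop = FALSE]
  sa <- sb <- sc <- 0
  theta_l <- stats::setNames(rep(NA_real_, length(ds$loci)), ds$loci)
  corrected <- character(0)
  for (l in ds$loci) {
    r_l <- null_table$r_hat[null_table$locus == l]
    if (all(is.na(r_l)) ) next
    if (max(r_l, na.rm = TRUE) < 1e-9) {
      j <- match(l, ds$loci)
      inp <- locus_wc_input(ds, pops, j, min_pops = 2L)
      if (is.null(inp)) next
      comp <- wc_abc(inp$nvec, inp$pmat, inp$hmat)
    } else {
      inp <- ena_locus_input(ds, pops, l, failure_mix)
      if (is.null(inp)) next
      if (identical(inp, "drop")) {
        warning("locus ", l, " dropped: estimated null frequency is 1")
        next
      }
      comp_all <- wc_abc(inp$nvec, inp$pmat, inp$hmat)
      if (is.null(comp_all)) next
      vis <- colnames(inp$pmat) != ".null"
      comp <- list(a = comp_all$a[vis], b = comp_all$b[vis],
                   c = comp_all$c[vis])
      corrected <- c(corrected, l)
    }
    if (is.null(comp)) next
    al <- sum(comp$a); bl <- sum(comp$b); cl <- sum(comp$c)
    if (al + bl + cl > 0) theta_l[l] <- al / (al + bl + cl)
    sa <- sa + al; sb <- sb + bl; sc <- sc + cl
  }
  unc <- wc_fstats(ds, pops)
  list(theta_corrected = if (sa + sb + sc > 0) sa / (sa + sb + sc)
                         else NA_real_,
       theta_uncorrected = unc$theta,
       theta_by_locus_corrected = theta_l,
       theta_by_locus_uncorrected = unc$theta_by_locus,
       loci_corrected = corrected)
}

#' Per-locus F_IS / null-frequency point set
#'
#' Builds the diagnostic point cloud pairing each (population, locus)
#' null-frequency estimate with the single-locus F_IS (the ratio form
#' `1 - H_O/H_E` with unbiased `H_E`, which is stabler than a per-locus
#' variance-components f at small n).
#'
#' @param ds a [genotype_dataset()].
#' @param null_table optional [null_allele_table()] result.
#' @return data.frame: population, locus, r_hat, fis (rows with undefined
#'   F_IS dropped).
#' @export
fis_null_points <- function(ds, null_table = NULL) {
  if (is.null(null_table)) null_table <- null_allele_table(ds)
  pops <- unique(ds$population)
  out <- list()
  for (p in pops) {
    h <- heterozygosities(ds, p)
    for (l in ds$loci) {
      he <- h$H_E[l]
      if (!is.finite(he) || he <= 0) next
      r <- null_table$r_hat[null_table$population == p &
                            null_table$locus == l]
      if (length(r) != 1L || !is.finite(r)) next
      out[[length(out) + 1L]] <- data.frame(
        population = p, locus = l, r_hat = r, fis = 1 - h$H_O[l] / he,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Linear regression of per-locus F_IS on null-allele frequency
#'
#' Ordinary least squares of F_IS on `r_hat` with Pearson correlation and
#' its two-sided p-value. A positive, significant slope is the signature
#' of apparent heterozygote deficits being driven by null alleles rather
#' than by inbreeding.
#'
#' @param points data.frame with columns `r_hat` and `fis` (e.g. from
#'   [fis_null_points()]).
#' @return list of class `"fis_null_regression"`: `slope`, `intercept`,
#'   `r`, `p_value`, `n_points`. Slope is `NA` when `r_hat` has zero
#'   variance.
#' @export
fis_null_regression <- function(points) {
  pts <- points[is.finite(points$r_hat) & is.finite(points$fis), ,
                drop = FALSE]
  if (nrow(pts) < 3L) stop("need at least 3 finite points")
  if (stats::var(pts$r_hat) == 0)
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r = NA_real_, p_value = NA_real_,
                          n_points = nrow(pts)),
                     class = "fis_null_regression"))
  fit <- stats::lm(fis ~ r_hat, data = pts)
  ct <- stats::cor.test(pts$r_hat, pts$fis)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r = unname(ct$estimate), p_value = ct$p.value,
                 n_points = nrow(pts)),
            class = "fis_null_regression")
}

#' @export
print.fis_null_regression <- function(x, ...) {
  cat(sprintf("F_IS ~ null frequency: Y = %.4f + %.4f X; r = %.4f; p = %s (n = %d)\n",
              x$intercept, x$slope, x$r, format(x$p_value, digits = 3),
              x$n_points))
  invisible(x)
}

#' Heterogeneity screen: inbreeding versus null-allele artifact
#'
#' Classifies a population's positive multilocus F_IS by the heterogeneity
#' of its per-locus values. Inbreeding affects all loci equally, so the
#' whole F_IS distribution (including its lower quartile) shifts above the
#' near-zero band: "inbreeding-like". Null alleles elevate F_IS only at
#' the loci carrying them, so the bulk of loci stay near zero while the
#' null-affected set (EM estimate at or above `r_threshold`) is elevated:
#' "null-artifact-like". Anything else, including too few usable loci, is
#' "inconclusive".
#'
#' @param fis_by_locus named numeric vector of per-locus F_IS (e.g. the
#'   ratio form from [fis_null_points()]).
#' @param r_hat_by_locus named numeric vector of per-locus null-frequency
#'   estimates for the same population.
#' @param r_threshold loci with `r_hat >=` this are "null-affected"
#'   (default 0.05).
#' @param fis_band half-width of the "near zero" F_IS band (default 0.05).
#' @return character scalar: `"inbreeding-like"`, `"null-artifact-like"`
#'   or `"inconclusive"`.
#' @export
fis_heterogeneity_screen <- function(fis_by_locus, r_hat_by_locus,
                                     r_threshold = 0.05, fis_band = 0.05) {
  common <- intersect(names(fis_by_locus), names(r_hat_by_locus))
  fis <- fis_by_locus[common]; r <- r_hat_by_locus[common]
  ok <- is.finite(fis) & is.finite(r)
  fis <- fis[ok]; r <- r[ok]
  if (length(fis) < 3L) return("inconclusive")
  # Inbreeding shifts F_IS at every locus, so even the lower quartile sits
  # above the near-zero band; null alleles elevate only the affected loci,
  # leaving the bulk (and the lower quartile) near zero. The quartile rule
  # is used first because EM null estimates are themselves inflated under
  # genuine inbreeding and cannot define the "free" locus set there.
  if (stats::quantile(fis, 0.25, names = FALSE) > fis_band)
    return("inbreeding-like")
  affected <- r >= r_threshold
  if (any(affected) && !all(affected) &&
      mean(fis[affected]) > fis_band && mean(fis[!affected]) <= fis_band)
    return("null-artifact-like")
  "inconclusive"
}
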