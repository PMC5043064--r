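#' Codominant diploid multilocus genotype dataset
#'
#' Container for microsatellite genotypes: one row per individual, one column
#' per locus, each cell an unordered pair of integer allele sizes (base
#' pairs). Missing genotypes are encoded as `NA` in *both* allele slots;
#' half-missing genotypes are rejected because every estimator in the package
#' treats an individual as either fully typed or fully untyped at a locus.
#'
#' @param a1,a2 integer matrices (individuals x loci) of allele sizes; `NA`
#'   for missing. Pairs are unordered: the constructor stores
#'   `pmin(a1, a2)` / `pmax(a1, a2)`.
#' @param individuals character vector of unique individual identifiers.
#' @param population character vector, one population code per individual
#'   (e.g. `"CHN.QLH"`).
#' @param species character vector, one species label per individual;
#'   defaults to a single label for all.
#' @param loci character vector of unique locus names.
#' @return An object of class `"genotype_dataset"`.
#' @seealso [read_genepop()], [read_long_csv()], [allele_freqs()]
#' @export
genotype_dataset <- function(a1, a2, individuals, population,
                             species = rep("sp1", length(individuals)),
                             loci = colnames(a1)) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(individuals)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(a1)))
  if (length(loci) == 0L) stop("locus list must be non-empty")
  if (anyDuplicated(loci)) stop("locus names must be unique")
  if (nrow(a1) != n || nrow(a2) != n || ncol(a1) != length(loci) ||
      ncol(a2) != length(loci))
    stop("allele matrices must be individuals x loci")
  if (length(population) != n || length(species) != n)
    stop("population and species labels must have one entry per individual")
  half <- xor(is.na(a1), is.na(a2))
  if (any(half))
    stop("half-missing genotype at individual ",
         individuals[row(a1)[half][1]], ", locus ", loci[col(a1)[half][1]])
  if (any(a1 <= 0L, na.rm = TRUE) || any(a2 <= 0L, na.rm = TRUE))
    stop("allele sizes must be positive integers")
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  dimnames(lo) <- dimnames(hi) <- list(individuals, loci)
  structure(list(individuals = as.character(individuals),
                 population = as.character(population),
                 species = as.character(species),
                 loci = as.character(loci),
                 a1 = lo, a2 = hi),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$individuals), "individuals,",
      length(x$loci), "loci,", length(unique(x$population)), "populations,",
      length(unique(x$species)), "species\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
summary.genotype_dataset <- function(object, ...) {
  tab <- table(object$population)
  cat("Individuals per population:\n")
  print(tab)
  invisible(tab)
}

#' Population sample sizes
#' @param ds a [genotype_dataset()].
#' @return named integer vector of individuals per population, in order of
#'   first appearance.
#' @export
pop_sizes <- function(ds) {
  pops <- unique(ds$population)
  stats::setNames(vapply(pops, function(p) sum(ds$population == p),
                         integer(1)), pops)
}

#' Subset a genotype dataset by individuals
#' @param ds a [genotype_dataset()].
#' @param keep logical or integer index over individuals.
#' @return a `genotype_dataset` with the selected individuals.
#' @export
subset_individuals <- function(ds, keep) {
  genotype_dataset(ds$a1[keep, , drop = FALSE], ds$a2[keep, , drop = FALSE],
                   ds$individuals[keep], ds$population[keep],
                   ds$species[keep], ds$loci)
}

two_datasets_equal <- function(x, y) {
  identical(x$loci, y$loci) &&
    identical(x$population, y$population) &&
    identical(unname(x$a1), unname(y$a1)) &&
    identical(unname(x$a2), unname(y$a2))
}

#' Per-population, per-locus allele frequencies
#'
#' Tabulates non-missing gene copies for every population x locus cell and
#' normalises to frequencies. A missing genotype contributes nothing (no
#' single-allele contribution), so `gene_count` is always `2 * typed_n`.
#' Cells with no typed individuals carry an empty frequency vector and
#' `gene_count = 0`; this is a valid state, not an error.
#'
#' @param ds a [genotype_dataset()].
#' @return An object of class `"allele_freq_table"`: a list with one entry
#'   per population, each a list over loci of
#'   `list(freq = <named numeric>, gene_count, typed_n)`. Attributes
#'   `pops` and `loci` give the ordering.
#' @export
allele_freqs <- function(ds) {
  pops <- unique(ds$population)
  out <- lapply(pops, function(p) {
    rows <- which(ds$population == p)
    per_locus <- lapply(seq_along(ds$loci), function(j) {
      x <- c(ds$a1[rows, j], ds$a2[rows, j])
      x <- x[!is.na(x)]
      if (length(x) == 0L)
        return(list(freq = stats::setNames(numeric(0), character(0)),
                    gene_count = 0L, typed_n = 0L))
      tab <- table(x)
      list(freq = stats::setNames(as.numeric(tab) / length(x), names(tab)),
           gene_count = length(x), typed_n = length(x) %/% 2L)
    })
    names(per_locus) <- ds$loci
    per_locus
  })
  names(out) <- pops
  structure(out, pops = pops, loci = ds$loci, class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat("allele_freq_table:", length(attr(x, "pops")), "populations x",
      length(attr(x, "loci")), "loci\n")
  invisible(x)
}

# Mean allele frequencies per locus over a set of populations (unweighted
# across populations, as in Nei's gene-diversity decomposition). Populations
# untyped at a locus are dropped for that locus.
mean_freqs_across_pops <- function(ft, pops) {
  loci <- attr(ft, "loci")
  out <- lapply(loci, function(l) {
    mats <- lapply(pops, function(p) ft[[p]][[l]])
    mats <- Filter(function(e) e$gene_count > 0L, mats)
    if (length(mats) == 0L) return(stats::setNames(numeric(0), character(0)))
    alleles <- sort(unique(unlist(lapply(mats, function(e) names(e$freq)))))
    acc <- stats::setNames(numeric(length(alleles)), alleles)
    for (e in mats) acc[names(e$freq)] <- acc[names(e$freq)] + e$freq
    acc / length(mats)
  })
  names(out) <- loci
  out
}
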