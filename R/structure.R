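# Per-locus scaffolding for allele-size statistics: state counts per
# population and the size of each allelic state.
rst_locus_setup <- function(ds, pops, locus_j) {
  Cs <- list(); sizes <- NULL
  alleles <- sort(unique(c(ds$a1[, locus_j], ds$a2[, locus_j])))
  alleles <- alleles[!is.na(alleles)]
  if (length(alleles) < 2L) return(NULL)
  S <- length(alleles)
  Cmat <- matrix(0, 0, S)
  for (p in pops) {
    rows <- which(ds$population == p)
    x <- c(ds$a1[rows, locus_j], ds$a2[rows, locus_j])
    x <- x[!is.na(x)]
    if (length(x) == 0L) next
    Cmat <- rbind(Cmat, tabulate(match(x, alleles), nbins = S))
  }
  if (nrow(Cmat) < 2L) return(NULL)
  list(C = Cmat, sizes = as.numeric(alleles))
}

# Variance components of allele size at one locus given state counts C
# (populations x states) and state sizes y. Returns c(sigma_a, sigma_w)
# or NULL when degenerate.
rst_components <- function(C, y) {
  n_i <- rowSums(C)
  N <- sum(n_i); r <- nrow(C)
  means <- as.vector(C %*% y) / n_i
  grand <- sum(C %*% y) / N
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum(C %*% y^2) - sum(n_i * means^2)
  msb <- ssb / (r - 1)
  msw <- ssw / (N - r)
  nc <- (N - sum(n_i^2) / N) / (r - 1)
  sigma_a <- (msb - msw) / nc
  c(sigma_a = sigma_a, sigma_w = msw)
}

#' R_ST: allele-size analogue of F_ST
#'
#' Variance-components estimator on allele sizes: for each locus a one-way
#' ANOVA of gene-copy sizes grouped by population yields the
#' among-population and within-population size variance; the multilocus
#' R_ST is the ratio of summed components. Sensitive to stepwise-mutation
#' signal, unlike the allele-identity theta.
#'
#' @param ds a [genotype_dataset()] whose allele calls are integer sizes.
#' @param pops populations (default all).
#' @return list with `rst` (multilocus), `rst_by_locus`, and the summed
#'   variance components.
#' @references Slatkin M (1995) A measure of population subdivision based
#'   on microsatellite allele frequencies. Genetics 139:457-462.
#' @export
r_st <- function(ds, pops = unique(ds$population)) {
  if (length(pops) < 2L) stop("need at least two populations")
  num <- den <- 0
  by_locus <- stats::setNames(rep(NA_real_, length(ds$loci)), ds$loci)
  for (j in seq_along(ds$loci)) {
    setup <- rst_locus_setup(ds, pops, j)
    if (is.null(setup)) next
    comp <- rst_components(setup$C, setup$sizes)
    tot <- comp[1] + comp[2]
    if (is.finite(tot) && tot > 0) by_locus[j] <- comp[[1]] / tot
    if (is.finite(tot)) { num <- num + comp[[1]]; den <- den + tot }
  }
  list(rst = if (den > 0) unname(num / den) else NA_real_,
       rst_by_locus = by_locus, sigma_a = unname(num),
       sigma_total = unname(den))
}

#' Allele-size permutation test for stepwise-mutation signal
#'
#' Permutes the size labels among the distinct allelic states at each locus
#' (the genotype identity structure is untouched) and recomputes R_ST;
#' significantly larger observed R_ST than the permutational null `pR_ST`
#' indicates that stepwise mutation contributes to differentiation beyond
#' drift. The null distribution's mean approximates the size-blind
#' (F_ST-like) value.
#'
#' @param ds a [genotype_dataset()].
#' @param n_perm number of size permutations (must be >= 1).
#' @param seed integer RNG seed.
#' @param pops populations (default all).
#' @return list of class `"size_perm_test"`: `rst_obs`, `p_value`
#'   (add-one rule, `P(pR_ST >= R_ST)`), `prst_mean`, `prst_quantiles`,
#'   `n_perm`. All `NA` when every locus is monomorphic.
#' @export
allele_size_permutation_test <- function(ds, n_perm = 10000L, seed = 1L,
                                         pops = unique(ds$population)) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (length(pops) < 2L) stop("need at least two populations")
  setups <- lapply(seq_along(ds$loci), function(j)
    rst_locus_setup(ds, pops, j))
  keep <- !vapply(setups, is.null, logical(1))
  setups <- setups[keep]
  if (length(setups) == 0L)
    return(structure(list(rst_obs = NA_real_, p_value = NA_real_,
                          prst_mean = NA_real_, prst_quantiles = NULL,
                          n_perm = n_perm),
                     class = "size_perm_test"))
  multiloc <- function(size_list) {
    num <- den <- 0
    for (i in seq_along(setups)) {
      comp <- rst_components(setups[[i]]$C, size_list[[i]])
      tot <- comp[1] + comp[2]
      if (is.finite(tot)) { num <- num + comp[1]; den <- den + tot }
    }
    if (den > 0) num / den else NA_real_
  }
  obs <- multiloc(lapply(setups, `[[`, "sizes"))
  set.seed(seed)
  prst <- vapply(seq_len(n_perm), function(b)
    multiloc(lapply(setups, function(s) sample(s$sizes))), numeric(1))
  structure(list(rst_obs = obs,
                 p_value = (1 + sum(prst >= obs, na.rm = TRUE)) /
                   (1 + n_perm),
                 prst_mean = mean(prst, na.rm = TRUE),
                 prst_quantiles = stats::quantile(
                   prst, c(0.025, 0.5, 0.975), na.rm = TRUE),
                 n_perm = n_perm),
            class = "size_perm_test")
}

#' @export
print.size_perm_test <- function(x, ...) {
  cat(sprintf("allele-size permutation test: R_ST = %.4f, mean pR_ST = %.4f, p = %.4g (%d permutations)\n",
              x$rst_obs, x$prst_mean, x$p_value, x$n_perm))
  invisible(x)
}

#' Nei genetic distance between two populations
#'
#' `variant = "DA"` (default): `1 - mean over loci of sum_a sqrt(x_a y_a)`,
#' bounded in `[0, 1]` and well behaved with non-shared alleles.
#' `variant = "standard"`: Nei's 1972 distance
#' `-ln(J_xy / sqrt(J_x J_y))` with the J's averaged over loci. Loci
#' untyped in either population are dropped.
#'
#' @param ft an [allele_freqs()] table.
#' @param popA,popB population codes.
#' @param variant `"DA"` or `"standard"`.
#' @return distance (numeric); `NA` when there is no shared typed locus.
#' @references Nei M, Tajima F, Tateno Y (1983) Accuracy of estimated
#'   phylogenetic trees from molecular data. J Mol Evol 19:153-170.
#' @export
nei_distance <- function(ft, popA, popB, variant = c("DA", "standard")) {
  variant <- match.arg(variant)
  loci <- attr(ft, "loci")
  shared <- Filter(function(l)
    ft[[popA]][[l]]$gene_count > 0L && ft[[popB]][[l]]$gene_count > 0L,
    loci)
  if (length(shared) == 0L) return(NA_real_)
  if (variant == "DA") {
    s <- vapply(shared, function(l) {
      x <- ft[[popA]][[l]]$freq; y <- ft[[popB]][[l]]$freq
      common <- intersect(names(x), names(y))
      if (length(common) == 0L) return(0)
      sum(sqrt(x[common] * y[common]))
    }, numeric(1))
    return(1 - mean(s))
  }
  jx <- jy <- jxy <- numeric(length(shared))
  for (i in seq_along(shared)) {
    l <- shared[i]
    x <- ft[[popA]][[l]]$freq; y <- ft[[popB]][[l]]$freq
    jx[i] <- sum(x^2); jy[i] <- sum(y^2)
    common <- intersect(names(x), names(y))
    jxy[i] <- if (length(common)) sum(x[common] * y[common]) else 0
  }
  -log(mean(jxy) / sqrt(mean(jx) * mean(jy)))
}

#' Pairwise Nei distance matrix
#' @param ft an [allele_freqs()] table.
#' @param pops populations (default all).
#' @param variant see [nei_distance()].
#' @return symmetric matrix with zero diagonal.
#' @export
nei_distance_matrix <- function(ft, pops = attr(ft, "pops"),
                                variant = c("DA", "standard")) {
  variant <- match.arg(variant)
  k <- length(pops)
  d <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k))
    d[i, j] <- d[j, i] <- nei_distance(ft, pops[i], pops[j], variant)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Q criterion. Ties in Q are broken
#' deterministically by the lexicographic order of the joined taxon-pair
#' labels, so the result does not depend on input order. Negative branch
#' lengths are clamped to zero with the deficit transferred to the sister
#' edge (reported lengths; the raw lengths are kept in
#' `attr(tree, "raw_edge_length")`).
#'
#' @param d symmetric distance matrix with population dimnames, or a
#'   `"pairwise_stat"`.
#' @return an [ape] `"phylo"` object (unrooted; basal trichotomy).
#' @references Saitou N, Nei M (1987) The neighbor-joining method. Mol
#'   Biol Evol 4:406-425.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "pairwise_stat")) d <- d$value
  labs <- rownames(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least three populations")
  if (any(!is.finite(d[upper.tri(d)]))) stop("undefined distances in matrix")
  diag(d) <- 0
  n_nodes <- 2L * n - 2L
  edge <- matrix(0L, 0L, 2L); elen <- numeric(0); eraw <- numeric(0)
  active_id <- seq_len(n)            # node ids of active clusters
  active_lab <- labs                 # lexicographic tie-break keys
  D <- d
  next_node <- n + 1L
  while (length(active_id) > 3L) {
    m <- length(active_id)
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      pr <- sort(c(active_lab[ij[1]], active_lab[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    ri <- li; rj <- lj
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    u <- next_node; next_node <- next_node + 1L
    edge <- rbind(edge, c(u, active_id[i]), c(u, active_id[j]))
    elen <- c(elen, li, lj); eraw <- c(eraw, ri, rj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    newlab <- min(active_lab[c(i, j)])
    active_id <- c(active_id[keep], u)
    active_lab <- c(active_lab[keep], newlab)
  }
  # final three clusters joined at the basal node
  u <- next_node
  D3 <- D
  l1 <- (D3[1, 2] + D3[1, 3] - D3[2, 3]) / 2
  l2 <- (D3[1, 2] + D3[2, 3] - D3[1, 3]) / 2
  l3 <- (D3[1, 3] + D3[2, 3] - D3[1, 2]) / 2
  raw3 <- c(l1, l2, l3)
  cl3 <- pmax(raw3, 0)
  edge <- rbind(edge, c(u, active_id[1]), c(u, active_id[2]),
                c(u, active_id[3]))
  elen <- c(elen, cl3); eraw <- c(eraw, raw3)
  # renumber so the basal node is n+1 and internals follow preorder-ish
  map <- integer(n_nodes)
  map[seq_len(n)] <- seq_len(n)
  internal <- sort(unique(edge[, 1L]))
  map[internal] <- n + rank(-internal)  # basal (largest id) becomes n+1
  edge2 <- cbind(map[edge[, 1L]], map[edge[, 2L]])
  tr <- list(edge = edge2, edge.length = elen, tip.label = labs,
             Nnode = n - 2L)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  o <- match(paste(tr$edge[, 1], tr$edge[, 2]),
             paste(edge2[, 1], edge2[, 2]))
  attr(tr, "raw_edge_length") <- eraw[o]
  tr
}

# Canonical internal bipartitions of an unrooted phylo: for every edge
# whose child is an internal node, the descendant tip set; canonicalised
# as the side not containing the alphabetically first tip.
internal_splits <- function(tree) {
  n <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1L]
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  tips_under <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tips_under))
  }
  internal_children <- tree$edge[tree$edge[, 2L] > n, 2L]
  sigs <- vapply(internal_children, function(nd) {
    side <- tips_under(nd)
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    paste(sort(side), collapse = "\r")
  }, character(1))
  sigs[!is.na(sigs)]
}

#' Neighbor-joining population tree with locus bootstrap
#'
#' Builds the Nei-distance NJ tree on the full data, then resamples loci
#' with replacement `B` times, recomputing the distance matrix and tree
#' each time, and reports the percentage of replicates supporting each
#' internal bipartition of the full-data tree (stored in `node.label`).
#'
#' @param ds a [genotype_dataset()].
#' @param B bootstrap replicates.
#' @param variant distance variant, see [nei_distance()].
#' @param seed integer RNG seed.
#' @param pops populations (default all).
#' @return a `"phylo"` tree; internal nodes (except the basal one) carry
#'   bootstrap percentages in `node.label`; also returned in
#'   `attr(tree, "split_support")`.
#' @export
bootstrap_tree <- function(ds, B = 10000L, variant = c("DA", "standard"),
                           seed = 1L, pops = unique(ds$population)) {
  variant <- match.arg(variant)
  if (length(ds$loci) < 2L) stop("locus bootstrap needs at least 2 loci")
  if (B < 1L) stop("B must be >= 1")
  ft <- allele_freqs(ds)
  full <- neighbor_joining(nei_distance_matrix(ft, pops, variant))
  target <- internal_splits(full)
  hits <- stats::setNames(numeric(length(target)), target)
  set.seed(seed)
  L <- length(ds$loci)
  for (b in seq_len(B)) {
    pick <- sample.int(L, L, replace = TRUE)
    js <- sort(pick)
    sub <- genotype_dataset(ds$a1[, js, drop = FALSE],
                            ds$a2[, js, drop = FALSE],
                            ds$individuals, ds$population, ds$species,
                            make.unique(ds$loci[js]))
    db <- nei_distance_matrix(allele_freqs(sub), pops, variant)
    if (any(!is.finite(db[upper.tri(db)]))) next
    sp <- internal_splits(neighbor_joining(db))
    hit <- target %in% sp
    hits[hit] <- hits[hit] + 1
  }
  supp <- 100 * hits / B
  # attach node labels: map each internal child node to its split support
  n <- length(full$tip.label)
  labels <- rep(NA_character_, full$Nnode)
  kids <- split(full$edge[, 2L], full$edge[, 1L])
  ref <- sort(full$tip.label)[1L]
  tips_under <- function(node) {
    if (node <= n) return(full$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tips_under))
  }
  for (nd in unique(full$edge[full$edge[, 2L] > n, 2L])) {
    side <- tips_under(nd)
    if (ref %in% side) side <- setdiff(full$tip.label, side)
    sig <- paste(sort(side), collapse = "\r")
    if (sig %in% names(supp))
      labels[nd - n] <- formatC(supp[sig], format = "f", digits = 1)
  }
  full$node.label <- labels
  attr(full, "split_support") <- supp
  full
}
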