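#' Run the full analysis chain on a genotype dataset
#'
#' Orchestrates the end-to-end analysis in the order the statistics depend
#' on each other: null-allele estimation, Hardy-Weinberg tests (per
#' locus-population and the global heterozygote-deficiency test per
#' population) with Holm correction, per-population and species-level
#' diversity tables, the allele-size permutation test, pairwise theta with
#' permutation significance, Nei-distance neighbor-joining trees with
#' locus bootstrap, and the F_IS/null-frequency diagnostics (regression
#' plus per-population heterogeneity screen). Families for the Holm and
#' Bonferroni corrections are defined within species.
#'
#' @param ds a [genotype_dataset()] with at least one individual.
#' @param g rarefaction standard size (diploid individuals).
#' @param mc an [mc_params()] object for the HWE chains.
#' @param n_perm permutations for the allele-size test and pairwise theta
#'   (0 skips pairwise permutation p-values).
#' @param B bootstrap replicates for the NJ tree.
#' @param dist_variant Nei distance variant, see [nei_distance()].
#' @param fis_estimator passed to [pop_diversity()].
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param output_dir optional directory; when given, writes the report
#'   bundle (TSV tables, PHYLIP distance matrix, Newick tree, JSON
#'   summary, MANIFEST).
#' @return list of class `"msat_analysis"` with elements `diversity`,
#'   `species`, `hwe`, `global_hwe`, `null_alleles`, `size_perm`,
#'   `pairwise_fst`, `distance`, `tree`, `regression`, `screen`, `seed`,
#'   `config_hash`.
#' @export
msat_analysis <- function(ds, g = 10L, mc = mc_params(),
                          n_perm = 10000L, B = 10000L,
                          dist_variant = c("DA", "standard"),
                          fis_estimator = c("weir_cockerham", "nei"),
                          seed = 1L, output_dir = NULL) {
  dist_variant <- match.arg(dist_variant)
  fis_estimator <- match.arg(fis_estimator)
  if (length(ds$individuals) == 0L) stop("stage io: empty dataset")
  cfg <- list(g = g, mc = unclass(mc), n_perm = n_perm, B = B,
              dist_variant = dist_variant, fis_estimator = fis_estimator,
              seed = seed)
  hash <- config_hash(cfg)
  species <- unique(ds$species)
  pops <- unique(ds$population)

  null_tab <- null_allele_table(ds)

  mc1 <- mc; mc1$seed <- seed + 1L
  hwe <- hwe_table(ds, mc1, direction = "two_sided")
  # Holm family per species
  hwe$species <- ds$species[match(hwe$population, ds$population)]
  for (sp in species) {
    i <- hwe$species == sp
    hc <- holm_correction(hwe$p_value[i])
    hwe$p_holm[i] <- hc$adjusted
    hwe$significant[i] <- hc$reject
  }
  global_hwe <- do.call(rbind, lapply(seq_along(pops), function(i) {
    mcg <- mc; mcg$seed <- seed + 100L + i
    res <- global_heterozygote_deficiency(ds, pops[i], mcg)
    data.frame(population = pops[i], p_value = res$p_value,
               se_p = res$se_p, stringsAsFactors = FALSE)
  }))

  diversity <- pop_diversity(ds, g, fis_estimator)
  species_sum <- lapply(species, function(sp) {
    if (length(unique(ds$population[ds$species == sp])) < 2L) return(NULL)
    species_summary(ds, sp)
  })
  names(species_sum) <- species
  species_sum <- Filter(Negate(is.null), species_sum)

  per_species <- function(fun) {
    out <- lapply(species, function(sp) {
      sp_pops <- unique(ds$population[ds$species == sp])
      if (length(sp_pops) < 2L) return(NULL)
      sub <- subset_individuals(ds, ds$species == sp)
      fun(sub, sp_pops)
    })
    names(out) <- species
    Filter(Negate(is.null), out)
  }

  size_perm <- per_species(function(sub, sp_pops)
    allele_size_permutation_test(sub, n_perm, seed = seed + 2L))
  pw <- per_species(function(sub, sp_pops)
    pairwise_fst(sub, sp_pops, n_perm = n_perm, seed = seed + 3L))
  dist_m <- per_species(function(sub, sp_pops)
    nei_distance_matrix(allele_freqs(sub), sp_pops, dist_variant))
  trees <- lapply(dist_m, function(d) {
    if (nrow(d) >= 3L && all(is.finite(d[upper.tri(d)])))
      neighbor_joining(d) else NULL
  })
  btrees <- per_species(function(sub, sp_pops) {
    if (length(sp_pops) < 3L || length(sub$loci) < 2L) return(NULL)
    bootstrap_tree(sub, B, dist_variant, seed = seed + 4L)
  })

  points <- fis_null_points(ds, null_tab)
  regression <- if (!is.null(points) && nrow(points) >= 3L &&
                    stats::var(points$r_hat) > 0)
    fis_null_regression(points) else NULL
  screen <- vapply(pops, function(p) {
    pts <- points[points$population == p, , drop = FALSE]
    fis_heterogeneity_screen(
      stats::setNames(pts$fis, pts$locus),
      stats::setNames(pts$r_hat, pts$locus))
  }, character(1))

  out <- structure(list(diversity = diversity, species = species_sum,
                        hwe = hwe, global_hwe = global_hwe,
                        null_alleles = null_tab, size_perm = size_perm,
                        pairwise_fst = pw, distance = dist_m,
                        tree = trees, bootstrap_tree = btrees,
                        regression = regression, screen = screen,
                        points = points, seed = seed, config_hash = hash),
                   class = "msat_analysis")
  if (!is.null(output_dir)) write_report_bundle(out, ds, output_dir)
  out
}

#' @export
print.msat_analysis <- function(x, ...) {
  cat("msat_analysis (config", x$config_hash, ")\n")
  cat("  populations:", nrow(x$diversity), " species:",
      length(x$species), "\n")
  cat("  HWE tests performed:", sum(!is.na(x$hwe$p_value)),
      "; significant after Holm:", sum(x$hwe$significant, na.rm = TRUE),
      "\n")
  if (!is.null(x$regression)) {
    cat("  F_IS ~ null-frequency regression: ")
    print(x$regression)
  }
  cat("  heterogeneity screen:",
      paste(sprintf("%s=%s", names(x$screen), x$screen), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.msat_analysis <- function(object, ...) {
  print(object$diversity)
  invisible(object)
}

# Stable hash of the run configuration (polynomial rolling hash over the
# serialized list; stays in double-precision-exact integer range).
config_hash <- function(cfg) {
  raw <- serialize(cfg, NULL, version = 2L)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

write_report_bundle <- function(x, ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  put <- function(name, writer) {
    path <- file.path(dir, name)
    writer(path)
    manifest <<- c(manifest, name)
  }
  put("diversity_by_population.tsv", function(p)
    utils::write.table(x$diversity, p, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "NA"))
  if (length(x$species)) {
    sp <- do.call(rbind, lapply(x$species, function(s)
      data.frame(species = s$species, N_ind = s$N_ind, N_pop = s$N_pop,
                 A = s$A, A_E = s$A_E, H_O = s$H_O, H_S = s$H_S,
                 H_T = s$H_T, F_IS = s$F_IS, F_ST_nei = s$F_ST_nei,
                 F_ST_wc = s$F_ST_wc)))
    put("diversity_by_species.tsv", function(p)
      utils::write.table(sp, p, sep = "\t", row.names = FALSE,
                         quote = FALSE, na = "NA"))
  }
  put("hwe_tests.tsv", function(p)
    utils::write.table(x$hwe, p, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "NA"))
  put("null_allele_frequencies.tsv", function(p)
    utils::write.table(x$null_alleles, p, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "NA"))
  for (sp in names(x$pairwise_fst)) {
    put(paste0("pairwise_fst_", sp, ".tsv"), function(p)
      utils::write.table(x$pairwise_fst[[sp]]$value, p, sep = "\t",
                         quote = FALSE, na = "NA"))
  }
  for (sp in names(x$distance)) {
    put(paste0("distance_", sp, ".phylip"), function(p) {
      d <- x$distance[[sp]]
      con <- file(p, "w"); on.exit(close(con))
      writeLines(sprintf("%5d", nrow(d)), con)
      for (i in seq_len(nrow(d)))
        writeLines(paste(formatC(rownames(d)[i], width = -10),
                         paste(sprintf("%.6f", d[i, ]), collapse = " ")),
                   con)
    })
  }
  for (sp in names(x$bootstrap_tree)) {
    if (is.null(x$bootstrap_tree[[sp]])) next
    put(paste0("nj_tree_", sp, ".nwk"), function(p)
      ape::write.tree(x$bootstrap_tree[[sp]], p))
  }
  summary_json <- list(
    config_hash = x$config_hash, seed = x$seed,
    n_individuals = length(ds$individuals), n_loci = length(ds$loci),
    n_populations = length(unique(ds$population)),
    hwe_significant = sum(x$hwe$significant, na.rm = TRUE),
    screen = as.list(x$screen),
    regression = if (is.null(x$regression)) NULL else
      x$regression[c("slope", "intercept", "r", "p_value", "n_points")])
  put("summary.json", function(p)
    jsonlite::write_json(summary_json, p, auto_unbox = TRUE, digits = NA,
                         null = "null"))
  writeLines(c(sprintf("config_hash\t%s", x$config_hash),
               sprintf("complete\tTRUE"), manifest),
             file.path(dir, "MANIFEST"))
  invisible(dir)
}

#' Simulation-based validation of the analysis chain
#'
#' Runs simulate-then-analyze loops over the named presets and tabulates
#' parameter recovery: the multilocus F_IS estimate against the selfing
#' equilibrium `s/(2-s)`, the EM null-frequency estimate against the
#' realized injected frequency, the multilocus theta against the regime,
#' and the type-I error of the exact HWE test (enumeration path) on
#' random-mating demes.
#'
#' @param presets named list of [sim_config()]s (default
#'   [scenario_presets()]).
#' @param replicates simulation replicates per preset (>= 2).
#' @param seed integer master seed.
#' @return data.frame of class `"msat_validation"`: one row per preset x
#'   metric with the mean estimate, its standard error over replicates,
#'   and the generating truth.
#' @export
run_validation <- function(presets = scenario_presets(), replicates = 10L,
                           seed = 1L) {
  if (replicates < 2L) stop("replicates must be >= 2")
  rows <- list()
  for (nm in names(presets)) {
    cfg <- presets[[nm]]
    fis <- theta <- rerr <- alpha <- numeric(0)
    for (rep_i in seq_len(replicates)) {
      cfg_i <- cfg; cfg_i$seed <- seed + 1000L * match(nm, names(presets)) +
        rep_i
      sim <- simulate_genotypes(cfg_i)
      ds <- sim$dataset
      f <- wc_fstats(ds)
      fis <- c(fis, f$f); theta <- c(theta, f$theta)
      ni <- sim$truth$null_info
      if (!is.null(ni) && nrow(ni) > 0) {
        nt <- null_allele_table(ds)
        m <- merge(nt, ni, by = c("population", "locus"))
        rerr <- c(rerr, mean(m$r_hat - m$realized_r))
      }
      if (cfg$s == 0 && all(cfg$null_spec == 0)) {
        ht <- hwe_table(subset_individuals(
          ds, ds$population == unique(ds$population)[1L]),
          mc_params(seed = seed + rep_i), enum_cap = 2e4)
        p <- ht$p_value[ht$method == "exact_enumeration"]
        if (length(p)) alpha <- c(alpha, mean(p < 0.05))
      }
    }
    se <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
                      else NA_real_
    add <- function(metric, est, truth_v) {
      rows[[length(rows) + 1L]] <<- data.frame(
        preset = nm, metric = metric, estimate = mean(est),
        se = se(est), truth = truth_v, n = length(est),
        stringsAsFactors = FALSE)
    }
    add("F_IS", fis, cfg$s / (2 - cfg$s))
    add("theta", theta, NA_real_)
    if (length(rerr)) add("r_hat_bias", rerr, 0)
    if (length(alpha)) add("hwe_type1", alpha, 0.05)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("msat_validation", "data.frame")
  out
}
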