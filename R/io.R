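#' Read a GENEPOP file
#'
#' Parses the classic GENEPOP dialect: a title line, one locus name per line
#' (or a single comma-separated line), then population blocks delimited by
#' lines equal to `pop` (case-insensitive). Individual lines are
#' `name , a1a2 a1a2 ...` with fixed-width 2- or 3-digit allele codes;
#' `00`/`000` encodes a missing allele. The digit width is auto-detected
#' from the genotype field length unless `allele_digits` is given.
#'
#' GENEPOP files carry no explicit population names: by convention each
#' block is named from the last token of its final individual's name, unless
#' `pop_names` overrides this. Species labels are not part of the format;
#' supply `species_map` (population code -> species) when needed.
#'
#' @param path file path.
#' @param allele_digits 2 or 3, or `NULL` to auto-detect.
#' @param pop_names optional character vector of population codes, one per
#'   `pop` block.
#' @param species_map optional named character vector mapping population
#'   code to species label.
#' @return a [genotype_dataset()].
#' @export
read_genepop <- function(path, allele_digits = NULL, pop_names = NULL,
                         species_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\r$", "", lines)
  if (length(lines) < 3L) stop("GENEPOP parse error: file too short")
  body <- lines[-1L]
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_idx) == 0L)
    stop("GENEPOP parse error: no 'pop' delimiter found")
  locus_lines <- body[seq_len(pop_idx[1L] - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) stop("GENEPOP parse error: no locus names")

  blocks <- vector("list", length(pop_idx))
  bounds <- c(pop_idx, length(body) + 1L)
  for (b in seq_along(pop_idx)) {
    rows <- body[seq(bounds[b] + 1L, bounds[b + 1L] - 1L)]
    blocks[[b]] <- rows[nzchar(trimws(rows))]
  }
  if (any(vapply(blocks, length, integer(1)) == 0L))
    stop("GENEPOP parse error: empty population block")

  parse_ind <- function(line, lineno) {
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2L)
      stop("GENEPOP parse error at line ", lineno, ": no comma separator")
    name <- trimws(parts[1L])
    codes <- strsplit(trimws(paste(parts[-1L], collapse = " ")),
                      "\\s+")[[1]]
    if (length(codes) != length(loci))
      stop("GENEPOP parse error at line ", lineno, ": expected ",
           length(loci), " genotypes, found ", length(codes))
    list(name = name, codes = codes)
  }

  lineno_of <- function(b, i) 1L + bounds[b] + i  # position in original file
  inds <- list(); k <- 0L
  for (b in seq_along(blocks)) for (i in seq_along(blocks[[b]])) {
    k <- k + 1L
    inds[[k]] <- c(parse_ind(blocks[[b]][i], lineno_of(b, i)), block = b)
  }

  all_codes <- unlist(lapply(inds, `[[`, "codes"))
  if (is.null(allele_digits)) {
    w <- unique(nchar(all_codes))
    if (length(w) != 1L || !(w %in% c(4L, 6L)))
      stop("GENEPOP parse error: cannot auto-detect allele digit width ",
           "(genotype field widths: ", paste(w, collapse = ","), ")")
    allele_digits <- w / 2L
  }
  if (!allele_digits %in% c(2L, 3L)) stop("allele_digits must be 2 or 3")
  if (any(nchar(all_codes) != 2L * allele_digits))
    stop("GENEPOP parse error: genotype field width inconsistent with ",
         allele_digits, "-digit coding")

  n <- length(inds); L <- length(loci)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    codes <- inds[[i]]$codes
    x1 <- as.integer(substr(codes, 1L, allele_digits))
    x2 <- as.integer(substr(codes, allele_digits + 1L, 2L * allele_digits))
    miss1 <- x1 == 0L; miss2 <- x2 == 0L
    if (any(xor(miss1, miss2)))
      stop("GENEPOP parse error: half-missing genotype for individual '",
           inds[[i]]$name, "'")
    x1[miss1] <- NA_integer_; x2[miss2] <- NA_integer_
    a1[i, ] <- x1; a2[i, ] <- x2
  }

  block <- vapply(inds, function(e) e$block, integer(1))
  if (is.null(pop_names)) {
    pop_names <- vapply(seq_along(blocks), function(b) {
      last <- inds[[max(which(block == b))]]$name
      toks <- strsplit(last, "\\s+")[[1]]
      toks[length(toks)]
    }, character(1))
    if (anyDuplicated(pop_names))
      pop_names <- make.unique(pop_names, sep = "_")
  }
  if (length(pop_names) != length(blocks))
    stop("pop_names must have one entry per population block")
  population <- pop_names[block]
  species <- if (is.null(species_map)) rep("sp1", n) else {
    if (!all(pop_names %in% names(species_map)))
      stop("species_map missing entries for some populations")
    unname(species_map[population])
  }
  ind_names <- make.unique(vapply(inds, `[[`, character(1), "name"))
  genotype_dataset(a1, a2, ind_names, population, species, loci)
}

#' Write a GENEPOP file
#'
#' Emits the dialect accepted by [read_genepop()]; the written file re-parses
#' to a dataset equal to the input (population block order preserved,
#' population code appended to each individual name so codes survive the
#' round trip).
#'
#' @param ds a [genotype_dataset()].
#' @param path output path.
#' @param allele_digits 2 or 3; every allele size must fit the width.
#' @param title first line of the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(ds, path, allele_digits = 3L,
                          title = "msatpop export") {
  if (!allele_digits %in% c(2L, 3L)) stop("allele_digits must be 2 or 3")
  maxcode <- 10L^allele_digits - 1L
  if (any(ds$a2 > maxcode, na.rm = TRUE))
    stop("allele size exceeds ", allele_digits, "-digit coding")
  fmt <- function(x) {
    x[is.na(x)] <- 0L
    formatC(x, width = allele_digits, flag = "0")
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(ds$loci, con)
  for (p in unique(ds$population)) {
    writeLines("pop", con)
    rows <- which(ds$population == p)
    for (i in rows) {
      geno <- paste0(fmt(ds$a1[i, ]), fmt(ds$a2[i, ]))
      writeLines(paste0(ds$individuals[i], " ", p, " , ",
                        paste(geno, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a long-format genotype CSV
#'
#' One row per individual x locus with columns `individual`, `population`,
#' `species`, `locus`, `allele1`, `allele2`; alleles empty or `NA` when
#' missing. Semantics match the GENEPOP path: both alleles present or both
#' missing.
#'
#' @param path CSV path.
#' @return a [genotype_dataset()].
#' @export
read_long_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "population", "species", "locus",
            "allele1", "allele2")
  if (!all(need %in% names(df)))
    stop("long CSV must have columns: ", paste(need, collapse = ", "))
  key <- paste(df$individual, df$locus, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate (individual, locus) row: ", d$individual, " / ", d$locus)
  }
  inds <- unique(df$individual)
  loci <- unique(df$locus)
  a1 <- matrix(NA_integer_, length(inds), length(loci))
  a2 <- matrix(NA_integer_, length(inds), length(loci))
  i <- match(df$individual, inds); j <- match(df$locus, loci)
  to_int <- function(x) {
    x[!nzchar(trimws(as.character(x)))] <- NA
    suppressWarnings(as.integer(x))
  }
  a1[cbind(i, j)] <- to_int(df$allele1)
  a2[cbind(i, j)] <- to_int(df$allele2)
  if (any(xor(is.na(a1), is.na(a2))))
    stop("half-missing genotype in long CSV (one allele NA, the other not)")
  first <- !duplicated(df$individual)
  genotype_dataset(a1, a2, inds, df$population[first], df$species[first],
                   loci)
}

#' Write a long-format genotype CSV
#' @param ds a [genotype_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(ds, path) {
  n <- length(ds$individuals); L <- length(ds$loci)
  df <- data.frame(
    individual = rep(ds$individuals, times = L),
    population = rep(ds$population, times = L),
    species = rep(ds$species, times = L),
    locus = rep(ds$loci, each = n),
    allele1 = as.vector(ds$a1),
    allele2 = as.vector(ds$a2))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
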