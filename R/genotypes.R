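#' Genotype dosage matrix with SNP map
#'
#' Container for an `n x m` matrix of allele dosages coded 0/1/2 (the genotype
#' covariates of the marker-effect model) together with its SNP map
#' (identifier, chromosome, 1-based base-pair position) and individual
#' identifiers. Missing dosages are allowed until [impute_and_center()].
#'
#' @param dosages numeric matrix, individuals in rows, SNPs in columns;
#'   non-missing entries must be 0, 1, or 2.
#' @param snp_ids character vector of unique SNP identifiers (length `m`).
#' @param chromosomes chromosome label per SNP (length `m`).
#' @param positions 1-based base-pair position per SNP (length `m`).
#' @param individual_ids unique individual identifiers (length `n`).
#' @return An object of class `GenotypeMatrix`: a list with elements
#'   `dosages`, `snp_ids`, `chromosomes`, `positions`, `individual_ids`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 2, 1, 0), 3, 2),
#'                      snp_ids = c("s1", "s2"), chromosomes = c(1, 1),
#'                      positions = c(100, 200),
#'                      individual_ids = c("a", "b", "c"))
#' dim(g$dosages)
#' @export
genotype_matrix <- function(dosages, snp_ids, chromosomes = NULL,
                            positions = NULL, individual_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages); m <- ncol(dosages)
  snp_ids <- as.character(snp_ids)
  if (length(snp_ids) != m) stopf("snp_ids length %d != %d columns", length(snp_ids), m)
  if (anyDuplicated(snp_ids)) {
    stopf("duplicate SNP ids: %s",
          paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  }
  individual_ids <- as.character(individual_ids %||% seq_len(n))
  if (length(individual_ids) != n) stopf("individual_ids length != n")
  if (anyDuplicated(individual_ids)) stopf("duplicate individual ids")
  chromosomes <- as.character(chromosomes %||% rep("1", m))
  if (length(chromosomes) != m) stopf("chromosomes length != m")
  positions <- as.integer(positions %||% seq_len(m))
  if (length(positions) != m) stopf("positions length != m")
  bad <- which(!is.na(dosages) & !(dosages %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stopf("dosage not in {0,1,2,NA} at row %s (individual %s), column %s (SNP %s): value %s",
          bad[1, 1], individual_ids[bad[1, 1]], bad[1, 2], snp_ids[bad[1, 2]],
          format(dosages[bad[1, , drop = FALSE]]))
  }
  dimnames(dosages) <- list(individual_ids, snp_ids)
  structure(list(dosages = dosages, snp_ids = snp_ids,
                 chromosomes = chromosomes, positions = positions,
                 individual_ids = individual_ids),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d SNPs on %d chromosome(s); %d missing dosage(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$chromosomes)),
              sum(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$dosages)

#' Read genotypes from delimited text or PLINK-style text files
#'
#' For `format = "csv"` the file is comma- or tab-delimited with a header row
#' of SNP ids and the individual id in the first column; optional columns are
#' not supported. The SNP map (chromosome/position) may be supplied as a
#' separate map file via `map`; otherwise SNPs are placed consecutively on a
#' single chromosome. For `format = "plink"`, `path` names a `.ped` file whose
#' sibling `.map` file provides the SNP map; biallelic genotypes are converted
#' to dosages of the minor allele (frequency computed from the data) and
#' `0 0` becomes missing.
#'
#' @param path path to the genotype file (`.csv`/`.tsv`, or `.ped`).
#' @param format `"csv"` (default) or `"plink"`.
#' @param map optional path to a 4-column PLINK-style map file
#'   (chromosome, snp id, genetic distance, position) used with `format = "csv"`.
#' @return A [genotype_matrix()] object.
#' @seealso [write_genotypes()], [impute_and_center()]
#' @export
read_genotypes <- function(path, format = c("csv", "plink"), map = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    tab <- read_delim_auto(path)
    if (ncol(tab) < 2L) stopf("genotype file needs an id column plus >=1 SNP column")
    ids <- as.character(tab[[1L]])
    dos <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(dos)) {
      nonnum <- which(!vapply(tab[-1L], is.numeric, logical(1)))[1L]
      stopf("non-numeric dosage column '%s'", names(tab)[-1L][nonnum])
    }
    snp_ids <- colnames(tab)[-1L]
    chrom <- NULL; pos <- NULL
    if (!is.null(map)) {
      mp <- read.table(map, header = FALSE, stringsAsFactors = FALSE)
      if (ncol(mp) < 4L) stopf("map file must have 4 columns (chr, id, cM, pos)")
      idx <- match(snp_ids, as.character(mp[[2L]]))
      if (anyNA(idx)) stopf("SNP ids missing from map: %s",
                            paste(snp_ids[is.na(idx)][1:min(5, sum(is.na(idx)))], collapse = ", "))
      chrom <- as.character(mp[[1L]])[idx]
      pos <- as.integer(mp[[4L]])[idx]
    }
    return(genotype_matrix(dos, snp_ids, chrom, pos, ids))
  }
  read_plink_text(path)
}

# PLINK text pair (.ped/.map), biallelic loci only; dosage of the minor allele.
read_plink_text <- function(ped_path) {
  map_path <- sub("\\.ped$", ".map", ped_path)
  if (identical(map_path, ped_path)) map_path <- paste0(ped_path, ".map")
  if (!file.exists(ped_path)) stopf("file not found: %s", ped_path)
  if (!file.exists(map_path)) stopf("map file not found: %s", map_path)
  mp <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  m <- nrow(mp)
  ped <- read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(ped) != 6L + 2L * m) {
    stopf("ped file has %d columns; expected %d (6 + 2 x %d SNPs)",
          ncol(ped), 6L + 2L * m, m)
  }
  n <- nrow(ped)
  ids <- ped[[2L]]
  dos <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    a1 <- ped[[6L + 2L * j - 1L]]
    a2 <- ped[[6L + 2L * j]]
    alle <- c(a1, a2)
    alle[alle == "0"] <- NA
    lev <- sort(unique(alle[!is.na(alle)]))
    if (length(lev) > 2L) stopf("SNP %s has >2 alleles", mp[[2L]][j])
    if (length(lev) == 0L) stopf("SNP %s has all genotypes missing", mp[[2L]][j])
    # minor allele = less frequent; ties broken by sort order
    cnt <- table(factor(alle, levels = lev))
    minor <- lev[which.min(cnt)]
    miss <- is.na(a1) | a1 == "0" | is.na(a2) | a2 == "0"
    dos[, j] <- (a1 == minor) + (a2 == minor)
    dos[miss, j] <- NA_real_
  }
  genotype_matrix(dos, as.character(mp[[2L]]), as.character(mp[[1L]]),
                  as.integer(mp[[4L]]), ids)
}

#' Write genotypes to a delimited file (with optional map file)
#'
#' Inverse of [read_genotypes()] for the CSV dialect: header row of SNP ids,
#' first column `id`, missing dosages written as `NA`.
#'
#' @param g a [genotype_matrix()].
#' @param path output path for the dosage table.
#' @param map optional output path for a 4-column PLINK-style map file.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, map = NULL, sep = ",") {
  stopifnot(inherits(g, "GenotypeMatrix"))
  tab <- data.frame(id = g$individual_ids, g$dosages, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE, na = "NA")
  if (!is.null(map)) {
    write.table(data.frame(g$chromosomes, g$snp_ids, 0, g$positions),
                map, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Impute missing dosages and mean-center genotype columns
#'
#' Missing dosages are replaced by the column mean of the non-missing entries,
#' then every column is centered to mean zero. Centering decouples the overall
#' mean from allele frequencies and is the conventional preparation for
#' whole-genome regression; the stored column means let validation individuals
#' be centered identically at prediction time.
#'
#' @param g a [genotype_matrix()], or a bare dosage matrix.
#' @return A numeric matrix of class `centered_genotypes` with attribute
#'   `centers` (the column means used) and column names equal to the SNP ids.
#' @examples
#' g <- genotype_matrix(matrix(c(0, NA, 2), 3, 1), "s1")
#' X <- impute_and_center(g)
#' attr(X, "centers")  # 1
#' @export
impute_and_center <- function(g) {
  dos <- if (inherits(g, "GenotypeMatrix")) g$dosages else as.matrix(g)
  snp_ids <- colnames(dos) %||% paste0("snp", seq_len(ncol(dos)))
  all_missing <- which(colSums(!is.na(dos)) == 0L)
  if (length(all_missing) > 0L) {
    stopf("SNP(s) with all dosages missing: %s",
          paste(snp_ids[all_missing], collapse = ", "))
  }
  centers <- colMeans(dos, na.rm = TRUE)
  X <- sweep(dos, 2L, centers)
  if (anyNA(X)) X[is.na(X)] <- 0  # imputed value minus mean
  # re-center exactly (imputation shifts the mean only if values were missing)
  adj <- colMeans(X)
  if (max(abs(adj)) > 0) X <- sweep(X, 2L, adj)
  centers <- centers + adj
  structure(X, centers = centers, class = c("centered_genotypes", class(X)))
}
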