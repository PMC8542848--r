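#' Phenotype table
#'
#' An `n x t` matrix of phenotypic values for one or more traits, with
#' individual identifiers. Rows containing missing values are dropped with a
#' warning at construction: the hierarchical model has no missing-phenotype
#' machinery, so preparation must yield complete records.
#'
#' @param values numeric matrix or data frame, individuals in rows, traits in
#'   columns.
#' @param trait_names trait labels (default taken from column names).
#' @param individual_ids individual identifiers (default row names or 1..n).
#' @return An object of class `PhenotypeTable` with elements `values`
#'   (complete `n x t` matrix), `trait_names`, `individual_ids`.
#' @export
phenotype_table <- function(values, trait_names = NULL, individual_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  t <- ncol(values)
  if (t < 1L) stopf("at least one trait is required")
  trait_names <- as.character(trait_names %||% colnames(values) %||% paste0("trait", seq_len(t)))
  if (length(trait_names) != t) stopf("trait_names length != number of traits")
  individual_ids <- as.character(individual_ids %||% rownames(values) %||% seq_len(nrow(values)))
  if (length(individual_ids) != nrow(values)) stopf("individual_ids length != rows")
  if (anyDuplicated(individual_ids)) stopf("duplicate individual ids in phenotypes")
  keep <- complete.cases(values)
  if (!all(keep)) {
    warnf("dropping %d individual(s) with missing phenotypes", sum(!keep))
    values <- values[keep, , drop = FALSE]
    individual_ids <- individual_ids[keep]
  }
  dimnames(values) <- list(individual_ids, trait_names)
  structure(list(values = values, trait_names = trait_names,
                 individual_ids = individual_ids),
            class = "PhenotypeTable")
}

#' @export
print.PhenotypeTable <- function(x, ...) {
  cat(sprintf("PhenotypeTable: %d individuals x %d trait(s) [%s]\n",
              nrow(x$values), length(x$trait_names),
              paste(x$trait_names, collapse = ", ")))
  invisible(x)
}

#' Read a phenotype table from delimited text
#'
#' First column individual id, remaining columns traits; comma- or
#' tab-delimited with a header row; missing token `NA`.
#'
#' @param path file path.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  tab <- read_delim_auto(path)
  if (ncol(tab) < 2L) stopf("phenotype file needs an id column plus >=1 trait column")
  phenotype_table(as.matrix(tab[, -1L, drop = FALSE]),
                  trait_names = names(tab)[-1L],
                  individual_ids = as.character(tab[[1L]]))
}

#' Write a phenotype table to a delimited file
#'
#' @param ph a [phenotype_table()].
#' @param path output path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(ph, path, sep = ",") {
  stopifnot(inherits(ph, "PhenotypeTable"))
  tab <- data.frame(id = ph$individual_ids, ph$values, check.names = FALSE)
  write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
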