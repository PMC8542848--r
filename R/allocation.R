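#' SNP class allocation
#'
#' Maps class labels to sets of marker indices. Classes may overlap: a marker
#' allocated to several classes contributes one effect term per class in the
#' multi-class model. Indices are 1-based column indices into the genotype
#' matrix.
#'
#' @param members named list of integer vectors of marker indices; names are
#'   the class labels (order is kept and defines the sampler's update order).
#' @param m total number of markers the indices refer to.
#' @return An object of class `ClassAllocation` with elements `classes`
#'   (labels), `members` (named list of sorted unique index vectors), and `m`.
#' @examples
#' class_allocation(list(A = c(1, 2), B = 3), m = 3)
#' @export
class_allocation <- function(members, m) {
  if (!is.list(members) || is.null(names(members)) || any(names(members) == ""))
    stopf("members must be a named list of index vectors")
  if (anyDuplicated(names(members))) stopf("duplicate class labels")
  members <- lapply(members, function(ix) sort(unique(as.integer(ix))))
  m <- as.integer(m)
  for (cl in names(members)) {
    ix <- members[[cl]]
    if (length(ix) == 0L) stopf("class '%s' is empty", cl)
    if (any(ix < 1L | ix > m)) stopf("class '%s' has indices outside 1..%d", cl, m)
  }
  structure(list(classes = names(members), members = members, m = m),
            class = "ClassAllocation")
}

#' @export
print.ClassAllocation <- function(x, ...) {
  sizes <- vapply(x$members, length, integer(1))
  cat(sprintf("ClassAllocation: %d class(es) over %d markers (%d effect terms)\n",
              length(x$classes), x$m, sum(sizes)))
  for (cl in x$classes) cat(sprintf("  %s: %d\n", cl, sizes[[cl]]))
  invisible(x)
}

#' Read a SNP class map
#'
#' Two-column delimited file (`snp_id`, `class_label`) with a header row.
#' Duplicate (snp, class) rows are collapsed; a SNP listed under two labels
#' is placed in both classes (overlapping allocation).
#'
#' @param path file path.
#' @param g the [genotype_matrix()] the SNP ids must resolve against.
#' @return A [class_allocation()].
#' @export
read_class_map <- function(path, g) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  tab <- read_delim_auto(path)
  if (ncol(tab) < 2L) stopf("class map needs two columns (snp_id, class_label)")
  snp <- as.character(tab[[1L]]); lab <- as.character(tab[[2L]])
  idx <- match(snp, g$snp_ids)
  if (anyNA(idx)) {
    unknown <- unique(snp[is.na(idx)])
    stopf("class map names SNP id(s) absent from the genotype map: %s",
          paste(utils::head(unknown, 10L), collapse = ", "))
  }
  members <- lapply(split(idx, factor(lab, levels = unique(lab))), unique)
  class_allocation(members, ncol(g$dosages))
}

#' Write a class allocation as a two-column class-map file
#'
#' @param alloc a [class_allocation()].
#' @param g the [genotype_matrix()] supplying SNP ids.
#' @param path output path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_class_map <- function(alloc, g, path, sep = ",") {
  stopifnot(inherits(alloc, "ClassAllocation"), inherits(g, "GenotypeMatrix"))
  rows <- do.call(rbind, lapply(alloc$classes, function(cl) {
    data.frame(snp_id = g$snp_ids[alloc$members[[cl]]], class_label = cl,
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build SNP classes from a genome-annotation table
#'
#' One class per distinct feature type; SNPs carrying several feature types
#' appear in every matching class; SNPs with no annotation row fall into the
#' absorbing class `"intergenic"`.
#'
#' @param ann data frame (or path to a two-column delimited file) with columns
#'   `snp_id` and `feature_type`.
#' @param g the [genotype_matrix()] the SNP ids must resolve against.
#' @param default_class label of the absorbing class for unannotated SNPs.
#' @return A [class_allocation()].
#' @export
allocate_by_annotation <- function(ann, g, default_class = "intergenic") {
  stopifnot(inherits(g, "GenotypeMatrix"))
  if (is.character(ann) && length(ann) == 1L) ann <- read_delim_auto(ann)
  if (is.null(ann) || nrow(ann) == 0L) {
    warnf("empty annotation table: all %d SNPs allocated to '%s'",
          ncol(g$dosages), default_class)
    return(class_allocation(setNames(list(seq_len(ncol(g$dosages))), default_class),
                            ncol(g$dosages)))
  }
  snp <- as.character(ann[[1L]]); type <- as.character(ann[[2L]])
  idx <- match(snp, g$snp_ids)
  if (anyNA(idx)) {
    stopf("annotation names SNP id(s) absent from the genotype map: %s",
          paste(utils::head(unique(snp[is.na(idx)]), 10L), collapse = ", "))
  }
  members <- lapply(split(idx, factor(type, levels = unique(type))), unique)
  rest <- setdiff(seq_len(ncol(g$dosages)), unlist(members))
  if (length(rest) > 0L) {
    members[[default_class]] <- sort(unique(c(members[[default_class]], rest)))
  }
  class_allocation(members, ncol(g$dosages))
}

#' Build one SNP class per chromosome
#'
#' Allocates all SNPs on the same chromosome to the same class; the classes
#' partition the markers.
#'
#' @param g a [genotype_matrix()] with chromosome labels.
#' @return A [class_allocation()] with one class per distinct chromosome,
#'   labelled `chr<label>`.
#' @export
allocate_by_chromosome <- function(g) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  chrom <- g$chromosomes
  members <- split(seq_along(chrom), factor(chrom, levels = unique(chrom)))
  names(members) <- paste0("chr", names(members))
  class_allocation(members, ncol(g$dosages))
}

#' Two-class allocation around a focal SNP set
#'
#' Splits the markers into a `"focal"` class (e.g. SNPs near a GWAS signal or
#' on one chromosome) and a `"rest"` class holding the complement — the
#' 2-class analysis used to concentrate prior variance on a region of
#' interest.
#'
#' @param g a [genotype_matrix()].
#' @param focal character vector of SNP ids forming the focal class; must be a
#'   non-empty proper subset of the SNP ids.
#' @return A [class_allocation()] with disjoint, exhaustive classes `focal`
#'   and `rest`.
#' @export
allocate_two_class <- function(g, focal) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  focal <- unique(as.character(focal))
  idx <- match(focal, g$snp_ids)
  if (anyNA(idx)) {
    stopf("focal SNP id(s) absent from the genotype map: %s",
          paste(utils::head(focal[is.na(idx)], 10L), collapse = ", "))
  }
  m <- ncol(g$dosages)
  if (length(idx) == 0L) stopf("focal set is empty")
  if (length(idx) == m) stopf("focal set equals all SNPs; the model degenerates to one class")
  class_allocation(list(focal = idx, rest = setdiff(seq_len(m), idx)), m)
}
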