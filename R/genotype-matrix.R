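# Genotype matrix container: isolates x loci allele labels with population
# tags. Heterozygous entries are "a/b" cells; NA marks failed amplifications.

#' Construct a multilocus genotype matrix
#'
#' The central container for multilocus haploid genotypes: one row per
#' isolate, one column per locus, allele labels as character strings.
#' Heteroplasmic (heterozygous) entries are unordered allele pairs encoded
#' `"a/b"` with `a < b`; missing data are `NA`.
#'
#' @param data a data.frame with columns `isolate_id`, `population`, and one
#'   column per locus, or a matrix/data.frame of allele labels to which ids
#'   and populations are attached.
#' @param isolate_id,population optional vectors overriding/supplying the id
#'   and population columns.
#' @return an object of class `genotype_matrix` (a data.frame with attribute
#'   `loci`).
#' @examples
#' gm <- genotype_matrix(data.frame(
#'   isolate_id = c("i1", "i2"), population = "p1",
#'   locA = c("a", "b"), locB = c("x", "x")))
#' loci(gm)
#' @export
genotype_matrix <- function(data, isolate_id = NULL, population = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!is.null(isolate_id)) data$isolate_id <- as.character(isolate_id)
  if (!is.null(population)) data$population <- as.character(population)
  if (is.null(data$isolate_id))
    data$isolate_id <- sprintf("iso%03d", seq_len(nrow(data)))
  if (is.null(data$population)) data$population <- "pop1"
  loci <- setdiff(names(data), c("isolate_id", "population"))
  if (!length(loci)) stop("genotype matrix needs at least one locus column")
  dup <- data$isolate_id[duplicated(data$isolate_id)]
  if (length(dup))
    stop("duplicate isolate ids: ", paste(unique(dup), collapse = ", "))
  data <- data[c("isolate_id", "population", loci)]
  for (l in loci) data[[l]] <- normalize_cell(as.character(data[[l]]))
  rownames(data) <- NULL
  structure(data, loci = loci, class = c("genotype_matrix", "data.frame"))
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
loci <- function(x) attr(x, "loci")

# allele labels as plain character matrix (isolates x loci)
allele_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x)[, loci(x), drop = FALSE])
  rownames(m) <- x$isolate_id
  m
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Multilocus genotype matrix: %d isolates, %d loci, %d population(s)\n",
              nrow(x), length(loci(x)), length(unique(x$population))))
  nhet <- sum(vapply(loci(x), function(l) sum(is_het_cell(x[[l]])), integer(1)))
  if (nhet > 0) cat(sprintf("  heteroplasmic entries: %d\n", nhet))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
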