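# Shared helpers: IUPAC two-base ambiguity codes, sequence superposition,
# heterozygous-cell encoding.

.IUPAC2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
.BASES <- c("A", "C", "G", "T")

#' Two-base IUPAC ambiguity code
#'
#' @param b1,b2 single bases among A, C, G, T; order is irrelevant.
#' @return the IUPAC symbol for the unordered base pair (e.g. `"R"` for A/G).
#' @keywords internal
iupac_code <- function(b1, b2) {
  key <- paste(sort(c(toupper(b1), toupper(b2))), collapse = "")
  code <- .IUPAC2[key]
  if (is.na(code)) stop("not a pair of distinct bases: ", b1, "/", b2)
  unname(code)
}

#' Bases encoded by a two-base IUPAC ambiguity symbol
#' @param code a single character among M, R, W, S, Y, K.
#' @return character vector of the two bases, alphabetical.
#' @keywords internal
iupac_bases <- function(code) {
  key <- names(.IUPAC2)[match(toupper(code), .IUPAC2)]
  if (is.na(key)) stop("not a two-base ambiguity code: ", code)
  strsplit(key, "")[[1]]
}

is_ambiguity <- function(ch) toupper(ch) %in% .IUPAC2

seq_chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]

#' Site-wise superposition of two equal-length sequences
#'
#' Identical sites keep their base; differing sites become the matching
#' two-base IUPAC ambiguity code. This is the sequence a chromatogram of a
#' two-haplotype mixture reads as.
#'
#' @param s1,s2 equal-length base strings (A/C/G/T only).
#' @return a single string, possibly containing ambiguity codes.
#' @export
superpose_seqs <- function(s1, s2) {
  a <- seq_chars(s1)
  b <- seq_chars(s2)
  if (length(a) != length(b)) stop("sequences differ in length")
  out <- a
  d <- which(a != b)
  for (i in d) out[i] <- iupac_code(a[i], b[i])
  paste(out, collapse = "")
}

#' Encode / test a heterozygous genotype cell
#'
#' Heterozygous entries are unordered allele pairs stored as `"a/b"` with
#' `a < b` in lexicographic order.
#' @param a,b allele labels.
#' @return `het_cell()`: the canonical cell string. `is_het_cell()`: logical.
#' @export
het_cell <- function(a, b) {
  paste(sort(c(as.character(a), as.character(b))), collapse = "/")
}

#' @rdname het_cell
#' @param x character vector of genotype cells.
#' @export
is_het_cell <- function(x) !is.na(x) & grepl("/", x, fixed = TRUE)

het_alleles <- function(x) strsplit(x, "/", fixed = TRUE)

# canonicalise a possibly mis-ordered het cell; "" -> NA
normalize_cell <- function(x) {
  x[!is.na(x) & !nzchar(x)] <- NA_character_
  i <- which(is_het_cell(x))
  if (length(i)) {
    x[i] <- vapply(het_alleles(x[i]), function(p) paste(sort(p), collapse = "/"),
                   character(1))
  }
  x
}
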