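# Plain-text readers and writers: genotype TSV, trace TSV, Ct TSV,
# haplotype FASTA, and the packaged COX3 haplotype survey fixture.
# 1-based site coordinates throughout; canonical files round-trip
# byte-identically.

#' Read / write a genotype table
#'
#' TSV with header columns `isolate_id`, `population`, then one column per
#' locus. Heterozygous cells are `"a/b"` (normalised so `a < b`
#' lexicographically on read); empty cells are missing.
#'
#' @param path file path.
#' @return `read_genotype_table()`: a [genotype_matrix()].
#' @export
read_genotype_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, na.strings = "")
  need <- c("isolate_id", "population")
  if (!all(need %in% names(df)))
    stop("genotype table needs columns isolate_id and population (",
         path, ")")
  dup <- df$isolate_id[duplicated(df$isolate_id)]
  if (length(dup)) {
    line <- which(duplicated(df$isolate_id))[1] + 1L
    stop("duplicate isolate id '", dup[1], "' at line ", line)
  }
  genotype_matrix(df)
}

#' @rdname read_genotype_table
#' @param gm a [genotype_matrix()].
#' @export
write_genotype_table <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  utils::write.table(as.data.frame(gm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a trace-peak table
#'
#' TSV with columns `pos` (1-based), `A`, `C`, `G`, `T` (non-negative peak
#' heights).
#'
#' @param path file path.
#' @return `read_trace_table()`: a `trace_profile` data.frame.
#' @export
read_trace_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("pos", .BASES) %in% names(df)))
    stop("trace table needs columns pos, A, C, G, T (", path, ")")
  if (any(df[, .BASES] < 0)) stop("negative peak height in ", path)
  structure(df[c("pos", .BASES)],
            class = c("trace_profile", "data.frame"))
}

#' @rdname read_trace_table
#' @param profile a `trace_profile`.
#' @export
write_trace_table <- function(profile, path) {
  utils::write.table(as.data.frame(profile)[c("pos", .BASES)], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a Ct panel table
#'
#' TSV with columns `gene`, `length_bp`, `is_reference`, then `ct_1`,
#' `ct_2`, ... (unequal replicate counts are NA-padded).
#'
#' @param path file path.
#' @return `read_ct_table()`: a [ct_panel()].
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("gene", "length_bp", "is_reference")
  if (!all(need %in% names(df)))
    stop("Ct table needs columns gene, length_bp, is_reference (", path, ")")
  ctcols <- grep("^ct_\\d+$", names(df), value = TRUE)
  if (!length(ctcols)) stop("no ct_<i> replicate columns in ", path)
  ct <- lapply(seq_len(nrow(df)), function(i) {
    v <- as.numeric(df[i, ctcols])
    v[!is.na(v)]
  })
  ct_panel(df$gene, df$length_bp, ct, as.logical(df$is_reference))
}

#' @rdname read_ct_table
#' @param panel a [ct_panel()].
#' @export
write_ct_table <- function(panel, path) {
  stopifnot(inherits(panel, "ct_panel"))
  k <- max(vapply(panel$ct, length, integer(1)))
  ctm <- t(vapply(panel$ct, function(x) c(x, rep(NA, k - length(x))),
                  numeric(k)))
  df <- data.frame(gene = panel$gene, length_bp = panel$length_bp,
                   is_reference = panel$is_reference, ctm,
                   check.names = FALSE)
  names(df)[-(1:3)] <- sprintf("ct_%d", seq_len(k))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read / write haplotype sequences as FASTA
#'
#' One record per haplotype; the record id is the haplotype label. IUPAC
#' ambiguity codes are allowed (consensus sequences of heteroplasmic
#' isolates).
#'
#' @param path file path.
#' @return `read_haplotype_fasta()`: named character vector of sequences.
#' @export
read_haplotype_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_haplotype_fasta
#' @param seqs named character vector of sequences.
#' @export
write_haplotype_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a COX3-style haplotype survey fixture
#'
#' TSV with columns `population`, `n_isolates` (isolates successfully typed
#' at the locus), `haplotype_counts` (copy counts in the
#' two-copies-per-isolate convention, e.g. `"1:5;6:9;9:12;10:2"`) and
#' `het_genotypes` (`"1/6;4/12"`, empty when none). Populations whose
#' counts do not sum to `2 * n_isolates` are reported with a warning, never
#' silently fixed.
#'
#' @param path file path; defaults to the packaged survey of COX3 haplotype
#'   counts and heteroplasmic genotypes among 284 *Thelephora ganbajun*
#'   isolates from 27 populations in Yunnan.
#' @return a [haplotype_catalog()].
#' @export
read_haplotype_survey <- function(path = system.file(
    "extdata", "cox3_haplotype_survey.tsv", package = "mitohet")) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, na.strings = NULL)
  need <- c("population", "n_isolates", "haplotype_counts", "het_genotypes")
  if (!nrow(df) || !all(need %in% names(df)))
    stop("malformed haplotype survey fixture: ", path)
  counts <- list()
  hets <- data.frame(population = character(0), hap1 = character(0),
                     hap2 = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    p <- df$population[i]
    entries <- strsplit(df$haplotype_counts[i], ";", fixed = TRUE)[[1]]
    entries <- entries[nzchar(trimws(entries))]
    if (!length(entries)) stop("population ", p, ": no haplotype counts")
    kv <- strsplit(trimws(entries), ":", fixed = TRUE)
    if (any(lengths(kv) != 2))
      stop("population ", p, ": malformed haplotype_counts entry")
    counts[[p]] <- stats::setNames(
      as.numeric(vapply(kv, `[`, character(1), 2)),
      vapply(kv, `[`, character(1), 1))
    g <- df$het_genotypes[i]
    if (!is.na(g) && nzchar(trimws(g))) {
      prs <- strsplit(trimws(strsplit(g, ";", fixed = TRUE)[[1]]), "/",
                      fixed = TRUE)
      for (pr in prs) {
        if (length(pr) != 2)
          stop("population ", p, ": malformed het genotype")
        hets <- rbind(hets, data.frame(population = p, hap1 = pr[1],
                                       hap2 = pr[2], stringsAsFactors = FALSE))
      }
    }
  }
  sizes <- stats::setNames(as.integer(df$n_isolates), df$population)
  haplotype_catalog(counts, sizes = sizes, hets = hets)
}

#' Read the packaged qPCR Ct survey
#'
#' Replicate-mean threshold cycles for five amplicons (12S rRNA, COX1
#' exon 3, the COX1 alpha and beta intron fragments, and the nuclear
#' beta-tubulin reference) in six *T. ganbajun* isolates, as a list of
#' single-replicate [ct_panel()]s keyed by isolate. Because only the means
#' are carried, [summarize_panel()] on these panels uses the mean-Ct path
#' (SD omitted).
#'
#' @param path fixture path; defaults to the packaged table.
#' @return named list of [ct_panel()] objects.
#' @export
read_ct_survey <- function(path = system.file(
    "extdata", "qpcr_ct_survey.tsv", package = "mitohet")) {
  df <- utils::read.delim(path, check.names = FALSE)
  lapply(split(df, df$isolate), function(d)
    ct_panel(d$gene, d$length_bp, as.list(d$ct_mean),
             as.logical(d$is_reference)))
}
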