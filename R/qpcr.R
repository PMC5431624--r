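# Relative per-cell copy number from quantitative PCR threshold cycles.
# The reference is a single-copy nuclear gene in a dikaryotic cell, hence
# fixed at two copies per cell; amplification efficiency is idealised at
# exactly 2 per cycle, so at a common fluorescence threshold
#   Ln * Nn * 2^ctn = Lm * Nm * 2^ctm   with Nn = 2,
# giving Nm = 2 * Ln * 2^ctn / (Lm * 2^ctm).

#' Construct a qPCR Ct panel
#'
#' @param genes character vector of gene names.
#' @param lengths amplicon lengths in bp (> 0).
#' @param ct list of numeric replicate Ct vectors (one per gene, each with
#'   >= 1 positive value), or a matrix with one row per gene.
#' @param is_reference logical; exactly one gene must be the nuclear
#'   reference.
#' @param seed optional provenance seed recorded on the object.
#' @return an object of class `ct_panel`.
#' @export
ct_panel <- function(genes, lengths, ct, is_reference, seed = NULL) {
  genes <- as.character(genes)
  if (is.matrix(ct)) ct <- lapply(seq_len(nrow(ct)), function(i) ct[i, ])
  stopifnot(length(genes) == length(lengths),
            length(genes) == length(ct),
            length(genes) == length(is_reference))
  ct <- lapply(ct, function(x) as.numeric(x[!is.na(x)]))
  if (any(lengths <= 0)) stop("amplicon lengths must be positive")
  if (any(vapply(ct, length, integer(1)) < 1))
    stop("every gene needs at least one replicate Ct")
  if (any(unlist(ct) <= 0)) stop("Ct values must be positive")
  if (sum(is_reference) != 1)
    stop("panel needs exactly one nuclear reference gene")
  structure(list(gene = genes, length_bp = as.numeric(lengths), ct = ct,
                 is_reference = as.logical(is_reference), seed = seed),
            class = "ct_panel")
}

#' @export
print.ct_panel <- function(x, ...) {
  cat(sprintf("qPCR Ct panel: %d genes (reference: %s)\n",
              length(x$gene), x$gene[x$is_reference]))
  for (i in seq_along(x$gene))
    cat(sprintf("  %-12s %4g bp  Ct: %s\n", x$gene[i], x$length_bp[i],
                paste(sprintf("%.2f", x$ct[[i]]), collapse = ", ")))
  invisible(x)
}

#' Relative mitochondrial copy number per cell
#'
#' `Nm = (2 * Ln * 2^ctn) / (Lm * 2^ctm)`: the target's per-cell copy
#' number relative to a two-copy nuclear reference, correcting for amplicon
#' length. Strictly increasing in `ctn`, strictly decreasing in `ctm`, and
#' invariant under a common shift of both Ct values.
#'
#' @param ctn reference (nuclear) threshold cycle.
#' @param ctm target (mitochondrial) threshold cycle.
#' @param Ln,Lm reference and target amplicon lengths in bp (> 0).
#' @return copies per cell (vectorised).
#' @examples
#' relative_copy_number(ctn = 17.80, ctm = 11.33, Ln = 140, Lm = 165)
#' @export
relative_copy_number <- function(ctn, ctm, Ln, Lm) {
  if (any(Ln <= 0) || any(Lm <= 0)) stop("amplicon lengths must be positive")
  if (any(ctn <= 0) || any(ctm <= 0)) stop("Ct values must be positive")
  (2 * Ln / Lm) * 2^(ctn - ctm)
}

#' Summarise a Ct panel into per-gene copy numbers
#'
#' When the target and the reference have the same number of replicates,
#' replicate `i` of the target is paired with replicate `i` of the reference,
#' a copy number is computed per replicate and reported as mean and SD
#' (`NA` for a single replicate). When replicate counts differ the copy
#' number is computed once from the mean Ct values and the SD is omitted
#' (`NA`).
#'
#' @param panel a [ct_panel()].
#' @return data.frame of class `copy_number_summary` with columns `gene`,
#'   `copies`, `sd`, `n_reps`.
#' @export
summarize_panel <- function(panel) {
  stopifnot(inherits(panel, "ct_panel"))
  ref <- which(panel$is_reference)
  if (!length(ref)) stop("no reference row in panel")
  ctn <- panel$ct[[ref]]
  Ln <- panel$length_bp[ref]
  targets <- which(!panel$is_reference)
  rows <- lapply(targets, function(i) {
    ctm <- panel$ct[[i]]
    if (length(ctm) == length(ctn)) {
      per_rep <- relative_copy_number(ctn, ctm, Ln, panel$length_bp[i])
      data.frame(gene = panel$gene[i], copies = mean(per_rep),
                 sd = if (length(per_rep) > 1) stats::sd(per_rep)
                      else NA_real_,
                 n_reps = length(per_rep), stringsAsFactors = FALSE)
    } else {
      data.frame(gene = panel$gene[i],
                 copies = relative_copy_number(mean(ctn), mean(ctm), Ln,
                                               panel$length_bp[i]),
                 sd = NA_real_, n_reps = NA_integer_,
                 stringsAsFactors = FALSE)
    }
  })
  structure(do.call(rbind, rows),
            class = c("copy_number_summary", "data.frame"))
}

#' @export
print.copy_number_summary <- function(x, ...) {
  cat("Relative copy numbers per cell (vs 2-copy nuclear reference):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-12s %s%s\n", x$gene[i], format(x$copies[i], digits = 4),
                if (is.na(x$sd[i])) "  (sd omitted)"
                else sprintf(" ± %s", format(x$sd[i], digits = 3))))
  invisible(x)
}

#' Major/minor copy-number ratio of two targets
#'
#' @param result_a,result_b either numeric copy numbers or one-row subsets
#'   of a [summarize_panel()] result.
#' @param labels labels for the two targets (defaults to gene names when
#'   rows are supplied, else `"a"`/`"b"`). Ties are broken to the first
#'   label.
#' @return list with `ratio` (`max/min`, >= 1) and `major` (label of the
#'   more abundant type).
#' @export
major_minor_ratio <- function(result_a, result_b, labels = NULL) {
  pick <- function(r, default) {
    if (is.numeric(r)) list(n = r, lab = default)
    else list(n = r$copies, lab = r$gene)
  }
  a <- pick(result_a, "a"); b <- pick(result_b, "b")
  if (!is.null(labels)) { a$lab <- labels[1]; b$lab <- labels[2] }
  if (a$n <= 0 || b$n <= 0) stop("copy numbers must be positive")
  if (a$n >= b$n) list(ratio = a$n / b$n, major = a$lab)
  else list(ratio = b$n / a$n, major = b$lab)
}
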