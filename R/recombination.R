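# Multilocus clonality / recombination inference on haploid genotypes:
# index of association (IA) and rbarD with an allele-shuffling permutation
# null, pairwise phylogenetic compatibility (generalised four-gamete test)
# with PcP, and clone correction.
#
# Conventions (Agapow & Burt / Multilocus):
#   d_j(a, b)  per-locus mismatch indicator over isolate pairs
#   V_O        population variance (1/n_pairs denominator) of the summed
#              mismatch distance over pairs
#   V_E = sum_j var_j, with var_j the population variance of d_j
#   IA = V_O / V_E - 1
#   rbarD = (V_O - V_E) / (2 * sum_{j<k} sqrt(var_j * var_k))
# Under linkage equilibrium the per-locus mismatches are independent, so
# V_O ~ V_E and IA ~ 0; complete clonal linkage drives rbarD to 1.

# heterozygous entries carry no single haplotype: blank them (default
# handling; phase with em_phase first to keep those isolates)
.drop_het_entries <- function(m) {
  i <- is_het_cell(m)
  if (any(i)) {
    message(sum(i), " heteroplasmic entr", if (sum(i) == 1) "y" else "ies",
            " excluded from recombination testing (phase first to keep them)")
    m[i] <- NA_character_
  }
  m
}

#' Multilocus mismatch distance between two genotype rows
#'
#' Number of loci at which two isolates carry different alleles, over the
#' loci non-missing in both. `NA` (with a warning) when the rows share no
#' scored locus.
#'
#' @param g1,g2 character vectors of allele labels over the same loci.
#' @return integer count (or `NA`).
#' @export
mismatch_distance <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("rows cover different loci")
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) {
    warning("no shared non-missing loci; distance undefined")
    return(NA_integer_)
  }
  sum(g1[ok] != g2[ok])
}

# per-locus pairwise mismatch indicators as a pairs x loci matrix
# (NA where either isolate is missing at the locus)
.pair_mismatches <- function(m) {
  n <- nrow(m)
  ut <- upper.tri(matrix(0, n, n))
  sapply(seq_len(ncol(m)), function(j) {
    a <- m[, j]
    d <- outer(a, a, "!=")[ut]  # NA propagates from missing cells
    as.numeric(d)
  })
}

.pop_var <- function(x) mean(x^2) - mean(x)^2

#' Index of association and rbarD
#'
#' The index of association compares the variance over isolate pairs of the
#' multilocus mismatch distance with its expectation under free
#' recombination (the sum of the per-locus variances): `IA = V_O/V_E - 1`.
#' `rbarD` rescales the covariance excess by its maximum,
#' `(V_O - V_E) / (2 * sum_{j<k} sqrt(var_j var_k))`, making values
#' comparable across locus counts and bounded by \[-1, 1\]. All variances
#' use the population (1/n_pairs) denominator. Missing cells are handled by
#' pairwise deletion. Heteroplasmic entries are excluded.
#'
#' @param gm a [genotype_matrix()] with >= 2 isolates.
#' @param variance `"population"` (default, the Multilocus convention) or
#'   `"sample"` (n_pairs - 1 denominator); affects small samples only
#'   through a common factor that cancels in `IA` and `rbarD`, so the
#'   option mainly documents the convention.
#' @return list: `IA`, `rbarD` (`NA` with `defined = FALSE` when the data
#'   are monomorphic, and `NA` for `rbarD` with a single locus), `V_O`,
#'   `V_E`, `n_isolates`, `n_loci`, `n_pairs`, `defined`.
#' @examples
#' gm <- genotype_matrix(data.frame(L1 = c("A","A","a","a"),
#'                                  L2 = c("B","B","b","b")))
#' ia_rbard(gm)  # fully linked two-founder sample: IA = 1, rbarD = 1
#' @export
ia_rbard <- function(gm, variance = c("population", "sample")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  variance <- match.arg(variance)
  m <- .drop_het_entries(allele_matrix(gm))
  n <- nrow(m)
  if (n < 2) stop("need at least 2 isolates")
  D <- .pair_mismatches(m)
  shared <- rowSums(!is.na(D))
  if (any(shared == 0)) {
    warning(sum(shared == 0), " isolate pair(s) share no scored locus; dropped")
  }
  vfun <- if (variance == "population") .pop_var else
    function(x) if (length(x) < 2) 0 else stats::var(x)
  var_j <- apply(D, 2, function(d) vfun(d[!is.na(d)]))
  tot <- rowSums(D, na.rm = TRUE)[shared > 0]
  V_O <- vfun(tot)
  V_E <- sum(var_j)
  defined <- V_E > 0
  IA <- if (defined) V_O / V_E - 1 else NA_real_
  s <- sqrt(var_j)
  denom <- (sum(s)^2 - sum(s^2)) / 2
  rbarD <- if (defined && ncol(m) >= 2 && denom > 0)
    (V_O - V_E) / (2 * denom) else NA_real_
  list(IA = IA, rbarD = rbarD, V_O = V_O, V_E = V_E,
       n_isolates = n, n_loci = ncol(m), n_pairs = sum(shared > 0),
       defined = defined)
}

#' Shuffle alleles within each locus
#'
#' The randomisation behind the permutation null: alleles are independently
#' permuted across isolates within every locus column, so per-locus allele
#' proportions are exactly preserved while all between-locus associations
#' are destroyed (an artificially freely recombining dataset). Missing cells
#' stay missing in place.
#'
#' @param gm a [genotype_matrix()].
#' @param seed integer seed.
#' @return a permuted `genotype_matrix`.
#' @export
permute_matrix <- function(gm, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!is.null(seed)) set.seed(seed)
  out <- gm
  for (l in loci(gm)) {
    v <- out[[l]]
    i <- which(!is.na(v))
    if (length(i) > 1) out[[l]][i] <- v[sample(i)]
  }
  out
}

#' Permutation test of the index of association
#'
#' Compares the observed `IA` with its distribution over `n_perm`
#' within-locus allele shuffles ([permute_matrix()]). Under clonality the
#' observed `IA` exceeds the shuffled values; the one-sided p-value is
#' `(1 + #{permutations with IA >= observed}) / (1 + n_perm)`, which never
#' returns exactly zero.
#'
#' @param gm a [genotype_matrix()].
#' @param n_perm number of permutations (>= 1; 500 is conventional).
#' @param seed integer seed for reproducibility.
#' @return object of class `ia_test`: `IA`, `rbarD`, `p`, `perm_IA`,
#'   `n_perm`, `seed`.
#' @export
ia_test <- function(gm, n_perm = 500L, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- ia_rbard(gm)
  if (!obs$defined) stop("IA undefined on monomorphic data")
  if (!is.null(seed)) set.seed(seed)
  perm_IA <- vapply(seq_len(n_perm), function(b)
    suppressMessages(ia_rbard(permute_matrix(gm)))$IA, numeric(1))
  p <- (1 + sum(perm_IA >= obs$IA, na.rm = TRUE)) / (1 + n_perm)
  structure(list(IA = obs$IA, rbarD = obs$rbarD, p = p, perm_IA = perm_IA,
                 n_perm = as.integer(n_perm), seed = seed,
                 n_isolates = obs$n_isolates, n_loci = obs$n_loci),
            class = "ia_test")
}

#' @export
print.ia_test <- function(x, ...) {
  cat(sprintf("Index of association test (%d isolates, %d loci, %d permutations)\n",
              x$n_isolates, x$n_loci, x$n_perm))
  cat(sprintf("  IA = %.4g, rbarD = %.4g, P(perm IA >= obs) = %.4g%s\n",
              x$IA, x$rbarD, x$p, .stars(x$p)))
  invisible(x)
}

#' Histogram of the permutation null with the observed IA
#' @param x an `ia_test`.
#' @param ... passed to [graphics::hist()].
#' @method plot ia_test
#' @export
plot.ia_test <- function(x, ...) {
  graphics::hist(x$perm_IA, xlim = range(c(x$perm_IA, x$IA)),
                 main = "IA permutation null", xlab = "IA", ...)
  graphics::abline(v = x$IA, col = "red", lwd = 2)
  invisible(x)
}

.stars <- function(p) if (p < 0.01) " **" else if (p < 0.05) " *" else ""

#' Phylogenetic compatibility of two loci
#'
#' Generalised four-gamete test. The observed allele combinations of the two
#' loci are laid out as marks in an alleles-of-j by alleles-of-k matrix; the
#' loci are incompatible when one can leave a marked box and return to it by
#' alternating horizontal and vertical moves through other marked boxes —
#' i.e. when the bipartite graph whose vertices are the alleles and whose
#' edges are the observed combinations contains a cycle. Compatibility is
#' therefore tested as acyclicity (the graph is a forest); for two biallelic
#' loci this reduces to observing at most three of the four gametes.
#'
#' @param gm a [genotype_matrix()].
#' @param locus_j,locus_k locus column names.
#' @return logical: `TRUE` when compatible (explainable by mutation on a
#'   single tree without homoplasy or recombination).
#' @export
pairwise_compatible <- function(gm, locus_j, locus_k) {
  stopifnot(inherits(gm, "genotype_matrix"),
            all(c(locus_j, locus_k) %in% loci(gm)))
  m <- .drop_het_entries(allele_matrix(gm))
  a <- m[, locus_j]; b <- m[, locus_k]
  ok <- !is.na(a) & !is.na(b)
  combos <- unique(data.frame(a = a[ok], b = b[ok], stringsAsFactors = FALSE))
  if (!nrow(combos)) stop("no isolate scored at both loci")
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("j:", combos$a), to = paste0("k:", combos$b)),
    directed = FALSE)
  igraph::ecount(g) == igraph::vcount(g) - igraph::count_components(g)
}

#' Pairwise compatibility matrix of all loci
#' @param gm a [genotype_matrix()] with >= 2 loci.
#' @return symmetric logical matrix (diagonal `NA`).
#' @export
compat_matrix <- function(gm) {
  l <- loci(gm)
  if (length(l) < 2) stop("need at least 2 loci")
  cm <- matrix(NA, length(l), length(l), dimnames = list(l, l))
  for (i in seq_along(l)) for (j in seq_along(l)) if (i < j) {
    cm[i, j] <- cm[j, i] <-
      suppressMessages(pairwise_compatible(gm, l[i], l[j]))
  }
  cm
}

#' Proportion of phylogenetically compatible locus pairs (PcP)
#' @param gm a [genotype_matrix()] with >= 2 loci.
#' @return proportion in \[0, 1\].
#' @export
pcp <- function(gm) {
  cm <- compat_matrix(gm)
  mean(cm[upper.tri(cm)])
}

#' Permutation test of phylogenetic incompatibility
#'
#' Counts the incompatible locus pairs in the observed sample and compares
#' it with the counts in `n_perm` within-locus allele shuffles (artificially
#' recombined datasets). A clonal sample shows *fewer* incompatibilities
#' than its recombined counterparts, so the primary p-value is
#' `(1 + #{permutations with count <= observed}) / (1 + n_perm)`; the
#' complementary tail (`p_excess`, observed count unusually high —
#' recombination in excess of the shuffle null) is reported alongside, since
#' the two hypotheses ("no recombination" vs "free recombination") point in
#' opposite directions.
#'
#' @inheritParams ia_test
#' @return list: `n_incompatible`, `p` (deficit tail), `p_excess`,
#'   `perm_counts`, `n_perm`, `seed`.
#' @export
incompatibility_test <- function(gm, n_perm = 500L, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  count_incompat <- function(g) {
    cm <- suppressMessages(compat_matrix(g))
    sum(!cm[upper.tri(cm)])
  }
  obs <- count_incompat(gm)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(b)
    count_incompat(permute_matrix(gm)), numeric(1))
  list(n_incompatible = obs,
       p = (1 + sum(perm <= obs)) / (1 + n_perm),
       p_excess = (1 + sum(perm >= obs)) / (1 + n_perm),
       perm_counts = perm, n_perm = as.integer(n_perm), seed = seed)
}

#' Clone-correct a genotype matrix
#'
#' Keeps one representative isolate (the lexicographically smallest id) per
#' distinct multilocus genotype. Idempotent.
#'
#' @param gm a [genotype_matrix()].
#' @return the reduced `genotype_matrix`.
#' @export
clone_correct <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  m <- allele_matrix(gm)
  key <- apply(m, 1, function(r) paste(ifelse(is.na(r), "\x01NA", r),
                                       collapse = "\x01"))
  ord <- order(gm$isolate_id)
  keep <- ord[!duplicated(key[ord])]
  out <- gm[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, loci = loci(gm), class = class(gm))
}

#' Polymorphic alignment sites as loci
#'
#' Converts an alignment of homoplasmic called sequences into a genotype
#' matrix with one locus per polymorphic site (allele = base), for
#' intra-genic among-site recombination tests. Monomorphic sites are
#' dropped; `N` and `-` are treated as missing. Ambiguity codes are refused:
#' heteroplasmic isolates must be phased (or excluded) first.
#'
#' @param alignment named character vector of equal-length sequences.
#' @param populations optional population labels (recycled).
#' @return a [genotype_matrix()] with locus columns `site_<pos>`; a fully
#'   monomorphic alignment yields an empty `data.frame` (no loci to test).
#' @export
sites_to_loci <- function(alignment, populations = "pop1") {
  if (!length(alignment)) stop("empty alignment")
  chars <- lapply(alignment, seq_chars)
  if (length(unique(lengths(chars))) != 1) stop("ragged alignment")
  m <- do.call(rbind, chars)
  if (any(is_ambiguity(m)))
    stop("alignment contains ambiguity codes; phase heteroplasmic ",
         "isolates first (em_phase) or exclude them")
  m[m %in% c("N", "-")] <- NA_character_
  poly <- which(apply(m, 2, function(col)
    length(unique(col[!is.na(col)])) >= 2))
  if (!length(poly)) return(data.frame())
  sub <- as.data.frame(m[, poly, drop = FALSE], stringsAsFactors = FALSE)
  names(sub) <- sprintf("site_%d", poly)
  ids <- names(alignment)
  if (is.null(ids)) ids <- sprintf("iso%03d", seq_along(alignment))
  genotype_matrix(sub, isolate_id = ids,
                  population = rep_len(populations, length(alignment)))
}

#' Full multilocus recombination report
#'
#' Umbrella test combining the index-of-association permutation test and
#' the phylogenetic compatibility analysis, optionally after clone
#' correction: the columns a clonality survey reports per sample (IA,
#' rbarD, PcP, significance).
#'
#' @param gm a [genotype_matrix()] with >= 2 loci.
#' @param n_perm permutations for both tests.
#' @param seed integer seed.
#' @param clone_correct reduce to unique multilocus genotypes first.
#' @return object of class `recomb_report`: `IA`, `rbarD`, `p_IA`, `PcP`,
#'   `n_incompatible`, `p_incompat` (deficit tail), `p_incompat_excess`,
#'   `compat` (matrix), `n_isolates`, `n_loci`, `n_perm`, `seed`,
#'   `clone_corrected`.
#' @export
recomb_test <- function(gm, n_perm = 500L, seed = NULL,
                        clone_correct = FALSE) {
  if (clone_correct) gm <- mitohet::clone_correct(gm)
  it <- ia_test(gm, n_perm = n_perm, seed = seed)
  ic <- incompatibility_test(gm, n_perm = n_perm,
                             seed = if (is.null(seed)) NULL else seed + 1L)
  cm <- suppressMessages(compat_matrix(gm))
  structure(list(IA = it$IA, rbarD = it$rbarD, p_IA = it$p,
                 PcP = mean(cm[upper.tri(cm)]),
                 n_incompatible = ic$n_incompatible, p_incompat = ic$p,
                 p_incompat_excess = ic$p_excess, compat = cm,
                 n_isolates = nrow(gm), n_loci = length(loci(gm)),
                 n_perm = as.integer(n_perm), seed = seed,
                 clone_corrected = clone_correct),
            class = "recomb_report")
}

#' @export
print.recomb_report <- function(x, ...) {
  cat(sprintf("Multilocus recombination report (n = %d%s, %d loci, %d permutations)\n",
              x$n_isolates, if (x$clone_corrected) ", clone-corrected" else "",
              x$n_loci, x$n_perm))
  cat(sprintf("  IA = %.4g%s   rbarD = %.4g   PcP = %.3g\n",
              x$IA, .stars(x$p_IA), x$rbarD, x$PcP))
  cat(sprintf("  incompatible pairs: %d; P(deficit vs recombined) = %.4g, P(excess) = %.4g\n",
              x$n_incompatible, x$p_incompat, x$p_incompat_excess))
  invisible(x)
}

#' @method summary recomb_report
#' @export
summary.recomb_report <- function(object, ...) {
  data.frame(IA = object$IA, rbarD = object$rbarD, p_IA = object$p_IA,
             PcP = object$PcP, n_incompatible = object$n_incompatible,
             p_incompat = object$p_incompat, n = object$n_isolates,
             loci = object$n_loci)
}
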