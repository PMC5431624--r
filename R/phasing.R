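# Haplotype-mixture resolution and classification. Heteroplasmic isolates
# read as IUPAC-ambiguous sequences; they are resolved into haplotype pairs
# against the homoplasmic isolates of the sample, either combinatorially
# (consistent_pairs) or by frequency-based EM (em_phase), and each resolved
# mixture is classified by whether both constituent haplotypes also occur in
# homoplasmic isolates locally, only population-wide, or not at all.

#' Haplotype catalog with per-population copy counts
#'
#' Copy counts follow the two-copies-per-isolate convention: every
#' homoplasmic isolate contributes 2 copies of its haplotype and every
#' resolved heteroplasmic isolate contributes 1 copy of each constituent, so
#' per-population counts sum to twice the number of typed isolates.
#'
#' @param counts named list: population -> named numeric vector of haplotype
#'   copy counts (heterozygote contributions included).
#' @param sizes optional named integer vector of typed isolates per
#'   population; populations whose counts do not sum to `2 * size` are
#'   reported with a warning (never silently fixed).
#' @param hets optional data.frame (`population`, `hap1`, `hap2`) of
#'   heteroplasmic genotypes, one row per heteroplasmic isolate.
#' @param seqs optional named character vector of haplotype sequences,
#'   required by [consistent_pairs()].
#' @return an object of class `haplotype_catalog`.
#' @export
haplotype_catalog <- function(counts, sizes = NULL, hets = NULL,
                              seqs = NULL) {
  if (!length(counts) || is.null(names(counts)))
    stop("counts must be a named (by population) list")
  counts <- lapply(counts, function(x) {
    if (is.null(names(x))) stop("each count vector must be named by haplotype")
    x
  })
  if (!is.null(hets)) {
    hets <- as.data.frame(hets, stringsAsFactors = FALSE)
    stopifnot(all(c("population", "hap1", "hap2") %in% names(hets)))
    hets$hap1 <- as.character(hets$hap1)
    hets$hap2 <- as.character(hets$hap2)
    # canonical unordered order
    sw <- hets$hap1 > hets$hap2
    tmp <- hets$hap1[sw]; hets$hap1[sw] <- hets$hap2[sw]; hets$hap2[sw] <- tmp
  } else {
    hets <- data.frame(population = character(0), hap1 = character(0),
                       hap2 = character(0), stringsAsFactors = FALSE)
  }
  if (!is.null(sizes)) {
    bad <- names(counts)[vapply(names(counts), function(p) {
      !is.na(sizes[p]) && sum(counts[[p]]) != 2 * sizes[[p]]
    }, logical(1))]
    if (length(bad))
      warning("copy counts do not sum to 2 x sample size in: ",
              paste(bad, collapse = ", "))
  }
  structure(list(counts = counts, sizes = sizes, hets = hets, seqs = seqs),
            class = "haplotype_catalog")
}

#' @export
print.haplotype_catalog <- function(x, ...) {
  haps <- sort(unique(unlist(lapply(x$counts, names))))
  cat(sprintf("Haplotype catalog: %d haplotypes, %d population(s), %d heteroplasmic genotype(s)\n",
              length(haps), length(x$counts), nrow(x$hets)))
  tot <- catalog_totals(x)
  cat("  total copies:",
      paste(sprintf("%s(%g)", names(tot), tot), collapse = "; "), "\n")
  invisible(x)
}

# total copy count per haplotype across populations
catalog_totals <- function(catalog) {
  haps <- sort(unique(unlist(lapply(catalog$counts, names))))
  tot <- stats::setNames(numeric(length(haps)), haps)
  for (p in names(catalog$counts)) {
    cc <- catalog$counts[[p]]
    tot[names(cc)] <- tot[names(cc)] + cc
  }
  tot
}

#' Haplotype copies attributable to homoplasmic isolates
#'
#' Subtracts, per population, one copy for each occurrence of a haplotype
#' inside a heteroplasmic genotype, leaving the copies carried by
#' homoplasmic isolates only. A subtraction below zero indicates an
#' inconsistent catalog and raises an error naming the population and
#' haplotype.
#'
#' @param catalog a [haplotype_catalog()].
#' @return named list: population -> named numeric vector of homoplasmic
#'   copy counts.
#' @export
homoplasmic_counts <- function(catalog) {
  out <- catalog$counts
  for (i in seq_len(nrow(catalog$hets))) {
    p <- catalog$hets$population[i]
    for (h in c(catalog$hets$hap1[i], catalog$hets$hap2[i])) {
      if (is.null(out[[p]]) || is.na(out[[p]][h]))
        stop("heteroplasmic genotype names haplotype ", h,
             " absent from population ", p)
      out[[p]][h] <- out[[p]][h] - 1
      if (out[[p]][h] < 0)
        stop("copy count of haplotype ", h, " in population ", p,
             " drops below zero: catalog inconsistent")
    }
  }
  out
}

#' Classify a heteroplasmic haplotype mixture
#'
#' A mixture (h1, h2) observed in a population is *local* when both
#' haplotypes are carried by homoplasmic isolates (count >= 1 after
#' subtracting heterozygote contributions) in that same population; failing
#' that it is *global* when both are carried by homoplasmic isolates
#' somewhere in the whole sample; otherwise it is *unexplained* — the
#' mixture cannot be interpreted as a blend of two observed homoplasmic
#' types. Local implies global by construction.
#'
#' @param pair character vector of the two (distinct) haplotype labels.
#' @param population population in which the mixture was observed.
#' @param catalog a [haplotype_catalog()].
#' @return `"local"`, `"global"` or `"unexplained"`.
#' @export
classify_mixture <- function(pair, population, catalog) {
  pair <- as.character(pair)
  if (length(pair) != 2 || pair[1] == pair[2])
    stop("pair must be two distinct haplotype labels")
  known <- unique(unlist(lapply(catalog$counts, names)))
  if (!all(pair %in% known))
    stop("unknown haplotype label(s): ",
         paste(setdiff(pair, known), collapse = ", "))
  hc <- homoplasmic_counts(catalog)
  local_cc <- hc[[population]]
  if (is.null(local_cc)) stop("unknown population: ", population)
  get0 <- function(v, h) if (is.na(v[h])) 0 else v[[h]]
  if (all(vapply(pair, function(h) get0(local_cc, h) >= 1, logical(1))))
    return("local")
  tot <- Reduce(`+`, lapply(names(hc), function(p) {
    v <- stats::setNames(numeric(length(known)), known)
    v[names(hc[[p]])] <- hc[[p]]
    v
  }))
  if (all(tot[pair] >= 1)) return("global")
  "unexplained"
}

#' Classify every heteroplasmic genotype in a catalog
#'
#' @param catalog a [haplotype_catalog()] with a non-empty `hets` table.
#' @return data.frame (`population`, `hap1`, `hap2`, `class`), one row per
#'   heteroplasmic isolate.
#' @export
classify_mixtures <- function(catalog) {
  hets <- catalog$hets
  if (!nrow(hets)) return(cbind(hets, class = character(0)))
  hets$class <- vapply(seq_len(nrow(hets)), function(i)
    classify_mixture(c(hets$hap1[i], hets$hap2[i]), hets$population[i],
                     catalog), character(1))
  hets
}

#' Catalog haplotype pairs consistent with a heteroplasmic sequence
#'
#' Returns every unordered pair of catalog haplotypes whose site-wise
#' superposition (identical bases where equal, the matching IUPAC code where
#' different) equals the observed ambiguous sequence. When no catalog pair
#' fits, each single catalog haplotype compatible with the sequence is
#' completed with the implied novel partner (taking the other base at every
#' ambiguous site); novel partners are labelled by their sequence.
#'
#' @param het_sequence IUPAC-coded sequence with >= 1 two-base ambiguity
#'   code.
#' @param catalog a [haplotype_catalog()] carrying haplotype `seqs`.
#' @return data.frame (`hap1`, `hap2`, `novel`); zero rows when no
#'   resolution exists at all.
#' @export
consistent_pairs <- function(het_sequence, catalog) {
  seqs <- catalog$seqs
  if (is.null(seqs)) stop("catalog carries no haplotype sequences")
  target <- seq_chars(het_sequence)
  amb <- which(is_ambiguity(target))
  if (!length(amb)) stop("sequence has no ambiguity code; nothing to phase")
  labs <- names(seqs)
  none <- data.frame(hap1 = character(0), hap2 = character(0),
                     novel = logical(0), stringsAsFactors = FALSE)
  keep <- vapply(seqs, function(s) nchar(s) == length(target), logical(1))
  labs <- labs[keep]
  out <- none
  if (length(labs) >= 2) {
    cmb <- utils::combn(labs, 2)
    for (k in seq_len(ncol(cmb))) {
      sup <- superpose_seqs(seqs[[cmb[1, k]]], seqs[[cmb[2, k]]])
      if (identical(sup, paste(target, collapse = "")))
        out <- rbind(out, data.frame(hap1 = cmb[1, k], hap2 = cmb[2, k],
                                     novel = FALSE, stringsAsFactors = FALSE))
    }
  }
  if (nrow(out)) return(out)
  # novel-haplotype completion of single catalog matches
  for (l in labs) {
    s <- seq_chars(seqs[[l]])
    compatible <- all(s[-amb] == target[-amb]) &&
      all(vapply(amb, function(i) s[i] %in% iupac_bases(target[i]),
                 logical(1)))
    if (compatible) {
      partner <- target
      for (i in amb) partner[i] <- setdiff(iupac_bases(target[i]), s[i])
      partner <- paste(partner, collapse = "")
      pr <- sort(c(l, partner))
      out <- rbind(out, data.frame(hap1 = pr[1], hap2 = pr[2], novel = TRUE,
                                   stringsAsFactors = FALSE))
    }
  }
  unique(out)
}

# enumerate the unordered full-sequence pairs an IUPAC sequence can resolve
# into: 2^(k-1) pairs for k ambiguous sites
.expand_pairs <- function(s) {
  ch <- seq_chars(s)
  amb <- which(is_ambiguity(ch))
  if (!length(amb)) {
    seq1 <- paste(ch, collapse = "")
    return(list(c(seq1, seq1)))
  }
  if (length(amb) > 12)
    stop("sequence has ", length(amb),
         " ambiguous sites; pair expansion capped at 12")
  choices <- lapply(amb, function(i) iupac_bases(ch[i]))
  grid <- expand.grid(choices, stringsAsFactors = FALSE)
  pairs <- vector("list", nrow(grid))
  seen <- character(0)
  n_out <- 0
  for (g in seq_len(nrow(grid))) {
    a <- ch; b <- ch
    for (j in seq_along(amb)) {
      a[amb[j]] <- grid[g, j]
      b[amb[j]] <- setdiff(iupac_bases(ch[amb[j]]), grid[g, j])
    }
    pr <- sort(c(paste(a, collapse = ""), paste(b, collapse = "")))
    key <- paste(pr, collapse = "|")
    if (!key %in% seen) {
      seen <- c(seen, key)
      n_out <- n_out + 1
      pairs[[n_out]] <- pr
    }
  }
  pairs[seq_len(n_out)]
}

#' EM phasing of heteroplasmic sequences against homoplasmic references
#'
#' Maximum-likelihood haplotype frequencies by expectation-maximisation in
#' the style of Excoffier & Slatkin: each homoplasmic isolate contributes
#' two copies of its haplotype; each heteroplasmic isolate is an unordered
#' pair drawn from the (unknown) haplotype frequencies, summed over every
#' pair consistent with its ambiguity codes. Frequencies are updated from
#' posterior pair weights until the largest frequency change falls below
#' `tol`. Each heteroplasmic isolate is resolved to its maximum-posterior
#' pair. The algorithm is deterministic (uniform initialisation,
#' lexicographic tie-break); `seed` is accepted for interface stability and
#' ignored.
#'
#' @param sequences named character vector of called sequences (IUPAC
#'   ambiguity codes at heteroplasmic sites).
#' @param max_iter iteration cap; non-convergence sets a warning flag rather
#'   than erroring.
#' @param tol convergence tolerance on haplotype frequencies.
#' @param seed ignored (see above).
#' @return object of class `em_phase`: `frequencies` (named, summing to 1),
#'   `resolutions` (data.frame `isolate`, `hap1`, `hap2`, `posterior`,
#'   `n_pairs`), `loglik` (per-iteration trace, non-decreasing),
#'   `iterations`, `converged`.
#' @export
em_phase <- function(sequences, max_iter = 500L, tol = 1e-8, seed = NULL) {
  if (!length(sequences)) stop("no sequences")
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("iso%03d", seq_along(sequences))
  pair_sets <- lapply(sequences, .expand_pairs)
  haps <- sort(unique(unlist(pair_sets)))
  p <- stats::setNames(rep(1 / length(haps), length(haps)), haps)
  n2 <- 2 * length(sequences)
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0
  # per-isolate pair index matrices for speed
  idx <- lapply(pair_sets, function(ps)
    cbind(match(vapply(ps, `[`, character(1), 1), haps),
          match(vapply(ps, `[`, character(1), 2), haps)))
  for (iter in seq_len(max_iter)) {
    counts <- stats::setNames(rep(0, length(haps)), haps)
    ll <- 0
    for (i in seq_along(idx)) {
      m <- idx[[i]]
      w <- p[m[, 1]] * p[m[, 2]] * ifelse(m[, 1] == m[, 2], 1, 2)
      tw <- sum(w)
      if (tw <= 0) w <- rep(1 / nrow(m), nrow(m)) else w <- w / tw
      ll <- ll + log(max(tw, .Machine$double.xmin))
      for (k in seq_len(nrow(m))) {
        counts[m[k, 1]] <- counts[m[k, 1]] + w[k]
        counts[m[k, 2]] <- counts[m[k, 2]] + w[k]
      }
    }
    loglik <- c(loglik, ll)
    p_new <- counts / n2
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations")
  res <- do.call(rbind, lapply(seq_along(idx), function(i) {
    m <- idx[[i]]
    w <- p[m[, 1]] * p[m[, 2]] * ifelse(m[, 1] == m[, 2], 1, 2)
    if (sum(w) <= 0) w <- rep(1, nrow(m))
    w <- w / sum(w)
    best <- order(-w, haps[m[, 1]], haps[m[, 2]])[1]
    data.frame(isolate = names(sequences)[i],
               hap1 = haps[m[best, 1]], hap2 = haps[m[best, 2]],
               posterior = w[best], n_pairs = nrow(m),
               stringsAsFactors = FALSE)
  }))
  structure(list(frequencies = p, resolutions = res, loglik = loglik,
                 iterations = iter, converged = converged),
            class = "em_phase")
}

#' @export
print.em_phase <- function(x, ...) {
  cat(sprintf("EM haplotype phasing: %d haplotypes, %d isolates, %d iterations (%s)\n",
              length(x$frequencies), nrow(x$resolutions), x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  log-likelihood: %.4f\n", utils::tail(x$loglik, 1)))
  amb <- x$resolutions[x$resolutions$n_pairs > 1, ]
  cat(sprintf("  heteroplasmic isolates resolved: %d (min posterior %.3f)\n",
              nrow(amb), if (nrow(amb)) min(amb$posterior) else NA_real_))
  invisible(x)
}

#' @method coef em_phase
#' @export
coef.em_phase <- function(object, ...) object$frequencies

#' @method logLik em_phase
#' @export
logLik.em_phase <- function(object, ...) {
  structure(utils::tail(object$loglik, 1), df = length(object$frequencies) - 1,
            class = "logLik")
}

#' Map single-locus genotypes to (possibly ambiguous) sequences
#'
#' Convenience bridge from a genotype matrix to the phasing layer: each
#' isolate's allele label at `locus` is replaced by its haplotype sequence;
#' heteroplasmic `"a/b"` cells become the IUPAC superposition of the two
#' haplotype sequences.
#'
#' @param gm a [genotype_matrix()].
#' @param locus locus column name.
#' @param seqs named character vector mapping allele labels to sequences.
#' @return named character vector of sequences (names = isolate ids);
#'   isolates missing at `locus` are dropped.
#' @export
genotypes_to_sequences <- function(gm, locus, seqs) {
  stopifnot(inherits(gm, "genotype_matrix"), locus %in% loci(gm))
  cells <- stats::setNames(gm[[locus]], gm$isolate_id)
  cells <- cells[!is.na(cells)]
  vapply(cells, function(cell) {
    if (is_het_cell(cell)) {
      pr <- het_alleles(cell)[[1]]
      superpose_seqs(seqs[[pr[1]]], seqs[[pr[2]]])
    } else seqs[[cell]]
  }, character(1))
}

#' Build a haplotype catalog from phased single-locus genotypes
#'
#' Counts two copies per homoplasmic isolate and one copy per constituent of
#' each heteroplasmic genotype, per population.
#'
#' @param gm a [genotype_matrix()] (entries may be heteroplasmic).
#' @param locus locus column name.
#' @param seqs optional haplotype sequences to attach.
#' @return a [haplotype_catalog()].
#' @export
catalog_from_genotypes <- function(gm, locus, seqs = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), locus %in% loci(gm))
  pops <- unique(gm$population)
  counts <- list()
  hets <- data.frame(population = character(0), hap1 = character(0),
                     hap2 = character(0), stringsAsFactors = FALSE)
  sizes <- stats::setNames(integer(length(pops)), pops)
  for (p in pops) {
    cells <- gm[[locus]][gm$population == p]
    cells <- cells[!is.na(cells)]
    sizes[p] <- length(cells)
    copies <- character(0)
    for (cell in cells) {
      if (is_het_cell(cell)) {
        pr <- sort(het_alleles(cell)[[1]])
        copies <- c(copies, pr)
        hets <- rbind(hets, data.frame(population = p, hap1 = pr[1],
                                       hap2 = pr[2], stringsAsFactors = FALSE))
      } else copies <- c(copies, cell, cell)
    }
    tab <- table(copies)
    counts[[p]] <- stats::setNames(as.numeric(tab), names(tab))
  }
  haplotype_catalog(counts, sizes = sizes, hets = hets, seqs = seqs)
}
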