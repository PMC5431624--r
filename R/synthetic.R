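# Seeded generators for genotype matrices, heteroplasmic mixtures, trace-peak
# profiles and qPCR Ct panels. These emulate the data-generating assumptions
# of the downstream analyses (clonal vs panmictic multilocus structure,
# two-haplotype mixtures with a minor/major copy ratio, idealised exponential
# PCR amplification), so every stage is testable without raw chromatograms.

#' Simulation configuration
#'
#' Bundles and validates the parameters of [simulate_genotype_matrix()].
#'
#' @param n_isolates number of isolates to simulate.
#' @param loci named list; each element is `list(alleles =, freqs =)` giving
#'   the allele labels and their population frequencies at that locus
#'   (frequencies must sum to 1 within 1e-9).
#' @param mode `"clonal"` (replicate a small founder set), `"panmictic"`
#'   (loci drawn independently: linkage equilibrium), or `"mixed"`.
#' @param n_populations number of equally sized population labels.
#' @param clonal_fraction for `mode = "mixed"`, the proportion of isolates
#'   copied from founders rather than drawn panmicticly; in \[0, 1\].
#' @param n_founders number of founder genotypes in clonal/mixed modes.
#' @param founders optional matrix/data.frame of founder allele labels
#'   (rows = founders, columns = loci); drawn at random (distinct where the
#'   allele space allows) when `NULL`.
#' @param het_rate proportion of isolates later made heteroplasmic by
#'   [inject_heteroplasmy()]; in \[0, 1\].
#' @param mixing_fraction minor/major haplotype copy ratio in (0, 1\].
#' @param seed integer seed driving every draw.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_isolates,
                       loci,
                       mode = c("panmictic", "clonal", "mixed"),
                       n_populations = 1L,
                       clonal_fraction = 0.5,
                       n_founders = 2L,
                       founders = NULL,
                       het_rate = 0,
                       mixing_fraction = 0.4,
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_isolates >= 1, n_populations >= 1, n_founders >= 1)
  if (het_rate < 0 || het_rate > 1) stop("het_rate must be in [0, 1]")
  if (clonal_fraction < 0 || clonal_fraction > 1)
    stop("clonal_fraction must be in [0, 1]")
  if (mixing_fraction <= 0 || mixing_fraction > 1)
    stop("mixing_fraction must be in (0, 1]")
  if (is.null(names(loci)) || any(!nzchar(names(loci))))
    stop("loci must be a named list")
  for (nm in names(loci)) {
    l <- loci[[nm]]
    if (is.null(l$alleles) || is.null(l$freqs) ||
        length(l$alleles) != length(l$freqs))
      stop("locus ", nm, ": need matching alleles and freqs")
    if (abs(sum(l$freqs) - 1) > 1e-9)
      stop("locus ", nm, ": allele frequencies must sum to 1 (got ",
           format(sum(l$freqs)), ")")
    if (any(l$freqs < 0)) stop("locus ", nm, ": negative allele frequency")
  }
  structure(list(n_isolates = as.integer(n_isolates), loci = loci,
                 mode = mode, n_populations = as.integer(n_populations),
                 clonal_fraction = clonal_fraction,
                 n_founders = as.integer(n_founders), founders = founders,
                 het_rate = het_rate, mixing_fraction = mixing_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# one panmictic draw of m multilocus genotypes
.draw_panmictic <- function(loci, m) {
  cols <- lapply(loci, function(l)
    sample(as.character(l$alleles), m, replace = TRUE, prob = l$freqs))
  as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
}

.draw_founders <- function(loci, k) {
  space <- prod(vapply(loci, function(l) length(l$alleles), numeric(1)))
  for (try in 1:200) {
    f <- .draw_panmictic(loci, k)
    if (k <= space && !anyDuplicated(f)) return(f)
    if (k > space) return(f)  # distinctness impossible, accept
  }
  f
}

#' Simulate a multilocus genotype matrix
#'
#' Panmictic mode draws each locus independently from its allele frequencies
#' (linkage equilibrium, the null of the index-of-association test); clonal
#' mode replicates a small founder set evenly across isolates (complete
#' linkage); mixed mode copies a `clonal_fraction` of isolates from founders
#' and draws the rest panmicticly. Reproducible given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()] with attributes `seed` and `founders`.
#' @export
simulate_genotype_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_isolates
  founders <- NULL
  rows <- switch(config$mode,
    panmictic = .draw_panmictic(config$loci, n),
    clonal = {
      founders <- if (is.null(config$founders))
        .draw_founders(config$loci, config$n_founders)
      else as.data.frame(config$founders, stringsAsFactors = FALSE)
      founders[rep_len(seq_len(nrow(founders)), n), , drop = FALSE]
    },
    mixed = {
      founders <- if (is.null(config$founders))
        .draw_founders(config$loci, config$n_founders)
      else as.data.frame(config$founders, stringsAsFactors = FALSE)
      n_clonal <- round(config$clonal_fraction * n)
      cl <- founders[rep_len(seq_len(nrow(founders)), n_clonal), , drop = FALSE]
      pm <- .draw_panmictic(config$loci, n - n_clonal)
      idx <- sample.int(n)  # interleave so populations mix both regimes
      rbind(cl, pm)[idx, , drop = FALSE]
    })
  rownames(rows) <- NULL
  pops <- sprintf("pop%d", sort(rep_len(seq_len(config$n_populations), n)))
  gm <- genotype_matrix(rows,
                        isolate_id = sprintf("iso%04d", seq_len(n)),
                        population = pops)
  attr(gm, "seed") <- config$seed
  attr(gm, "founders") <- founders
  gm
}

#' Inject heteroplasmy into a homoplasmic genotype matrix
#'
#' Each isolate is independently selected with probability `het_rate`; a
#' selected isolate becomes heteroplasmic at exactly one locus (mirroring the
#' field observation that heteroplasmy at different genes rarely co-occurs),
#' with the second allele drawn from its population's allele pool at that
#' locus. All non-selected entries are left bitwise unchanged. The truth
#' (isolate, locus, major and minor allele, mixing fraction) is recorded in
#' attribute `het_truth` for recovery tests.
#'
#' @param gm homoplasmic [genotype_matrix()].
#' @param het_rate per-isolate selection probability in \[0, 1\].
#' @param mixing_fraction minor/major copy ratio recorded in the truth table.
#' @param seed integer seed.
#' @return the modified `genotype_matrix` with attribute `het_truth`.
#' @export
inject_heteroplasmy <- function(gm, het_rate, mixing_fraction = 0.4,
                                seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (het_rate < 0 || het_rate > 1) stop("het_rate must be in [0, 1]")
  am <- allele_matrix(gm)
  if (any(is_het_cell(am)))
    stop("matrix already contains heteroplasmic entries")
  set.seed(seed)
  sel <- which(stats::runif(nrow(gm)) < het_rate)
  truth <- data.frame(isolate_id = character(0), locus = character(0),
                      allele_major = character(0), allele_minor = character(0),
                      mixing_fraction = numeric(0),
                      stringsAsFactors = FALSE)
  for (i in sel) {
    pop <- gm$population[i]
    pools <- lapply(loci(gm), function(l) {
      p <- unique(stats::na.omit(am[gm$population == pop, l]))
      if (length(p) < 2) p <- unique(stats::na.omit(am[, l]))
      p
    })
    names(pools) <- loci(gm)
    ok <- names(pools)[vapply(pools, length, integer(1)) >= 2 &
                         !is.na(am[i, loci(gm)])]
    if (!length(ok)) next  # nothing injectable for this isolate
    loc <- if (length(ok) == 1) ok else sample(ok, 1)
    major <- am[i, loc]
    minor <- sample(setdiff(pools[[loc]], major), 1)
    gm[[loc]][i] <- het_cell(major, minor)
    truth <- rbind(truth, data.frame(
      isolate_id = gm$isolate_id[i], locus = loc, allele_major = major,
      allele_minor = minor, mixing_fraction = mixing_fraction,
      stringsAsFactors = FALSE))
  }
  attr(gm, "het_truth") <- truth
  attr(gm, "seed") <- seed
  gm
}

#' Simulate a four-channel trace-peak profile of a haplotype mixture
#'
#' Emulates the per-site peak heights of a Sanger chromatogram reading a
#' mixture of two haplotypes: at every site the major base channel has mean
#' `signal`; where the haplotypes differ, the minor base channel has mean
#' `signal * mixing_fraction`; all other channels have mean 0. Noise is
#' half-normal (a centred Gaussian of scale `noise_sd` truncated at zero)
#' added to every channel, so fluorescence never goes negative.
#'
#' @param major_seq,minor_seq equal-length A/C/G/T strings.
#' @param mixing_fraction minor/major copy ratio in (0, 1\].
#' @param signal mean major peak height (arbitrary fluorescence units).
#' @param noise_sd scale of the half-normal channel noise; 0 for noiseless.
#' @param seed integer seed (ignored when `noise_sd = 0`).
#' @return a `trace_profile`: data.frame with columns `pos`, `A`, `C`, `G`,
#'   `T` and attribute `truth` (major, minor, mixing fraction, differing
#'   sites).
#' @export
simulate_trace <- function(major_seq, minor_seq, mixing_fraction,
                           signal = 100, noise_sd = 0, seed = 1L) {
  a <- seq_chars(major_seq)
  b <- seq_chars(minor_seq)
  if (length(a) != length(b)) stop("sequences differ in length")
  if (mixing_fraction <= 0 || mixing_fraction > 1)
    stop("mixing_fraction must be in (0, 1]")
  if (!all(c(a, b) %in% .BASES)) stop("sequences must be A/C/G/T only")
  n <- length(a)
  h <- matrix(0, n, 4, dimnames = list(NULL, .BASES))
  h[cbind(seq_len(n), match(a, .BASES))] <- signal
  d <- which(a != b)
  h[cbind(d, match(b[d], .BASES))] <- signal * mixing_fraction
  if (noise_sd > 0) {
    set.seed(seed)
    h <- h + abs(matrix(stats::rnorm(n * 4, 0, noise_sd), n, 4))
  }
  structure(data.frame(pos = seq_len(n), h, check.names = FALSE),
            truth = list(major = paste(a, collapse = ""),
                         minor = paste(b, collapse = ""),
                         mixing_fraction = mixing_fraction,
                         het_sites = d, seed = seed),
            class = c("trace_profile", "data.frame"))
}

#' @export
print.trace_profile <- function(x, ...) {
  cat(sprintf("Trace profile: %d sites, peak range [%.3g, %.3g]\n",
              nrow(x), min(x[, .BASES]), max(x[, .BASES])))
  tr <- attr(x, "truth")
  if (!is.null(tr))
    cat(sprintf("  truth: mixing fraction %.3g, %d differing site(s)\n",
                tr$mixing_fraction, length(tr$het_sites)))
  invisible(x)
}

#' Plot a trace profile as channel height curves
#'
#' @param x a `trace_profile`.
#' @param ... passed to [graphics::matplot()].
#' @method plot trace_profile
#' @export
plot.trace_profile <- function(x, ...) {
  graphics::matplot(x$pos, as.matrix(x[, .BASES]), type = "l", lty = 1,
                    col = c("green3", "blue", "black", "red"),
                    xlab = "position", ylab = "peak height", ...)
  graphics::legend("topright", legend = .BASES, lty = 1,
                   col = c("green3", "blue", "black", "red"), bty = "n")
  invisible(x)
}

#' Simulate a qPCR Ct panel from true per-cell copy numbers
#'
#' Inverts the relative copy-number equation: with a nuclear reference at 2
#' copies per cell and idealised doubling per cycle, a noiseless target
#' threshold cycle satisfies
#' `ctm = ctn + log2(2 * Ln / (Lm * Nm))`. Replicates add Gaussian jitter of
#' scale `replicate_sd` to every Ct. At `replicate_sd = 0` this round-trips
#' exactly with [relative_copy_number()].
#'
#' @param copies named vector of true copies per cell for the target genes
#'   (all > 0).
#' @param lengths named vector of amplicon lengths in bp for the targets and
#'   the reference gene (all > 0).
#' @param ref_gene name of the nuclear reference gene (2 copies per cell).
#' @param ref_ct noiseless reference threshold cycle.
#' @param replicate_sd Gaussian jitter of replicate Ct values, in cycles.
#' @param n_reps replicates per gene.
#' @param seed integer seed.
#' @return a [ct_panel()].
#' @export
simulate_ct <- function(copies, lengths, ref_gene, ref_ct,
                        replicate_sd = 0, n_reps = 3L, seed = 1L) {
  if (any(copies <= 0)) stop("copy numbers must be positive")
  if (any(lengths <= 0)) stop("amplicon lengths must be positive")
  if (!ref_gene %in% names(lengths)) stop("no length for reference gene")
  targets <- names(copies)
  if (!all(targets %in% names(lengths))) stop("missing target lengths")
  Ln <- lengths[[ref_gene]]
  ct0 <- c(stats::setNames(ref_ct, ref_gene),
           ref_ct + log2(2 * Ln / (lengths[targets] * copies[targets])))
  set.seed(seed)
  ct <- lapply(ct0, function(mu) mu + stats::rnorm(n_reps, 0, replicate_sd))
  ct_panel(genes = names(ct0),
           lengths = c(Ln, unname(lengths[targets])),
           ct = ct,
           is_reference = names(ct0) == ref_gene,
           seed = seed)
}

#' Would an amplicon be detected after a given number of PCR cycles?
#'
#' Idealised exponential amplification (efficiency exactly 2): detection
#' occurs once `copies_per_cell * template_cells * 2^cycles` reaches the
#' detection threshold in molecules. Monotone non-decreasing in cycles,
#' copies and template cells. This is the model behind screening the
#' abundant mitochondrial copy at few cycles and the rare copy only at many
#' cycles.
#'
#' @param copies_per_cell copies of the target per cell (> 0).
#' @param template_cells number of template cells (> 0).
#' @param cycles PCR cycle count (> 0).
#' @param threshold detection threshold in molecules (>= 0).
#' @return logical (vectorised over its arguments).
#' @export
amplicon_detected <- function(copies_per_cell, template_cells, cycles,
                              threshold) {
  if (any(copies_per_cell <= 0, template_cells <= 0, cycles <= 0))
    stop("copies, cells and cycles must be positive")
  if (any(threshold < 0)) stop("threshold must be non-negative")
  copies_per_cell * template_cells * 2^cycles >= threshold
}

#' Simulate a pool of distinct haplotype sequences
#'
#' Utility for phasing/caller tests: random A/C/G/T sequences, pairwise
#' distinct.
#'
#' @param n_hap number of haplotypes.
#' @param n_sites sequence length.
#' @param seed integer seed.
#' @return named character vector (`h1`, `h2`, ...).
#' @export
simulate_haplotype_seqs <- function(n_hap, n_sites, seed = 1L) {
  set.seed(seed)
  for (try in 1:200) {
    s <- vapply(seq_len(n_hap), function(i)
      paste(sample(.BASES, n_sites, replace = TRUE), collapse = ""),
      character(1))
    if (!anyDuplicated(s))
      return(stats::setNames(s, sprintf("h%d", seq_len(n_hap))))
  }
  stop("could not draw ", n_hap, " distinct sequences of length ", n_sites)
}
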