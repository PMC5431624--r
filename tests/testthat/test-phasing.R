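# Haplotype-mixture resolution (combinatorial and EM) and classification of
# heteroplasmic genotypes against the homoplasmic background.

test_that("consistent_pairs finds exactly the superposition-consistent pairs", {
  h1 <- "ACGTACGTAC"
  h6 <- "ACGTGCGTAC"  # one difference at site 5 (A/G)
  cat <- haplotype_catalog(list(p = c(h1 = 2, h6 = 2)),
                           seqs = c(h1 = h1, h6 = h6))
  out <- consistent_pairs(superpose_seqs(h1, h6), cat)
  expect_equal(nrow(out), 1L)
  expect_setequal(c(out$hap1, out$hap2), c("h1", "h6"))
  expect_false(out$novel)

  expect_error(consistent_pairs(h1, cat), "no ambiguity")
})

test_that("consistent_pairs agrees with exhaustive pair enumeration", {
  set.seed(41)
  seqs <- simulate_haplotype_seqs(6, 8, seed = 41)
  cat <- haplotype_catalog(list(p = stats::setNames(rep(2, 6), names(seqs))),
                           seqs = seqs)
  for (k in 1:20) {
    pr <- sample(names(seqs), 2)
    target <- superpose_seqs(seqs[[pr[1]]], seqs[[pr[2]]])
    got <- consistent_pairs(target, cat)
    # oracle: test every catalog pair by direct superposition
    cmb <- utils::combn(names(seqs), 2)
    expected <- Filter(Negate(is.null), lapply(seq_len(ncol(cmb)), function(i) {
      if (identical(superpose_seqs(seqs[[cmb[1, i]]], seqs[[cmb[2, i]]]),
                    target)) sort(cmb[, i])
    }))
    got_pairs <- lapply(seq_len(nrow(got)), function(i)
      sort(c(got$hap1[i], got$hap2[i])))
    expect_setequal(vapply(got_pairs, paste, character(1), collapse = "|"),
                    vapply(expected, paste, character(1), collapse = "|"))
  }
})

test_that("unexplainable mixtures are completed with novel haplotypes", {
  h1 <- "AAAAA"
  cat <- haplotype_catalog(list(p = c(h1 = 2)), seqs = c(h1 = h1))
  out <- consistent_pairs("ARAAA", cat)  # A/G at site 2: partner unseen
  expect_true(all(out$novel))
  expect_true("AGAAA" %in% c(out$hap1, out$hap2))
})

test_that("EM reduces to empirical frequencies on homoplasmic data", {
  seqs <- c(rep("AAAA", 6), rep("AAGA", 3), "TTTT")
  fit <- em_phase(seqs)
  expect_equal(sum(fit$frequencies), 1)
  expect_equal(unname(fit$frequencies[c("AAAA", "AAGA", "TTTT")]),
               c(0.6, 0.3, 0.1))
  expect_true(fit$converged)
})

test_that("abundant homoplasmic references dominate the het posterior", {
  h1 <- "ACGTACGTAC"
  h6 <- "ACGTGCGTTC"  # two differences: sites 5 and 9
  het <- superpose_seqs(h1, h6)
  fit <- em_phase(c(rep(h1, 5), rep(h6, 5), het))
  res <- fit$resolutions[11, ]
  # the alternative resolution is a pair of never-seen recombinant haplotypes
  expect_equal(res$n_pairs, 2L)
  expect_setequal(c(res$hap1, res$hap2), c(h1, h6))
  expect_gt(res$posterior, 0.99)
  expect_true(all(diff(fit$loglik) >= -1e-9))
})

test_that("EM recovers injected heteroplasmic pairs on synthetic populations", {
  pool <- simulate_haplotype_seqs(6, 12, seed = 11)
  cfg <- sim_config(120, loci = list(
    cox3 = list(alleles = names(pool),
                freqs = c(0.3, 0.25, 0.15, 0.12, 0.1, 0.08))),
    mode = "panmictic", seed = 42)
  gm <- inject_heteroplasmy(simulate_genotype_matrix(cfg), 0.15, 0.4,
                            seed = 43)
  truth <- attr(gm, "het_truth")
  fit <- em_phase(genotypes_to_sequences(gm, "cox3", pool))
  ok <- vapply(seq_len(nrow(truth)), function(i) {
    r <- fit$resolutions[fit$resolutions$isolate == truth$isolate_id[i], ]
    setequal(c(r$hap1, r$hap2),
             unname(pool[c(truth$allele_major[i], truth$allele_minor[i])]))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("catalog copy counts reconcile with population sizes", {
  cat3 <- read_haplotype_survey()
  for (p in names(cat3$counts))
    expect_equal(sum(cat3$counts[[p]]), 2 * cat3$sizes[[p]])
  # 12 distinct haplotypes; 568 copies = 2 x 284 typed isolates
  tot <- Reduce(`+`, lapply(cat3$counts, function(x) {
    v <- stats::setNames(numeric(12), as.character(1:12)); v[names(x)] <- x; v
  }))
  expect_equal(sum(tot), 568)
  expect_equal(unname(tot), c(144, 2, 4, 2, 8, 173, 56, 9, 47, 31, 91, 1))
})

test_that("heterozygote subtraction yields homoplasmic copy counts", {
  cat3 <- read_haplotype_survey()
  hc <- homoplasmic_counts(cat3)
  expect_equal(hc[["DL-DL"]],
               c("1" = 4, "6" = 8, "9" = 12, "10" = 2))
  expect_equal(hc[["KM-SM"]],
               c("1" = 4, "3" = 1, "4" = 0, "6" = 3, "10" = 2, "11" = 0,
                 "12" = 0))
  # population without hets is untouched
  expect_equal(hc[["BS-BS"]], cat3$counts[["BS-BS"]])
  # subtraction below zero is a data inconsistency, not a silent fix
  bad <- haplotype_catalog(list(p = c(a = 1, b = 4)),
                           hets = data.frame(population = "p",
                                             hap1 = "a", hap2 = "b"))
  bad$hets <- rbind(bad$hets, bad$hets)
  expect_error(homoplasmic_counts(bad), "below zero")
})

test_that("mixtures classify as local, global or unexplained", {
  cat3 <- read_haplotype_survey()
  expect_equal(classify_mixture(c("1", "6"), "DL-DL", cat3), "local")
  # haplotype 10's only Kaiyuan copy sits inside the heterozygote itself
  expect_equal(classify_mixture(c("1", "10"), "HH-KY", cat3), "global")
  expect_equal(classify_mixture(c("4", "12"), "KM-SM", cat3), "unexplained")
  expect_error(classify_mixture(c("1", "99"), "DL-DL", cat3), "unknown")
  expect_error(classify_mixture(c("1", "1"), "DL-DL", cat3), "distinct")
})

test_that("the full survey classifies into 3 local, 5 global, 2 unexplained", {
  cls <- classify_mixtures(read_haplotype_survey())
  key <- function(d) unique(paste(d$hap1, d$hap2, sep = "/"))
  expect_setequal(key(cls[cls$class == "local", ]),
                  c("1/6", "10/6", "7/9"))
  expect_setequal(key(cls[cls$class == "global", ]),
                  c("1/10", "11/6", "10/7", "3/6", "11/8"))
  expect_setequal(key(cls[cls$class == "unexplained", ]),
                  c("12/4", "11/4"))
  expect_equal(length(key(cls[cls$class == "local", ])), 3L)
  expect_equal(length(key(cls[cls$class == "unexplained", ])), 2L)
})

test_that("a local mixture would still classify as global without its population", {
  cat3 <- read_haplotype_survey()
  cls <- classify_mixtures(cat3)
  loc <- cls[cls$class == "local", ]
  for (i in seq_len(nrow(loc))) {
    drop <- cat3
    keep <- setdiff(names(drop$counts), loc$population[i])
    drop$counts <- drop$counts[keep]
    drop$sizes <- drop$sizes[keep]
    drop$hets <- drop$hets[drop$hets$population != loc$population[i], ]
    # both haplotypes still present in homoplasmic isolates elsewhere
    hc <- homoplasmic_counts(drop)
    tot <- Reduce(`+`, lapply(names(hc), function(p) {
      v <- stats::setNames(numeric(12), as.character(1:12))
      v[names(hc[[p]])] <- hc[[p]]; v
    }))
    expect_true(all(tot[c(loc$hap1[i], loc$hap2[i])] >= 1))
  }
})

test_that("catalog_from_genotypes applies the two-copy convention", {
  gm <- genotype_matrix(data.frame(
    isolate_id = c("i1", "i2", "i3"), population = "p1",
    cox3 = c("h1", "h1/h6", "h6")))
  cat <- catalog_from_genotypes(gm, "cox3")
  expect_equal(cat$counts$p1, c(h1 = 3, h6 = 3))
  expect_equal(nrow(cat$hets), 1L)
  expect_equal(classify_mixture(c("h1", "h6"), "p1", cat), "local")
})
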