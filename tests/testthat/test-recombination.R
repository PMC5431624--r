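# Multilocus clonality statistics, permutation nulls, phylogenetic
# compatibility, clone correction, sites-as-loci conversion.

test_that("mismatch distance counts differing shared loci", {
  expect_equal(mismatch_distance(c("A", "B"), c("A", "B")), 0)
  expect_equal(mismatch_distance(c("A", "B"), c("a", "b")), 2)
  expect_equal(mismatch_distance(c("A", "B"), c("a", "B")), 1)
  expect_equal(mismatch_distance(c("A", NA), c("a", "b")), 1)
  expect_warning(d <- mismatch_distance(c("A", NA), c(NA, "b")), "undefined")
  expect_true(is.na(d))
  expect_error(mismatch_distance(c("A"), c("A", "B")), "loci")
})

test_that("IA and rbarD match the hand-computed two-founder values", {
  st <- ia_rbard(two_founder_gm())
  expect_equal(st$V_O, 8 / 9)
  expect_equal(st$V_E, 4 / 9)
  expect_equal(st$IA, 1)
  expect_equal(st$rbarD, 1)
})

test_that("degenerate inputs are flagged, not mangled", {
  # single polymorphic locus: V_O equals V_E identically, IA = 0
  one <- genotype_matrix(data.frame(L1 = c("a", "a", "b", "b")))
  st <- ia_rbard(one)
  expect_equal(st$IA, 0)
  expect_true(is.na(st$rbarD))
  # monomorphic data: undefined
  mono <- genotype_matrix(data.frame(L1 = rep("a", 4), L2 = rep("b", 4)))
  expect_false(ia_rbard(mono)$defined)
  expect_error(ia_rbard(genotype_matrix(data.frame(L1 = "a"))), "2 isolates")
  # heteroplasmic entries are excluded with a message
  het <- genotype_matrix(data.frame(L1 = c("a/b", "a", "b", "a"),
                                    L2 = c("x", "y", "x", "y")))
  expect_message(ia_rbard(het), "excluded")
})

test_that("IA and rbarD agree with a brute-force pair-loop computation", {
  set.seed(13)
  for (k in 1:15) {
    gm <- genotype_matrix(data.frame(
      L1 = sample(letters[1:3], 12, replace = TRUE),
      L2 = sample(LETTERS[1:4], 12, replace = TRUE),
      L3 = sample(c("x", "y"), 12, replace = TRUE)))
    st <- ia_rbard(gm)
    if (!st$defined || is.na(st$rbarD)) next
    bf <- brute_ia(gm)
    expect_equal(st$IA, bf$IA)
    expect_equal(st$rbarD, bf$rbarD)
    expect_gte(st$rbarD, -1)
    expect_lte(st$rbarD, 1)
  }
})

test_that("IA and rbarD are invariant to relabeling and reordering", {
  set.seed(29)
  gm <- genotype_matrix(data.frame(
    L1 = sample(c("a", "b", "c"), 20, replace = TRUE),
    L2 = sample(c("p", "q"), 20, replace = TRUE)))
  st <- ia_rbard(gm)
  relab <- gm
  relab$L1 <- c(a = "zz", b = "m", c = "k")[relab$L1]
  relab$L2 <- c(p = "2", q = "1")[relab$L2]
  relab <- genotype_matrix(as.data.frame(relab)[sample(20), ])
  st2 <- ia_rbard(relab)
  expect_equal(st2$IA, st$IA)
  expect_equal(st2$rbarD, st$rbarD)
})

test_that("within-locus shuffles preserve allele multisets in place", {
  set.seed(17)
  gm <- genotype_matrix(data.frame(
    L1 = c(sample(c("a", "b"), 19, replace = TRUE), NA),
    L2 = sample(c("x", "y", "z"), 20, replace = TRUE)))
  pm <- permute_matrix(gm, seed = 5)
  for (l in loci(gm)) {
    expect_identical(sort(pm[[l]][!is.na(pm[[l]])]),
                     sort(gm[[l]][!is.na(gm[[l]])]))
    expect_identical(is.na(pm[[l]]), is.na(gm[[l]]))
  }
  # single isolate: nothing to shuffle
  one <- genotype_matrix(data.frame(L1 = "a", L2 = "x"))
  expect_identical(as.data.frame(permute_matrix(one, seed = 1)),
                   as.data.frame(one))
})

test_that("the IA permutation test separates clonal from recombined data", {
  clonal <- two_founder_gm(10)  # n = 20, complete association
  it <- ia_test(clonal, n_perm = 500, seed = 7)
  expect_lte(it$p, 0.01)
  expect_equal(length(it$perm_IA), 500L)
  # mean permuted IA hovers near the null expectation of 0
  expect_lt(abs(mean(it$perm_IA)),
            3 * stats::sd(it$perm_IA) / sqrt(length(it$perm_IA)))
  expect_error(ia_test(clonal, n_perm = 0), "n_perm")
  # reproducible given the seed
  it2 <- ia_test(clonal, n_perm = 100, seed = 3)
  it3 <- ia_test(clonal, n_perm = 100, seed = 3)
  expect_identical(it2$perm_IA, it3$perm_IA)
})

test_that("pairwise compatibility implements the marked-box rule", {
  gm3 <- function(a, b) genotype_matrix(data.frame(L1 = a, L2 = b))
  # three of four gametes: compatible
  expect_true(pairwise_compatible(gm3(c("A", "A", "a"), c("B", "b", "B")),
                                  "L1", "L2"))
  # all four gametes: incompatible
  expect_false(pairwise_compatible(gm3(c("A", "A", "a", "a"),
                                       c("B", "b", "B", "b")), "L1", "L2"))
  # multi-allele 6-cycle (1,x)(2,x)(2,y)(3,y)(3,z)(1,z): incompatible
  cyc <- gm3(c("1", "2", "2", "3", "3", "1"),
             c("x", "x", "y", "y", "z", "z"))
  expect_false(pairwise_compatible(cyc, "L1", "L2"))
  expect_false(oracle_compatible(data.frame(a = c("1", "2", "2", "3", "3", "1"),
                                            b = c("x", "x", "y", "y", "z", "z"))))
  # a star of combinations sharing one allele is always tree-like
  expect_true(pairwise_compatible(gm3(c("A", "A", "A"), c("x", "y", "z")),
                                  "L1", "L2"))
})

test_that("the forest test agrees with the marked-box path oracle", {
  set.seed(19)
  for (k in 1:300) {
    gm <- random_two_locus_gm(sample(4:30, 1), sample(2:5, 1),
                              sample(2:5, 1))
    combos <- unique(data.frame(a = gm$locj, b = gm$lock,
                                stringsAsFactors = FALSE))
    expect_identical(pairwise_compatible(gm, "locj", "lock"),
                     oracle_compatible(combos),
                     label = paste("case", k))
  }
})

test_that("PcP counts compatible pairs and the permutation test is directional", {
  # two biallelic loci with all four gametes: PcP = 0
  four <- genotype_matrix(data.frame(L1 = c("A", "A", "a", "a"),
                                     L2 = c("B", "b", "B", "b")))
  expect_equal(pcp(four), 0)
  expect_error(pcp(genotype_matrix(data.frame(L1 = c("a", "b")))), "2 loci")
  # clonal data: no incompatibility, fewer than in recombined shuffles
  clonal <- genotype_matrix(data.frame(
    L1 = rep(c("A", "a", "q"), each = 8),
    L2 = rep(c("B", "b", "r"), each = 8),
    L3 = rep(c("C", "c", "s"), each = 8)))
  expect_equal(pcp(clonal), 1)
  inc <- incompatibility_test(clonal, n_perm = 200, seed = 11)
  expect_equal(inc$n_incompatible, 0)
  expect_lt(inc$p, 0.05)
  # panmictic data sit inside their own shuffle distribution
  set.seed(23)
  pan <- genotype_matrix(data.frame(
    L1 = sample(c("A", "a"), 40, replace = TRUE),
    L2 = sample(c("B", "b"), 40, replace = TRUE),
    L3 = sample(c("C", "c"), 40, replace = TRUE)))
  expect_gt(incompatibility_test(pan, n_perm = 200, seed = 13)$p, 0.05)
  expect_error(incompatibility_test(clonal, n_perm = 0), "n_perm")
})

test_that("clone correction keeps one lexicographically first representative", {
  gm <- genotype_matrix(data.frame(
    isolate_id = c("z9", "a1", "m5", "b2"), population = "p",
    L1 = c("A", "A", "a", "A"), L2 = c("B", "B", "b", "B")))
  cc <- clone_correct(gm)
  expect_equal(cc$isolate_id, c("a1", "m5"))
  expect_identical(as.data.frame(clone_correct(cc)), as.data.frame(cc))
  # all-unique matrix unchanged
  uniq <- genotype_matrix(data.frame(L1 = c("a", "b"), L2 = c("x", "x")))
  expect_equal(nrow(clone_correct(uniq)), 2L)
})

test_that("a 299-isolate sample with 32 founder genotypes clone-corrects to 32", {
  set.seed(37)
  founders <- data.frame(
    L1 = sample(letters[1:8], 32, replace = TRUE),
    L2 = sample(LETTERS[1:8], 32, replace = TRUE),
    L3 = sprintf("g%02d", 1:32))  # forces 32 distinct multilocus genotypes
  cfg <- sim_config(299, loci = list(
    L1 = list(alleles = letters[1:8], freqs = rep(1 / 8, 8)),
    L2 = list(alleles = LETTERS[1:8], freqs = rep(1 / 8, 8)),
    L3 = list(alleles = sprintf("g%02d", 1:32), freqs = rep(1 / 32, 32))),
    mode = "clonal", founders = founders, seed = 3)
  gm <- simulate_genotype_matrix(cfg)
  expect_equal(nrow(gm), 299L)
  expect_equal(nrow(clone_correct(gm)), 32L)
})

test_that("alignments convert to per-site locus matrices", {
  aln <- c(s1 = "AACGT", s2 = "AACGA", s3 = "ATCGA", s4 = "ATCGT")
  gm <- sites_to_loci(aln)
  expect_s3_class(gm, "genotype_matrix")
  expect_equal(loci(gm), c("site_2", "site_5"))
  expect_equal(as.vector(table(gm$site_2)[c("A", "T")]), c(2L, 2L))
  # monomorphic alignment: nothing to test
  expect_equal(nrow(sites_to_loci(rep("ACGT", 3))), 0L)
  # ambiguity codes must be phased away first
  expect_error(sites_to_loci(c("ACRT", "ACGT")), "phase")
  # four polymorphic sites yield a 4-locus matrix
  set.seed(5)
  base <- sample(c("A", "C", "G", "T"), 341, replace = TRUE)
  seqs <- vapply(1:10, function(i) {
    s <- base
    for (p in c(20, 100, 200, 300)) if (stats::runif(1) < 0.5)
      s[p] <- setdiff(c("A", "C", "G", "T"), base[p])[1]
    paste(s, collapse = "")
  }, character(1))
  expect_equal(length(loci(sites_to_loci(seqs))), 4L)
})

test_that("association p-values fall as the clonal fraction rises", {
  loci4 <- lapply(1:4, function(i) list(alleles = c("a", "b"),
                                        freqs = c(0.5, 0.5)))
  names(loci4) <- paste0("L", 1:4)
  founders <- data.frame(L1 = c("a", "b"), L2 = c("a", "b"),
                         L3 = c("a", "b"), L4 = c("a", "b"))
  mean_p <- vapply(c(0, 0.25, 1), function(cf) {
    ps <- vapply(1:12, function(r) {
      cfg <- sim_config(40, loci4, mode = "mixed", clonal_fraction = cf,
                        founders = founders, seed = 100 * r + round(100 * cf))
      ia_test(simulate_genotype_matrix(cfg), n_perm = 99,
              seed = r)$p
    }, numeric(1))
    mean(ps)
  }, numeric(1))
  expect_true(mean_p[2] < mean_p[1])
  expect_true(mean_p[3] < mean_p[2])
})

test_that("the umbrella report assembles all clonality statistics", {
  clonal <- two_founder_gm(8)
  rep <- recomb_test(clonal, n_perm = 99, seed = 2)
  expect_s3_class(rep, "recomb_report")
  expect_equal(rep$IA, 1)
  expect_equal(rep$rbarD, 1)
  expect_lte(rep$p_IA, 0.05)
  expect_equal(rep$PcP, 1)  # two biallelic loci, only 2 gametes observed
  sm <- summary(rep)
  expect_equal(sm$n, 16)
  # clone correction reduces to distinct genotypes before testing
  dup <- genotype_matrix(data.frame(
    L1 = rep(c("A", "a", "A", "a"), each = 4),
    L2 = rep(c("B", "b", "b", "B"), each = 4)))
  cc <- recomb_test(dup, n_perm = 99, seed = 2, clone_correct = TRUE)
  expect_equal(cc$n_isolates, 4)
})
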