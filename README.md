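# mitohet

Mitochondrial heteroplasmy detection, haplotype phasing and recombination
tests for haploid (fungal) population samples.

In most sexual eukaryotes mitochondria are inherited from a single parent,
so an individual normally carries one mitochondrial genotype (homoplasmy).
Field surveys of the basidiomycete mushroom *Thelephora ganbajun* broke that
expectation: Sanger chromatograms of mitochondrial genes showed clean
"double peaks" at specific sites (two bases present in one fruiting body),
intron presence/absence typing found both COX1 intron variants in most
individuals, and multilocus allele associations pointed to mitochondrial
recombination. `mitohet` packages the complete computational chain such a
study needs:

* **Double-peak calling** (`call_trace`, `call_site`, `noise_floor`) — a
  site is heterozygous when both of its two tallest trace channels exceed
  `k`× the local noise floor (windowed median of non-maximal channels,
  default `k = 3`, window 5 sites each side) *and* the minor/major height
  ratio is at least `r = 0.2`. Replicate reads are reconciled with
  `confirm_heteroplasmy`; `singleton_audit` flags one-isolate variants for
  chromatogram re-inspection.
* **Haplotype phasing and mixture classification** (`em_phase`,
  `consistent_pairs`, `classify_mixture`) — heteroplasmic IUPAC sequences
  are resolved into haplotype pairs by Excoffier–Slatkin-style EM over
  haplotype frequencies, using the homoplasmic isolates as references.
  Each resolved mixture (h₁, h₂) is classified *local* (both haplotypes
  occur in homoplasmic isolates of the same population), *global* (both
  occur somewhere in the sample) or *unexplained*.
* **Relative copy number from qPCR** (`relative_copy_number`,
  `summarize_panel`, `major_minor_ratio`) — with a single-copy nuclear
  reference at 2 copies per dikaryotic cell and idealised doubling per
  cycle, a common fluorescence threshold gives
  `Ln·Nn·2^ctn = Lm·Nm·2^ctm`, hence

  ```
  Nm = (2 · Ln · 2^ctn) / (Lm · 2^ctm)
  ```

  copies per cell for a mitochondrial amplicon of length `Lm` with
  threshold cycle `ctm` against the nuclear reference (`Ln`, `ctn`).
* **Clonality and recombination statistics** (`ia_rbard`, `ia_test`,
  `pairwise_compatible`, `pcp`, `incompatibility_test`, `clone_correct`,
  `recomb_test`) — the index of association `I_A = V_O/V_E − 1` and its
  locus-count-corrected form `r̄_d = (V_O − V_E)/(2·Σ_{j<k}√(var_j·var_k))`,
  with significance from 500 within-locus allele shuffles; pairwise
  phylogenetic compatibility as a generalised four-gamete ("marked box")
  test implemented as acyclicity of the bipartite allele graph; `PcP`, the
  proportion of compatible locus pairs; and clone correction to one
  representative per multilocus genotype. `sites_to_loci` turns an
  alignment into a per-polymorphic-site locus matrix for intra-genic tests.
* **Synthetic data** (`simulate_genotype_matrix`, `inject_heteroplasmy`,
  `simulate_trace`, `simulate_ct`, `amplicon_detected`) — seeded
  generators for clonal/panmictic/mixed genotype matrices, two-haplotype
  trace mixtures with a mixing fraction, and Ct panels that invert the
  copy-number equation exactly, so every stage is testable end to end.

Two plain-text fixtures ship with the package: the published COX3
haplotype survey (per-population copy counts and heteroplasmic genotypes
for 284 isolates from 27 Yunnan populations; `read_haplotype_survey()`)
and the published mean Ct panel for six isolates (`read_ct_survey()`).

## Worked example

```r
library(mitohet)

# qPCR: per-cell copy numbers for isolate SL3-13 from its mean Ct values
summarize_panel(read_ct_survey()[["SL3-13"]])
#> Relative copy numbers per cell (vs 2-copy nuclear reference):
#>   12S          150.4  (sd omitted)
#>   COX1-ex3     164.3  (sd omitted)
#>   COX1-alpha   4.477e-05  (sd omitted)
#>   COX1-beta    14.02  (sd omitted)
```

About 150 mitochondrial genomes per cell (12S and COX1 exon 3 agree), with
the β intron at ~14 copies per cell and the α intron essentially absent
(~4.5 × 10⁻⁵): this isolate is β-major, and the minor type only becomes
PCR-visible at high cycle numbers (`amplicon_detected`).

```r
# classify every heteroplasmic COX3 genotype in the packaged survey
table(classify_mixtures(read_haplotype_survey())$class)
#>      global       local unexplained
#>           7           3           2
```

Of the 12 heteroplasmic isolates, 3 carry mixtures explainable by two
homoplasmic isolates of their own population, 7 (5 distinct genotypes) are
explainable only at the whole-sample level, and 2 contain a haplotype
never observed in a homoplasmic isolate.

```r
# clonality statistics on a fully linked two-founder sample
gm <- genotype_matrix(data.frame(L1 = rep(c("A", "a"), each = 10),
                                 L2 = rep(c("B", "b"), each = 10)))
recomb_test(gm, n_perm = 500, seed = 1)
#> Multilocus recombination report (n = 20, 2 loci, 500 permutations)
#>   IA = 1 **   rbarD = 1   PcP = 1
#>   incompatible pairs: 0; P(deficit vs recombined) = 0.001996, P(excess) = 1
```

Complete association (`I_A = r̄_d = 1`), no permutation reaches the
observed `I_A` (p = 1/501), and no locus pair is phylogenetically
incompatible — the signature of clonality.

## Vignette

`vignettes/mitohet-methods.Rmd` documents the models, the operationalised
thresholds, what the synthetic generators do and do not emulate, and the
numerical design choices.
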