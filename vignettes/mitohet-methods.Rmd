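---
title: "Models and methods behind mitohet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitohet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitohet)
```

`mitohet` implements the computational chain of a mitochondrial
heteroplasmy and recombination survey in a haploid fungal population:
calling heterozygous ("double peak") sites from Sanger-style trace
profiles, resolving heteroplasmic sequences into haplotype pairs against
homoplasmic references, estimating relative per-cell copy numbers from
qPCR threshold cycles, and testing multilocus genotypes for clonality
versus recombination. This vignette records the models, the tunable
parameters, and the design decisions a maintainer would want explained.

## The double-peak caller

A Sanger chromatogram read of a heteroplasmic template shows two
fluorescence peaks at every site where the two mitochondrial genotypes
differ. The field rule — both peaks must stand "significantly higher than
the basic noise level at neighbouring homozygous sites" — is qualitative;
we operationalise it with three parameters (`caller_params()`):

* **noise window `w`** (default 5 sites each side): the noise floor at a
  position is the median height of the *non-maximal* channels (the three
  channels below the tallest) over the surrounding window, the focal
  position excluded. Windows truncate at sequence ends. The published
  protocol does not say how many neighbouring sites defined "basic
  noise"; `w = 5` keeps the floor local while spanning enough sites
  (up to 30 channel values) for a stable median.
* **noise multiplier `k`** (default 3): a peak counts as real when its
  height exceeds `k` times the floor. Three-over-noise is the usual
  detection convention; `k` must exceed 1.
* **minor-ratio floor `r`** (default 0.2): the minor peak must also reach
  `r` times the major peak. This second, *relative* threshold is what
  keeps false het calls out when the noise floor is very low (a noise
  spike can clear `k`×floor but never 20 % of a genuine signal peak).

A site is then called `N` when even the tallest peak fails `k`×floor, a
two-base IUPAC code (het) when both rules pass, and the tallest channel's
base otherwise. Ties between equal maximal channels break
lexicographically, so calls are deterministic, and every threshold is
relative, so calls are invariant to uniform rescaling of the trace.
Because minor-peak height scales with the minor haplotype's copy
fraction, the caller's detection limit is `r`: mixtures below a 0.2
minor/major copy ratio are *designed* to be invisible, which is exactly
why the survey protocol also screens rare variants by high-cycle PCR
(`amplicon_detected()`, idealised doubling per cycle) rather than by
chromatogram alone.

Replicate confirmation (`confirm_heteroplasmy()`) intersects het sites
across an independent re-extraction/re-sequencing of the same specimen and
keeps only positions with concordant ambiguity codes.
`singleton_audit()` lists sites whose rare base occurs in exactly one
isolate — the standard re-inspection list before accepting a singleton
polymorphism.

## Phasing heteroplasmic sequences

A heteroplasmic isolate's consensus read is the site-wise superposition of
its two haplotypes (`superpose_seqs()`). With abundant homoplasmic
isolates in the sample, resolution is mostly combinatorial:
`consistent_pairs()` returns every catalog pair whose superposition equals
the observed sequence, falling back to novel-haplotype completions of
single catalog matches when no pair fits.

`em_phase()` handles the general case by maximum likelihood: haplotype
frequencies `p` are estimated by expectation–maximisation in the style of
Excoffier & Slatkin's haplotype-frequency EM, treating each heteroplasmic
isolate as an unordered pair (likelihood `2·p_a·p_b` summed over
consistent resolutions) and each homoplasmic isolate as two copies of its
haplotype. The coalescent-prior MCMC machinery of dedicated phasing
software is unnecessary here: the task is two-haplotype separation against
many homoplasmic references, where the EM posterior concentrates on the
reference-supported pair after a handful of iterations. Numerical
choices: uniform initialisation over the observed haplotype universe
(deterministic, so runs are reproducible without a seed), convergence when
the largest frequency change drops below `tol` (default 1e-8, iteration
cap 500 with a warning flag on non-convergence), per-isolate pair
expansion capped at 12 ambiguous sites (4096 resolutions) to bound
memory, ties in the maximum-posterior resolution broken lexicographically.
The log-likelihood is non-decreasing across iterations and frequencies sum
to one at every step; both are asserted in the test suite.

## Classifying haplotype mixtures

Copy counts follow the two-copies-per-isolate convention: a homoplasmic
isolate contributes 2 copies of its haplotype, a resolved heteroplasmic
isolate 1 copy of each constituent, so per-population counts sum to twice
the number of typed isolates — this is the convention under which the
packaged COX3 survey's counts reconcile exactly with its population sizes.
`homoplasmic_counts()` subtracts the heterozygote contributions; a
mixture (h₁, h₂) observed in population P is then

* **local** when both haplotypes retain count ≥ 1 in P,
* **global** when both retain count ≥ 1 somewhere in the sample,
* **unexplained** otherwise.

The subtraction matters: a haplotype whose only local copy sits inside the
heterozygote itself does not count as locally available (that is what
distinguishes a local from a global mixture in the packaged survey), and
the ≥ 1 threshold *after* subtraction reproduces every published local and
global annotation, including the case where a single residual copy in
another population is the sole global support. One oddity of the survey
is treated as given data: one population carries an odd total copy count
for one haplotype, which cannot arise under the pure two-copy convention;
the reader reports reconciliation failures but never silently repairs
them.

## Relative copy number from qPCR

With amplification efficiency idealised at exactly 2 per cycle, equal
fluorescence at threshold means equal amplified mass, and mass is
proportional to amplicon length times molecule count:
`Ln·Nn·2^ctn = Lm·Nm·2^ctm`. Fixing the nuclear single-copy reference at
`Nn = 2` copies per dikaryotic cell gives

\[ N_m = \frac{2\,L_n\,2^{ct_n}}{L_m\,2^{ct_m}}. \]

`summarize_panel()` pairs replicate *i* of the target with replicate *i*
of the reference, computes a copy number per replicate and reports
mean ± SD; when replicate counts differ it falls back to mean Ct values
and omits the SD. Only replicate means are published for the packaged
survey, so recomputations from it match the published per-cell means to
within one published replicate SD (asserted in the tests for all four
mitochondrial amplicons across all six isolates) but cannot match them
exactly. `major_minor_ratio()` divides mean copy numbers; the published
counterpart averaged per-replicate ratios, so order-of-magnitude agreement
is the right expectation there (Jensen's inequality separates the two
definitions by up to ~10 % at the observed replicate scatter).

## Clonality and recombination statistics

For multilocus haploid genotypes, let `d_j` be the mismatch indicator of
locus `j` over all isolate pairs and `D = Σ_j d_j` the multilocus mismatch
distance. With `V_O` the variance of `D` over pairs and
`V_E = Σ_j var(d_j)` its linkage-equilibrium expectation,

* index of association `I_A = V_O/V_E − 1`,
* `r̄_d = (V_O − V_E) / (2 Σ_{j<k} √(var_j var_k))`, the covariance excess
  rescaled by its maximum, bounded in [−1, 1] and comparable across locus
  counts.

All variances use the population (1/n_pairs) denominator, matching the
Multilocus/Agapow–Burt convention; a `variance = "sample"` switch is
exposed because the convention is undocumented in parts of the
literature, but both statistics are denominator-ratio invariant, so the
switch exists for transparency rather than effect. Monomorphic data
(`V_E = 0`) return an undefined-flagged result instead of dividing by
zero; a single locus gives `I_A = 0` identically and no `r̄_d`.

Significance comes from within-locus allele shuffling
(`permute_matrix()`): alleles are permuted across isolates independently
per locus, preserving allele proportions exactly while destroying
between-locus associations — an artificially recombined sample. The
one-sided p-value `(1 + #{perm I_A ≥ obs})/(1 + n_perm)` (default
`n_perm = 500`) never returns zero. Under the null the expected permuted
`I_A` is exactly 0 because per-locus variances are permutation-invariant
and cross-locus covariances vanish in expectation.

Phylogenetic compatibility (`pairwise_compatible()`) generalises the
four-gamete test: mark every observed allele combination in an
alleles-by-alleles matrix; the loci are incompatible when a marked box can
be left and re-entered via alternating horizontal/vertical moves through
other marked boxes. That cycle condition is exactly graph-theoretic
acyclicity of the bipartite allele graph with observed combinations as
edges, which is how it is implemented (via igraph); the naive marked-box
path enumeration survives as an independent oracle in the test suite,
where the two agree on 1000+ random locus pairs. `pcp()` reports the
proportion of compatible pairs. The incompatibility permutation test
compares the observed count of incompatible pairs with shuffled samples;
because the literature states the two nulls in opposite directions ("no
recombination" for the compatibility argument, "free recombination" for
the shuffle), `incompatibility_test()` reports both tails, with the
deficit tail (`observed ≤ permuted`, evidence of less recombination than
free shuffling) as the primary `p`.

Heteroplasmic entries carry no single haplotype, so they are excluded
(blanked with a message) from all association statistics by default; the
phasing module exists precisely to resolve them first when they should be
kept. Missing data are handled by pairwise deletion: distances use the
loci shared by a pair, compatibility uses the isolates scored at both
loci. `clone_correct()` reduces the sample to one representative (the
lexicographically smallest isolate id — deterministic and idempotent) per
distinct multilocus genotype before association testing, the standard
guard against clonal pseudo-replication.

## What the synthetic generators emulate

`simulate_genotype_matrix()` produces the two regimes the tests need —
clonal (founder replication: complete linkage) and panmictic (independent
per-locus draws: linkage equilibrium) — plus their mixture via
`clonal_fraction`. `inject_heteroplasmy()` selects isolates by a Bernoulli
rate and makes each heteroplasmic at exactly one locus (field surveys of
this system found heteroplasmy at different genes largely not
co-occurring), drawing the second allele from the population's allele
pool and recording the truth for recovery scoring. The default rate
regime used in tests, ~12/284 ≈ 4 %, mirrors the observed COX3
heteroplasmy frequency; the true mixing fractions behind observed double
peaks are unpublished, so the default `mixing_fraction = 0.4` is a free
parameter chosen to sit well above the caller's `r = 0.2` detection
floor while remaining visibly asymmetric, and tests probe both sides of
the floor (0.4 and 0.05).

`simulate_trace()` models peak heights only: major channel mean `signal`,
minor channel mean `signal × mixing_fraction` at differing sites, all
channels plus half-normal noise (a centred Gaussian truncated at zero —
fluorescence cannot be negative, and no noise model is published). It does
not emulate real chromatogram pathologies: peak-width variation, dye
blobs, mobility shifts, degrading signal along the read, or indel-induced
frame smearing. Passing round-trip tests therefore show the caller's
thresholds are internally consistent, not that real traces are this
clean. `simulate_ct()` inverts the copy-number equation exactly
(`ct_m = ct_n + log2(2·Ln/(Lm·Nm))`) and adds Gaussian replicate jitter;
real qPCR deviates through efficiency < 2 and plate effects, which are
deliberately out of scope (no standard-curve calibration mode).

## Problem sizes and reproducibility

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which the statistical assertions have
comfortable margins: 1000 random locus pairs for the forest-test/oracle
agreement, 50 panmictic samples of 60 isolates × 4 loci with 200
permutations for the type-I error of the `I_A` test (rejection rate
compared with 0.05 within 3 binomial SD), 200-isolate populations with
~30 injected heteroplasmies for EM recovery (≥ 95 % required), and
20 traces of 120 sites with 5 differing sites each for caller
round-trips. A single integer seed drives every stochastic step; the
published per-isolate multilocus genotypes live only in sequence-archive
accessions, so the published survey-level `I_A`/`r̄_d`/`PcP` table is not
recomputable here — the statistics are instead validated against
hand-computed examples, brute-force oracles and their sampling-theory
properties.

## Known limitations

* The caller assumes four clean channels per site; it reads peak tables,
  not binary chromatogram files, and models no base-quality scores or
  indels.
* EM phasing treats haplotypes as unlinked to population labels (one
  frequency pool); with strong population structure and very rare local
  haplotypes, the maximum-posterior resolution can prefer a globally
  common pair.
* The copy-number model fixes efficiency at 2; systematic efficiency
  differences between amplicons bias `N_m` multiplicatively.
* `I_A`/`r̄_d` p-values assume exchangeable isolates within the sample;
  clone correction mitigates, but does not remove, clonal structure
  within populations.
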