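---
title: "gbskit: models and design choices for two-enzyme GBS marker discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gbskit: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbskit)
```

gbskit implements the computational side of a two-enzyme
genotyping-by-sequencing (GBS) study: choosing an enzyme pair by in silico
digestion, predicting marker yield, cleaning reads, filtering SNP calls,
validating genotypes against an independent assay, annotating markers, and
running a single-marker association scan with a REML variance partition.
This vignette records the models behind each step, the parameters that
matter, and the design decisions taken where the underlying procedures are
ambiguous or under-specified.

## In silico digestion

A restriction enzyme is its IUPAC recognition site plus a top-strand cut
offset (`EcoRI` G^AATTC, `NlaIII` CATG^, `PstI` CTGCA^G, `ApeKI` G^CWGC,
`BstNI` CC^WGG). Cut positions are the 0-based coordinates
`match_start + cut_offset`; overlapping degenerate matches all count, and an
`N` in the sequence never satisfies a non-N pattern position. Site matching
is delegated to `Biostrings::matchPattern()` with the subject held literal;
the test suite checks it against an independent naive sliding-window
matcher.

Conventions worth knowing:

* Coordinates are 0-based half-open throughout the digestion module, so
  fragment tables export directly as BED. GFF3 and VCF positions elsewhere
  in the package stay 1-based, as those formats require.
* Cuts are computed on the top strand only. All five built-in enzymes are
  palindromic, so the restriction *site* map is strand-symmetric; the cut
  positions themselves shift by the overhang `width - 2 * offset` under
  reverse complement. Consequently the fragment length multiset of a
  reverse-complemented sequence mirrors exactly only for blunt cutters; for
  the built-ins it agrees up to that fixed shift. This is a property of
  staggered cutting, not an implementation artifact, and the tests assert
  the shifted relation explicitly.
* When both enzymes cut at the same coordinate, one cut is kept and the
  first enzyme passed to `double_digest()` takes labelling priority.
* Fragments that are mostly ambiguous sequence (> 50% N) are flagged, not
  removed; real assemblies contain N runs and the right treatment is the
  caller's decision.
* `length_histogram()` defaults to 100 bp bins up to 1 kb with everything
  longer pooled in a final overflow bar — the convention used when
  comparing enzyme combinations by their fragment length distribution.
* The default size-selection window is 200-300 bp inclusive, the window a
  two-enzyme GBS library is typically cut to. `size_select()` exposes three
  end filters because protocols differ in which fragments actually
  sequence: `any` (used for distribution assessment), `both_sites`, and
  `mixed_ends` (the classic rare/common library). Which end classes enter a
  sequenced library is rarely stated in study reports, so none is hard-wired
  into downstream steps.

## Expected marker yield

The design arithmetic is deliberately simple: `n_fragments x fragment_len x
snp_rate` expected SNPs. With 1.5 million fragments, 200 bp per fragment and
1 SNP per kb this gives 300,000 — the back-of-envelope scale for an
EcoRI-NlaIII library on a ~700 Mb fish genome. `fragment_len` defaults to
the lower bound of the size window (200 bp), the conservative reading under
which that arithmetic is exact.

Sequencing depth per locus per sample is modelled as Poisson with a shared
mean λ; a locus is detected in a sample when its depth reaches the threshold
t, so the per-sample detection probability is the Poisson upper tail
P(D ≥ t). Samples are independent, so the number of samples covering a locus
is Binomial(n, p) and the expected count of loci shared by at least m of n
samples is `L * P(Binom(n, p) >= m)`. Both assumptions are approximations —
real GBS depth is overdispersed and samples share library effects — and a
negative-binomial depth option (`overdispersion`, the NB size) is exposed
for sensitivity analysis, off by default. `saturation_curve()` converts a
per-sample sequencing amount into λ (`amount / library_bp`) and traces the
expected shared-SNP count, which rises monotonically and plateaus at the
locus count; only these shape properties are claimed, since the plateau
level of any real study depends on its data.

## The synthetic-data generators

Every downstream module is tested against generated data with exact truth
sidecars, deterministic under `sim_config(seed=)`. The defaults are
desk-scale but keep the ratios of a 500-sample teleost GBS study:

* genome 2 Mb in 2 chromosomes, with EcoRI/NlaIII sites planted at 2 per kb
  and every accidental site occurrence scrubbed, so the planted map **is**
  the digestion truth (`find_cut_positions()` recovers exactly the planted
  cuts);
* 1 SNP per kb, alternate-allele frequencies uniform on [0.05, 0.5],
  Hardy-Weinberg genotypes — about 2,000 loci;
* Poisson depth (λ = 10), depth-0 and an extra 2% of calls missing, 5% of
  true heterozygotes miscalled to a random homozygote (heterozygote dropout
  is the dominant discordance mode seen in GBS validation assays), site
  QUAL lognormal with 5% mass below 100;
* a quantitative trait with marginal mean 21.5 and SD 4.1 (the mg/g scale
  of a muscle EPA+DHA phenotype), 39 causal loci carrying 63% of the total
  additive variance, a polygenic background on the remaining loci, balanced
  binary sex with a small fixed effect (0.5 mg/g — studies use sex as a
  covariate without reporting its effect, so a small non-zero value keeps
  the covariate non-trivial), and heritability 0.5 (mid-range for fish
  body-composition traits; the source data report no estimate).

The generator draws causal effects N(0,1), rescales the polygenic
background so the causal subset's realised share of additive variance hits
the target, scales noise for the requested heritability, and finally scales
the whole trait to the requested marginal SD. The realised causal fraction
is returned as truth for recovery tests.

What the generator does **not** emulate — and therefore what passing tests
cannot show about real data: linkage disequilibrium (loci are independent),
family structure (the real 30-sire x 30-dam design induces relatedness; an
equivalent pedigree is not reconstructible from published information),
base-level sequencing error in reads, allele-specific dropout, and PCR
duplicates. Results on real data will be noisier in exactly these
directions.

Simulated read pairs start with the post-cut remnant of the enzyme at each
fragment end (`AATTC`, `CATG`) and carry truth labels for injected QC
violations, one per pair: a broken prefix, >5% N, mean quality below 20, or
a low-quality tail long enough that trimming leaves under 50 bp.

## Read quality control

The cleaning rules run in a fixed order: site-prefix retention, the
N-fraction filter, then (1) drop reads with quality below 20, (2) trim 5 bp
windows from read ends whose mean quality is below 20, (3) drop pairs with
a mate under 50 bp. Three readings had to be fixed:

* "quality lower than 20" is taken as **mean per-read** Phred below 20; a
  per-base reading would discard nearly every real read.
* Windows are removed from the 3' end only, in non-overlapping 5 bp steps,
  with a final partial window trimmed if its mean is below threshold.
  A low-quality tail that is not window-aligned therefore removes whole
  windows, slightly more than the tail itself.
* Any failing mate drops the whole pair (rule 3 is explicitly pair-level;
  the same semantics are applied to the other rules for consistency). The
  site-prefix check applies to both mates by default with a flag
  (`both_mates = FALSE`) to relax, since protocols differ on whether the
  second mate starts at a cut site.

The N rule is strict ("more than 5%"): a 100 bp read with exactly 5 N is
kept. QC is idempotent — re-running it on its own output changes nothing.

## Composite SNP filtering

A genotype call needs depth ≥ 5 (sub-threshold calls are masked to
missing), a site needs QUAL ≥ 100 and non-missing calls in at least
`ceiling(0.8 * n)` samples. Two documented readings:

* Threshold comparisons are inclusive: "depth higher than 5" and "depth
  threshold of 5" are used interchangeably in GBS practice, so ≥ is used
  throughout.
* The population criterion is stated both as "at least 80% of individuals"
  and as "400 individuals (90% of all sample)" in the source material;
  400/500 = 80%, so the default is 0.8 and the 90% phrasing is treated as a
  typo.

Only biallelic SNPs are filtered; indel and multiallelic records pass
through untouched with a warning, since the filter's depth/call-rate
semantics were defined for SNPs. The rejection log partitions removed sites
by the first failing rule (quality before call rate).
`shared_count_table()` evaluates the same retention rule over grids of
depth and call-rate thresholds; each cell equals `apply_snp_filter()` at
those settings, and counts are non-increasing along both axes.

## Genotype concordance

`build_confusion()` tallies pipeline versus assay calls over
{AA, AB, BB, NN}; `summarize_concordance()` computes the success rate
(identical AA/AB/BB calls over all compared loci) and specificity/
sensitivity with TN = both-AA, FP = pipeline non-reference but assay AA,
FN = pipeline AA but assay non-reference, and NN excluded from the four
cells. Two TP definitions are exposed because the published quantities are
ambiguous:

* `detection` (default): both methods non-reference, regardless of AB/BB
  agreement;
* `genotype`: the non-reference genotypes must match exactly, with AB/BB
  disagreements counted as detection failures (false negatives).

On the published croaker validation table (`croaker_validation_table()`,
1,500 genotypes), both definitions reproduce 1,421 concordant calls and a
94.7% success rate exactly. The published specificity (94.2%) and
sensitivity (98.3%) are **not** reproducible from that table under any
documented reading: the printed formulas give 901/955 = 94.3% specificity
and 529/531 = 99.6% (detection) or 520/531 = 97.9% (genotype) sensitivity.
The prose description of the two statistics also swaps their wording
relative to the displayed formulas; the formulas govern here, and the
residual 0.1-1.3 point gaps are reported as they are rather than tuned
away. A plausible explanation is that the published values were computed on
the per-locus supplementary genotypes with additional exclusions that the
table does not encode.

## SNP annotation

Location classes follow the precedence CDS-exon > UTR > intron >
intergenic, with UTR sides taken from the `five_prime_UTR` /
`three_prime_UTR` features (strand-resolved by the annotation itself). A
locus inside a gene span but in none of those features is an intron; this
includes non-coding-exon positions when the annotation lacks UTR features,
which is the usual convention for sparse GFF3s. Effects are classified by
rebuilding the spliced CDS from the genome, substituting the allele on the
coding strand and translating with the standard genetic code; CDS models
whose length is not a multiple of 3 produce a warning and `NA`. Against
multiple transcripts the most severe class wins
(stop_gained > frameshift > start_lost > stop_lost > missense >
synonymous). Frameshift is reserved for length-changing alleles with
`|len(ref) - len(alt)|` not divisible by 3 — a pure substitution can never
be a frameshift; in-frame indels are left `NA` rather than forced into a
substitution category.

## Association and variance partitioning

Population structure diagnostics use identity-by-state distances
(`1 - shared_alleles / (2 * compared_loci)`, with missing genotypes
excluded per pair) embedded by classical MDS (double-centering + spectral
decomposition, via `cmdscale`). The scan itself is ordinary least squares
`y ~ 1 + g + sex` per locus with additive dose coding (AA=0, AB=1, BB=2),
two-sided t test on the genotype coefficient. MDS axes are computable but
deliberately **not** included as scan covariates by default: the modelled
study ran a simple regression with sex only, and the toolkit reproduces
that analysis rather than improving on it (kinship-corrected mixed-model
scans are out of scope). Significance is a fixed inclusive threshold
p ≤ 1e-4 with no multiple-testing correction, again matching the modelled
analysis; Bonferroni and Benjamini-Hochberg options exist but are off by
default.

The variance partition fits `y = Xb + u + e`, `u ~ N(0, sigma_g2 K)`, by
REML on the spectral decomposition of the projected kernel: with S the
projection orthogonal to X, the eigenvectors of S(K+I)S with eigenvalue > 0
rotate the model so the restricted likelihood is a one-dimensional function
of `delta = sigma_e2 / sigma_g2`, maximised by Brent search over
`log(delta)` in [-25, 25] with tolerance 1e-8. Optima at the interval edge
are flagged as boundary solutions (a variance component is effectively
zero) rather than silently reported. K is the VanRaden genomic relationship
matrix (centred, frequency-scaled cross-product; missing genotypes
mean-imputed per locus; fixed and zero-variance loci excluded).

The headline statistic is the ratio `sigma_g2(GRM from the significant
subset) / sigma_g2(GRM from all markers)`, both fits with identical
covariates (intercept + sex). On the synthetic architecture (39 causal
loci, 63% causal share, n = 800, ~2,000 markers) the ratio recovers the
realised causal fraction to within about ±0.12 across seeds; the published
~63% figure from real croaker data depends on that study's genotypes and
phenotypes and is represented here by this recovery property, not
reproduced numerically. `ks_normality()` is the one-sample
Kolmogorov-Smirnov test against a normal with the sample mean and SD,
without a Lilliefors correction for the estimated parameters — the plain
test is what trait-distribution checks in this literature report.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly rather than by convention: empty
fragment lists give all-zero histograms; zero-length reads drop with reason
"empty"; monomorphic loci return `NA` association results with a reason;
sample pairs with no comparable loci get `NA` IBS distance with a warning;
zero kernels raise an error; undefined rates (zero denominators) are `NA`,
never 0. Ties at coincident cut positions resolve by argument order
(documented above). All stochastic tests fix seeds.

The test suite runs at desk scale by design: 2 Mb genomes, up to 800
samples and 100,000 null locus-tests for the calibration check, 20 seeds
for the variance-ratio recovery. These sizes were chosen so the full suite
completes in about two minutes while keeping every statistical check's
Monte-Carlo error well inside its assertion band (binomial 3 SE bands for
rate checks, ±0.12 for the variance ratio).

## A worked end-to-end example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42)
gen <- simulate_genome(cfg)
frags <- digest_genome(gen$genome, "EcoRI", "NlaIII")
library_frags <- size_select(frags, 200, 300, "any")

pop <- simulate_population(cfg, gen)
obs <- simulate_observations(pop)
kept <- apply_snp_filter(obs$genotypes, obs$depth, obs$qual, filter_policy())

ph <- simulate_phenotype(pop)
scan <- gwas_scan(kept$genotypes, ph$pheno)
hits <- significant_hits(scan, alpha = 1e-4)
variance_explained_ratio(ph$pheno$trait, pop$genotypes, ph$causal,
                         X = cbind(1, ph$pheno$sex))
```

## Known limitations

Methylation sensitivity (EcoRI's CpG behaviour), star activity and partial
digestion are not modelled; digestion is exact. Non-palindromic user
enzymes get a top-strand-only restriction map. The yield model ignores
allele dropout at polymorphic cut sites, which in real populations removes
markers non-randomly. The association module offers no mixed-model scan, no
haplotype tests, and no annotation enrichment (those require external
databases). The synthetic population has no LD and no pedigree, so power
and calibration results transfer to real data only qualitatively.
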