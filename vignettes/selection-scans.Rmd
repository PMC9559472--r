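---
title: "Detecting selective sweeps between two populations with sweepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps between two populations with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When two related populations diverge under different selection regimes — for
example two sheep breeds, one selected for high fecundity — loci under
directional selection in one population leave a local footprint: allele
frequencies at the selected site and its linked neighbours are dragged toward
fixation (genetic hitchhiking), which *depresses nucleotide diversity* in the
selected population and *elevates differentiation* between the populations.
`sweepscan` implements the standard two-statistic scan for such footprints:
sliding-window Weir–Cockerham $F_{ST}$ combined with the ratio of window
nucleotide diversity between a reference and a target population, with
candidate regions drawn from the joint tails of both distributions. Around
the scan it provides the supporting stages a real study needs: variant QC,
per-population diversity summaries, LD decay, population structure views
(PCA, neighbour-joining tree), gene annotation of candidate regions, and
exact-test validation of candidate SNPs against trait cohorts.

## Statistics

**Weir–Cockerham $F_{ST}$.** For each biallelic site with $r$ populations,
sample sizes $n_i$, alternate-allele frequencies $p_i$ and observed
heterozygote fractions $h_i$, the method-of-moments variance components are

* $a$ — among populations,
* $b$ — among individuals within populations,
* $c$ — within individuals,

and the per-site estimate is $\hat F_{ST} = a/(a+b+c)$. A window's
*weighted* $F_{ST}$ is the ratio of sums $\sum a / \sum (a+b+c)$ over its
member sites (the estimator vcftools reports as `WEIGHTED_FST`); the plain
mean of per-site ratios is reported alongside. Negative per-site components
are kept in the sums — clamping them at zero would bias window estimates
upward. Sites where any population has no called genotype, or where the
total variance is zero, are undefined and excluded.

**Nucleotide diversity.** Per site, $\pi = 2j(n-j)/(n(n-1))$ for $j$
alternate alleles among $n$ called alleles — the unordered-pair mismatch
fraction. Window $\pi$ is the per-bp sum over member sites, computed
separately in each population from that population's called genotypes. The
scan statistic is the ratio $\pi_{\text{ref}}/\pi_{\text{target}}$: a sweep
in the target population drives the ratio high, one in the reference drives
it low. Both tails are kept; the direction only labels the tail.

**Diversity summaries.** Per population the package reports the mean over
polymorphic sites of PIC
($1-\sum_i P_i^2-\sum_i\sum_{j>i}2P_i^2P_j^2$; maximum $0.375$ for a
biallelic marker), observed heterozygosity, expected heterozygosity
($1-\sum P_i^2$, uncorrected), $\pi$, and the average per-individual variant
count $K$. The printed definition of $K$ in the field is ambiguous; we
implement the literal per-individual mean (number of sites where an
individual carries at least one alternate allele, averaged over
individuals) as the primary column and the classical mean pairwise dosage
difference as a labelled alternative (`k_pairwise`), so either convention
can be compared.

## The joint-tail selection rule

Windows of 100 kb advanced by 50 kb (defaults; configurable) tile each
chromosome from position 1. A window is *rankable* when it holds at least
`min_snps` SNPs (default 3 — single-SNP windows make unstable ratios) and
both statistics are defined. Thresholds are **order-statistic quantiles**
(type 1, no interpolation): the 95th percentile of weighted $F_{ST}$ and the
5th/95th percentiles of the $\pi$ ratio, computed on rankable windows only.
A window is selected iff it *strictly* exceeds the $F_{ST}$ threshold *and*
falls strictly inside either ratio tail. Strict exceedance means a set of
identical windows selects nothing rather than everything; the quantile
convention is pinned because tail membership changes with interpolation
rules. Windows with $\pi_{\text{target}}=0$ and $\pi_{\text{ref}}>0$ get an
infinite ratio (high tail); windows with both zero are unrankable. Selected
windows that overlap or abut on the same chromosome and tail side merge
into candidate regions; genes (BED intervals, 0-based half-open, converted
to 1-based inclusive at the comparison) attach to a region when they overlap
it by at least 1 bp. Raw ratios are used for the tails; log ratios would
give the same selected set under any monotone quantile rule applied per
tail, so the choice is presentational.

## The simulator

Because a real study's raw data (reads, reference genome, caller runs) are
outside the package's scope, every stage is exercised on a bundled
two-population Wright–Fisher simulator whose defaults mirror a two-breed
design: 26 + 54 diploid samples, $10^4$–$10^5$ biallelic SNPs, a clean
split followed by 200 generations of independent drift at $N_e = 500$,
2% missing genotypes, and trait cohorts of 77 + 68 for the validation
stage. Ancestral frequencies are drawn from Beta(0.5, 0.5) — the U-shaped
spectrum typical of SNP discovery panels; the shape is configurable.

Two engines:

* **sitewise** — each site's frequency evolves independently by binomial
  resampling of $2N_e$ allele copies per generation. At a sweep locus the
  deterministic directional-selection update
  $p' = p(1+s)/(1+sp)$ is applied before each resampling step. The
  hitchhiking footprint is emulated directly: flanking sites receive the
  same update with a distance-decayed coefficient
  $s\,e^{-d/L}$, where $L$ (`sweep_footprint`, default 50 kb) sets the
  footprint scale. Sweeps from standing variation — the regime simulated
  here, with the beneficial allele starting as the minor allele at
  frequency $\ge 0.05$ — leave sub-Mb footprints because recombination has
  already shuffled the haplotype background before selection begins; 50 kb
  gives a footprint spanning a handful of 100-kb windows, which is what a
  windowed scan of reduced-representation data can actually resolve. This
  engine has no linkage disequilibrium between sites; it exists to make
  frequency-based statistics (QC, $\pi$, $F_{ST}$, the scan) fast to test
  at genome scale.
* **haplotype** — explicit $2N$ haplotypes per deme reproduce by random
  union of gametes with Poisson crossovers at a per-bp rate, giving genuine
  LD; selection weights parents by multiplicative fitness $(1+s)$ per
  beneficial allele. This engine backs the LD-decay module, where real
  linkage is the point.

The simulator emits VCF + population map + per-site truth table + a gene
BED in which one interval is forced to cover each sweep locus, so the
annotation stage has a known answer. One master seed drives everything;
identical seeds give byte-identical VCFs.

**What the simulator does not emulate:** mutation during the simulated
epoch, demography beyond a clean split (no migration, bottlenecks or
expansions), genotyping error and allelic dropout typical of
reduced-representation data, linked background selection, and — in
sitewise mode — any LD beyond the imposed sweep footprint. Tests passing
on this generator show the *statistics and the selection rule* behave as
designed under their own model assumptions; they do not certify
performance on real data with complex demography.

## Numerical and design choices

* **Hard filters**: the standard GATK germline thresholds (QD < 2, QUAL <
  30, SOR > 3, FS > 60, MQ < 40, MQRankSum < −12.5, ReadPosRankSum < −8
  fail a SNP; a parallel set for INDELs). All comparisons are strict, so a
  record sitting exactly on a threshold passes; absent annotations never
  fail a record, because the rank-sum annotations are only emitted at
  heterozygote-carrying sites.
* **MAF/missingness QC**: a site is removed iff MAF < 0.03 (computed on
  called alleles) or missingness > 0.20, both strict; boundary sites stay.
  The filter is idempotent.
* **Genotype decoding**: multiallelic and non-SNP records are dropped (not
  split) with logged counts; half calls (`./1`) are conservatively treated
  as missing; phase separators are ignored.
* **Coordinates**: VCF 1-based internally; BED 0-based half-open at the
  file boundary only.
* **LD**: composite genotypic $r^2$ (squared Pearson correlation of
  dosages over pairwise-complete samples) — the standard choice for
  unphased data; pairs with zero variance at either site are skipped.
  Defaults: 300 kb maximum distance, 1 kb bins.
* **PCA**: per-site mean imputation of missing dosages, centering by
  $2\hat p$, scaling by $\sqrt{2\hat p(1-\hat p)}$, eigendecomposition of
  the sample covariance; each component is oriented so its
  largest-magnitude coordinate is positive, making signs reproducible.
* **Tree**: Saitou–Nei neighbour joining (via ape) on the allele-sharing
  distance (mean $|d_i - d_j|/2$ over pairwise-complete sites); exact on
  additive distances. Negative branch lengths, which only arise on noisy
  input, are clamped to zero; the deficit is not moved to a sister branch
  because the sister is ambiguous on an unrooted tree.
* **Exact tests**: two-sided $p$ by the probability-mass rule (all tables
  with the observed margins whose probability is no larger than the
  observed one, with relative tie tolerance $10^{-7}$). The genotype-table
  (2×3, Freeman–Halton) test is primary, the allele-table 2×2 secondary.
  Complete enumeration is guarded at a table total of 1000; beyond that a
  Monte-Carlo estimate must be requested explicitly. No multiplicity
  correction is applied by default — the validation stage mirrors
  reporting raw significance across a small candidate panel — but a
  Bonferroni/BH switch exists and is logged in the output.
* **Ties in top-SNP extraction** break by (chromosome, position), making
  the report deterministic.

## Problem sizes used by the checks

The test suite and the acceptance script exercise the full design at
50,000 SNPs over 50 Mb (26 + 54 samples, $N_e=500$, 200 generations,
three sweeps at $s = 0.3$), with sweep-recovery rates measured across
dozens of seeded replicates; oracle-equivalence checks (per-site $F_{ST}$,
exact-test enumeration, quantile selection) run on hundreds to a thousand
small random fixtures. The LD and tree Monte-Carlo checks use smaller
deme sizes ($N_e \le 60$) because explicit-haplotype reproduction is
quadratic in population size; those sizes are stated in the tests
themselves.

## Known limitations

* The scan is frequency-based; haplotype-length signals (iHS, XP-EHH) are
  out of scope, so very recent sweeps with little frequency change are
  invisible to it.
* The empirical-quantile rule always selects ~5% of windows jointly
  eligible under independence; it is an outlier scan, not a test with
  controlled false-positive rate.
* $K$'s two conventions can differ by orders of magnitude; outputs label
  which is which, and comparisons across studies should check the
  convention first.
* Fisher's exact test on genotype tables is conservative at small counts;
  power statements in the tests are calibrated against the bundled cohort
  generator, not against any real cohort.
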