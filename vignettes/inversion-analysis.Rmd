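---
title: "Detecting and analysing polymorphic chromosomal inversions from SNP data"
author: "invrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and analysing polymorphic chromosomal inversions from SNP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Large polymorphic inversions suppress recombination between the inverted
and the ancestral chromosome orientation in heterokaryotypes. Over time
the two orientations accumulate divergence as if they were separate
populations, while still segregating together within species. In a
species radiation this produces a characteristic signature: genomic
regions, often tens of Mbp, in which the relationships among individuals
look nothing like the rest of the genome — three clusters on a local PC
axis (the two homokaryotypes and, between them, heterokaryotypes with
strongly elevated heterozygosity).

`invrad` implements the full analysis chain around this signature:

1. **Discovery** (`compute_window_profiles()`, `detect_outlier_regions()`)
   — windowed principal-coordinate profiles of pairwise genetic
   distances, clustered genome-wide to flag outlier regions.
2. **Genotyping** (`genotype_region()`) — per-sample inversion karyotypes
   (0 = homozygous ancestral orientation, 1 = heterokaryotype,
   2 = homozygous inverted) with outgroup polarisation.
3. **Rephasing** (`rephase_by_inversion()`, `extract_carrier_haplotype()`)
   — assignment of heterozygous alleles to the inverted or ancestral
   haplotype using class consensus.
4. **Selection statistics** (`ics_scan()`, `mk_test()`, `binned_dnds()`,
   `exonic_enrichment()`, `shared_polymorphism_fraction()`).
5. **Introgression and divergence** (`d_statistic()`,
   `conditioned_d_experiment()`, `pairwise_divergence_time()`,
   `ils_retention_probability()`).
6. **Sex linkage and segregation** (`hwe_excess_het_test()`,
   `fisher_sex_test()`, `mendelian_segregation_test()`).
7. **Simulators with planted truth** (`simulate_radiation()`,
   `simulate_cross()`, `simulate_selection_forward()`), which are the
   validation substrate for everything above.

The numbered scripts under `analysis/` run these stages in order on a
simulated study dataset and write their tables under `results/`.

# Models and procedures

## Windowed distance profiles and outlier detection

For each window (default 1 Mbp, half-overlapping steps — the window size
follows standard practice for Mbp-scale inversions; the half-overlap step
is a design choice) the pairwise distance between samples i and j is the
mean per-site allelic difference `|d_i − d_j|/2` over SNPs non-missing in
both, a proper semimetric in [0, 1]. Classical multidimensional scaling
(eigendecomposition of the double-centred squared-distance matrix) gives
per-window principal coordinates. Because the sign of each coordinate is
arbitrary, every window's PC k is aligned against a genome-wide anchor
profile (negated when the correlation with the anchor is negative; exact
orthogonality is left unchanged and logged).

Each window is then represented by its first two PCs, concatenated and
scaled to unit norm — two PCs capture the three-cluster karyotype
geometry, and the normalisation removes window-to-window scale
differences due to SNP density. k-means (default k = 2, 10 restarts,
fixed seed) separates a majority "background" cluster from outliers;
maximal runs of at least `min_run = 3` consecutive outlier windows become
region calls, and runs separated by fewer than `min_run` background
windows are merged. The run rule is deliberately conservative against
single-window noise. Windows with fewer than 25 SNPs or more than 50%
missing genotypes are skipped (PCA degeneracy guard; both configurable).

When several *different* inversions segregate at once, each has its own
genotype composition and therefore its own direction in feature space;
with k = 2 one structure can be absorbed into the background cluster. In
that setting we raise `k_clusters` to the number of candidate structures
plus one (the `analysis` of five simultaneous regions uses k = 6); the
background is still identified as the largest cluster, and the run rule
keeps precision.

## Multi-step PC genotyping

Within a called region: (1) PCA of region ALT dosages is fitted on a
reference panel (default: all ingroup samples; missing genotypes
mean-imputed per SNP); (2) one-dimensional k-means on PC1 with k chosen
from {2, 3} by the gap statistic (uniform reference on the PC1 range,
B = 20 draws) with the one-standard-error rule — prefer two clusters
unless the third improves the gap beyond the reference spread. This
matters because a heterokaryotype cluster can be genuinely diffuse when
the ancestral-orientation haplotypes are diverse, and a naive gap
comparison then over-splits; (3) non-panel samples are projected onto the
fitted axis and assigned to the nearest centre; (4) clusters map to
genotypes: with three clusters the middle one is the heterokaryotype and
the end cluster nearest the mean outgroup projection is genotype 0
(ancestral orientation, following the convention that the outgroup
carries the non-inverted arrangement); with two clusters the more
heterozygous cluster is the heterokaryotype and the other is polarised by
the outgroup. Assignment confidence is `1 − d1/d2` (distance to nearest
vs second-nearest centre); assignments below 0.2 are left unassigned,
guarding against intermediate projections. A call is flagged invalid if
the heterokaryotype cluster is not the most heterozygous.

The exact panel membership and number of PCs used in published
WGS-typing pipelines is generally not stated; fit-on-panel plus
projection is our reconstruction and is documented as such.

## Rephasing and the carrier haplotype

Homokaryotypes contribute two haplotypes of their own class (sites
heterozygous *within* a homokaryotype are split arbitrarily between its
two same-class haplotypes — they are within-class polymorphism). For
heterokaryotypes, at each heterozygous SNP the allele matching the
inverted-class consensus (majority allele among genotype-2 samples) goes
to the inverted haplotype; consensus ties leave the site unassigned. When
no genotype-2 homozygote exists the inverted consensus is inferred from
heterozygotes against the genotype-0 consensus. The "carrier haplotype"
extraction is the same subtraction restricted to heterozygous carriers,
with per-site support = the fraction of carriers agreeing with the
majority; it reconstructs an orientation class that exists only in
heterozygous state (the chromosome-9-like configuration).

## Selection statistics

`ics_scan()` correlates derived-allele dosage with inversion genotype
(Pearson, complete cases, at least 10 observations). Positive r means the
derived allele rides on inverted haplotypes. p-values use the
t-approximation with n−2 df; a seeded permutation option exists for small
n, where the t-approximation is visibly anti-conservative. The default
ICS threshold is score ≥ 7 and |r| ≥ 0.9 ("top-ranking" SNPs; both
configurable and echoed in outputs). Scores are capped at 320 where p
underflows.

`binned_dnds()` partitions [−1, 1] into bins of width 0.1 and computes,
per bin, `(n_nonsyn / L_n) / (n_syn / L_s)`. Site counts default to
Nei–Gojobori-style enumeration over annotated codons
(`nei_gojobori_sites()`): per codon position the three single-base
changes are enumerated, changes to stop codons are excluded with the
position's one site split among the remaining changes, and stop codons
contribute nothing. Whether published normalisations used per-bin or
global site counts is usually unstated; we use global counts.

`mk_test()` classifies each phased site once: a fixed difference if the
two classes are fixed for different alleles, polymorphic if variable
within either class; NI = (Pn/Ps)/(Dn/Ds), DoS = Dn/(Dn+Ds) − Pn/(Pn+Ps),
with zero denominators flagged rather than propagated.

## Introgression and divergence

`pairwise_divergence_time()` converts mean per-bp difference d into
t = d/(2μ) generations, with μ = 3×10⁻⁹ per bp per generation by default.
The denominator is the accessible scope length scaled by the pair's
completeness fraction, so monomorphic accessible sites count as zero
difference.

`d_statistic()` uses frequency-weighted site patterns
ABBA = (1−p1)p2p3(1−pO), BABA = p1(1−p2)p3(1−pO) and a delete-one block
jackknife (default 1 Mbp blocks; at least 20 non-empty blocks required)
for the SE and Z. `conditioned_d_experiment()` enumerates quartets in
which P1 and P2 are congeneric (same clade), P3 comes from another clade,
and exactly one of P1/P2 shares the species-majority inversion state with
P3 — ordered so P2 is the sharer — and computes D on SNPs *outside* all
called inversions. Under a drift-only null the D distribution is
symmetric around zero (sign test); planted transfer with genome-wide
admixture shifts it positive. Holm correction is applied across quartets.

`ils_retention_probability()` is the heterozygosity-decay factor
exp(−t/(2Ne)) raised to (lineages × inversions): the expected fraction of
ancestral heterozygosity that survives t generations of independent
sorting, the quantity whose smallness argues against incomplete lineage
sorting as an explanation for shared inversion polymorphism. Note this is
*not* the probability that a locus is still segregating — conditional on
segregating, drifted frequencies are spread out, so P(polymorphic) decays
more slowly (≈0.54 vs 0.37 at t = 2Ne from frequency 0.5); the
forward-simulation companion `wf_heterozygosity_retention()` measures the
retained-heterozygosity fraction, which the discrete Wright–Fisher model
matches as (1 − 1/2N)^t.

## Exact association tests

Heterozygote excess uses the Levene conditional distribution of
heterozygote counts given allele counts, one-sided towards excess;
monomorphic species return p = 1 with a flag. Cross-species pooling is
provided two ways, reflecting genuine ambiguity in how pooled values are
computed in practice: Fisher's combination of per-species p-values
(`pool_species_tests()`), and pooling the raw genotype counts before a
single exact test. For tables in which heterozygotes are the only carrier
class, per-species evidence is intrinsically weak and only the raw-count
pooling yields the dramatic combined significance.

`fisher_sex_test()` collapses (sex) × (genotype) tables to heterozygous
vs homozygous and computes the two-sided Fisher exact p as the sum of
tables no more probable than the observed one (the common convention,
with the conventional 1e-7 relative tie tolerance; this matches
`stats::fisher.test`, which the test-suite uses as an independent
cross-check). The reported odds ratio is the sample cross-product ratio
oriented so that values above 1 mean male-heterozygote enrichment — the
XY-like expectation. Samples of unknown sex are excluded and logged.

The Mendelian segregation test is the plain chi-square against 1:2:1
(df = 2, so p = exp(−χ²/2)).

# The simulators: what they emulate, and what they do not

## Radiation with planted inversions

`simulate_radiation()` draws genotypes from an event-driven structured
coalescent. A chromosome is a sequence of independent blocks (default
500 kbp): full linkage within a block, free recombination between blocks.
Outside inversions, populations are the clades of an ultrametric species
tree (branch lengths in generations); merge events follow the tree and
introgression events move lineages between populations backwards in time
with the configured probability. Inside an inversion region the
genealogy is conditioned on each haplotype's orientation class: the
inverted and ancestral classes are two populations that merge at the
inversion origin time. This yields exactly the structure the analysis
assumes — zero recombination between classes in heterokaryotypes,
in-region divergence set by the origin time, elevated heterokaryotype
heterozygosity — with planted truth for every sample and SNP.

Three deliberate simplifications:

* **Clade structure inside the region is collapsed**: within a class,
  haplotypes from different clades form one pool. This mirrors the
  biology in which inversion haplotypes move between clades as units, but
  it means the simulator cannot express residual clade structure within
  an orientation class.
* **Class diversity is asymmetric by default**: the inverted class gets
  founder-scale diversity (Ne/10) and the ancestral class radiation-scale
  diversity (2×Ne), reflecting the derived, initially single-copy origin
  of an inverted haplotype. This asymmetry is also what makes outgroup
  polarisation work: class-diagnostic alleles are then predominantly
  derived on the inverted stem, so the outgroup projects on the ancestral
  side. With symmetric classes the outgroup is equidistant in
  expectation and polarity becomes a coin flip. For a chromosome-9-like
  configuration — the ancestral orientation present only as a single
  re-introgressed lineage — the natural choice is a *small* ancestral
  class size (`anc_ne`), which tightens the heterokaryotype cluster.
* **Gene flux** (rare double crossovers between classes) is modelled as a
  per-block class swap with a configurable probability (default 0), not
  as positioned double-crossover tracts.

Mutations follow infinite sites; REF/ALT assignment is randomised so that
the ALT allele is ancestral for about half of SNPs, which exercises the
polarisation code honestly. Outgroup polarisation is known to mispolarise
mutations on the outgroup's own stem; those SNPs are monomorphic in the
ingroup and never reach downstream scans, and the test-suite checks
>95% agreement at ingroup-polymorphic SNPs. Effect classes are assigned
at random (default 70/15/15 noncoding/synonymous/nonsynonymous) — the
radiation simulator plants no selection, so its MK tables are expected to
be neutral; selection signal comes from the forward simulator.

What passing tests on this generator do **not** show about real data:
robustness to variant-calling artefacts, reference bias, centromeric
repeats and inversion breakpoint effects, population growth or
continuous migration, or linked selection outside the inversion.

## Pedigree cross

`simulate_cross()` crosses two founders homozygous for opposite
orientations and tracks founder-origin segments through F1/F2/F3.
Crossovers per meiosis are Poisson with the configured per-bp rate; a
parent heterozygous for the region places crossovers only outside it.
Truth records *realized* origin-switch positions, which is what windowed
PC1 state changes can observe. The windowed crossover counter assigns
each window to the nearest founder-state centroid, smooths state islands
shorter than 2 windows (noise suppression that would hide only
double-crossovers shorter than 2 windows), and counts a switch as
in-region only when both flanking windows lie entirely inside the region
— boundary switches belong to the flanks.

## Forward selection simulator

`simulate_selection_forward()` is a minimal two-background Wright–Fisher
model: the inverted and ancestral classes are non-recombining haploid
backgrounds of fixed sizes 2·Ne·f and 2·Ne·(1−f) (the inversion
polymorphism is held at frequency f, as under the balancing/sex-linked
maintenance regime the analysis targets; inversion loss or fixation is
out of scope). New mutations arise Poisson-distributed, land on a
background proportionally to its size and are synonymous or
nonsynonymous in proportion to the site ratio (default 2.8:1 per-site
nonsyn:syn, typical of vertebrate codon usage); sites within a
background are unlinked. Selection is per-mutation per-background: a
configurable fraction of nonsynonymous mutations arising on the inverted
background is beneficial, all other nonsynonymous mutations deleterious,
synonymous and noncoding mutations neutral. Sampling a diploid cohort
from the final frequencies (`forward_sim_cohort()`) feeds the standard
`ics_scan()` → `binned_dnds()` path, so the validation exercises the
same code as the data analysis. Under strict neutrality every bin's
normalized ratio is 1 in expectation; purifying selection depresses the
top bin; beneficial nonsynonymous input on the inverted background is
the only regime that pushes the top bin to or above 1 — the qualitative
pattern the binned dN/dS curve is designed to detect.

# Numerical choices and degenerate inputs

* Distances: pairs with no shared non-missing site are `NA`; the
  semimetric property is asserted to 1e-12 on complete data.
* MDS on a zero matrix returns all-zero coordinates and variance; rank
  deficiency is padded with zero columns.
* k-means runs with 10 restarts under a locally scoped seed (the
  caller's RNG stream is untouched).
* An invariant genotyping region short-circuits to a single genotype-0
  cluster.
* Correlation p-values are floored at 1e-321 before log-transform;
  scores cap at 320.
* NI is flagged undefined when any of Ps, Ds, Dn is zero; DoS needs both
  a divergence and a polymorphism denominator.
* Fisher's combination refuses p = 0 unless an explicit floor is given.
* The jackknife drops non-finite leave-one-out values (blocks carrying
  all informative sites).
* Missing dosages are excluded pairwise everywhere; nothing is imputed
  except the panel-mean imputation inside the genotyping PCA fit.

# Problem sizes used in validation

The shipped validation runs on deliberately scaled-down data chosen to
exercise every code path at comfortable statistical margins: radiations
of 60 ingroup samples + 4 outgroups over two 20 Mbp chromosomes with one
10.5 Mbp inversion (about 10⁵ SNPs at Ne = 5,000); a five-chromosome,
five-inversion variant; a 150-progeny pedigree; D-statistic quartets of
8 + 8 + 8 + 3 samples over 120 jackknife blocks with 40 null replicates;
divergence-time recovery on a 2,000-generation split at Ne = 500 (the
coalescent expectation for a cross-population pair is split + 2Ne);
forward simulations at Ne = 1,000 for 4Ne generations (five seeds) for
the headline dN/dS contrast, and smaller Ne for the neutrality and
purifying controls. The conditioned-D transfer scenario uses a strong
admixture pulse (30% at 1,000 generations) because that is the regime the
experiment is designed to flag — species sharing an inversion state
through hybridisation substantial enough to leave a genome-wide trace.

# Known limitations

* Breakpoint resolution is outside scope: calls inherit window
  granularity, and the simulator snaps planted regions to block
  boundaries.
* The structured coalescent treats recombination as free between blocks
  and absent within; linkage-disequilibrium decay within blocks is not
  modelled.
* Outgroup polarisation is genotype-majority over configured outgroups,
  not an alignment-based probabilistic inference.
* The ILS factor is a closed-form approximation; published supplementary
  calculations with unpublished parameters cannot be reproduced here.
* Exact conditional tests are discrete and therefore conservative; the
  sex-association type-I rate sits at the low edge of the nominal level
  for cohort-sized tables.
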