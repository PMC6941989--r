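---
title: "Methods: dissecting the evolutionary history of a shared mimicry supergene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting the evolutionary history of a shared mimicry supergene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Several closely related butterfly species can share a female-limited
mimicry polymorphism controlled by the same autosomal locus — a
supergene where a single Mendelian "switch" governs a complex wing
pattern. Four historical processes can produce such sharing:

1. **Introgression** — a mimicry allele crosses species boundaries by
   hybridization. Alleles then group by *phenotype* across species in a
   locus genealogy, with divergence between allelic classes *younger*
   than the species radiation.
2. **Incomplete lineage sorting (ILS)** — an ancestral balanced
   polymorphism is retained through speciation. Alleles also group by
   phenotype, but allele-class divergence *predates* the radiation.
3. **Allelic turnover** — the polymorphism is ancestral, but under
   multiallelic balancing selection new alleles continually arise and
   replace their predecessors. Extant alleles are species-specific, so
   the locus genealogy groups by *species*, yet the locus carries the
   footprint of long-term balancing selection: elevated Tajima's D,
   elongated genealogy branches, and residual trans-species variants
   whose sharing tracks phylogenetic proximity.
4. **Independent origin** — each species co-opts the locus separately.
   Alleles group by species, without the balancing-selection footprint.

The package implements the full inference chain used to discriminate
these hypotheses from multi-species resequencing data — windowed
F~ST~ and Tajima's D with genome-wide percentile enrichment, D′/LOD
linkage disequilibrium, locus-restricted PCA, per-SNP association,
gene-conversion tract detection, and distance genealogies — plus a
forward-time simulator that generates data under each scenario so the
whole chain is validated by scenario recovery.

# The forward simulator

`simulate_supergene()` runs a discrete-generation Wright–Fisher model
of `n_species` diploid populations of constant size N. Haplotypes are
0/1 vectors over a fixed grid of candidate SNP positions on one
chromosome; a latent integer *allele class* attached to each haplotype
represents the functional mimicry allele and is transmitted with the
supergene interval.

**Selection.** An individual carrying classes (c1, c2) expresses the
dominant class (by default the higher, i.e. younger, class id) and has
fitness

w = 1 − s·f,

where f is the current within-population frequency of its *expressed
phenotype*. This negative frequency-dependent selection (NFDS) is the
standard model for mimicry supergene balancing selection: rare morphs
escape predator attention. `s = 0` recovers pure drift; parents are
drawn by fitness-weighted multinomial sampling.

**Transmission.** Each gamete is a crossover mosaic of the parent's two
haplotypes (Poisson number of breakpoints, uniform positions);
breakpoints inside the locus interval are suppressed by default — the
supergene's hallmark recombination suppression. Gene conversion
initiates at a Poisson rate per gamete and copies a geometric-length
tract (mean 500 bp by default, within the empirically motivated
100–2000 bp range; the turnover preset uses 1000 bp) from the homolog.
Point mutation is recurrent at `mu_neutral` per site per generation.

**Innovation.** With probability `mu_allele` per haplotype per
generation, a haplotype founds a new allele class. The event flips
`n_markers` (default 5) random locus sites on the founder — a
coarse-grained stand-in for the linked functional and regulatory
divergence a new mimicry allele carries. Classes inherit their locus
sequence, so successive innovations along an allele lineage accumulate
divergence; the depth of between-class divergence therefore reflects
the *age* of the allelic system, which is exactly the axis separating
turnover from independent origin.

**Species.** Splits copy the population instantaneously (no bottleneck)
onto a fixed ((A,B),(C,D)) topology with staggered split times, giving
the phylogenetic-proximity gradient used by the shared-SNP analysis.
Migration replaces a Binomial(2N, rate) number of recipient haplotypes
with random donor haplotypes per generation in a configured window.

**Initialization.** The founding population is drawn at mutation–drift
equilibrium (site frequencies from the neutral spectrum, P(count = c) ∝
θ/c, assigned at linkage equilibrium) and burnt in for several hundred
generations before the first split so linkage structure can build up.
This avoids the many-multiples-of-N burn-in a cold start would need,
and the neutral calibration (below) verifies it: genome-wide windowed
Tajima's D is centred near zero.

## Scenario presets

`scenario_preset()` fixes the study conditions per scenario; all values
are package defaults chosen once, on forward-calibration grounds, so
each preset exhibits its defining qualitative signature:

| preset | N | generations (root/AB/CD/end) | s | mu_allele | ancestry |
|---|---|---|---|---|---|
| neutral | 200 | 300/700/900/1100 | 0 | 0 | 2 ancestral classes |
| ils | 100 | 500/650/750/850 | 0.6 | 0 | 2 ancestral classes |
| turnover | 100 | 400/1400/1800/2200 | 0.7 | 3e-4 | 2 ancestral classes |
| independent | 100 | 400/1400/1800/2200 | 0.35 | 0 | forced co-option at 2150 |
| introgression | 100 | 400/1400/1800/2200 | 0.5 | 0 | co-option in A at 1850, A→C pulse 1900–1950 |

Points that deserve justification:

* **N = 100 for the selection scenarios, 200 for the neutral control.**
  Allele-class turnover and post-split drift must run their course
  within the simulated horizon, and both timescales scale with N. The
  neutral calibration uses the larger population for a cleaner
  equilibrium.
* **Turnover: s = 0.7, mu_allele = 3e-4.** Strong NFDS holds 2–4
  classes at intermediate frequency (the regime that elevates window
  Tajima's D); the low innovation rate still yields ~100 innovations
  per lineage over the 1800 post-root generations, enough to replace
  the ancestral classes in every species. A higher innovation rate
  fragments the locus into many rare classes and *destroys* the
  balancing signature — an instructive regime we explored and rejected
  as a default.
* **Independent: co-option 50 generations before sampling.** The
  hypothesis is *recent, separate* recruitment of the locus; a young
  allele has essentially no genealogical footprint, which is what
  distinguishes it from turnover. NFDS (s = 0.35) keeps the new morph
  observable.
* **Introgression: a non-sister pulse (A→C) of 0.2% per generation for
  50 generations.** NFDS then amplifies the transferred allele at the
  locus while backcrossing dilutes the ~10% genome-wide donor ancestry.
  A sister-pair transfer is structurally confounded with sister-pair
  retention under turnover (both produce allele sharing between the
  youngest pair), so the preset uses the informative non-sister case;
  stronger pulses distort genome-wide species distances enough to
  corrupt the sister-pair inference itself.
* **Neutral: uniform SNP density.** The selection presets place
  candidate sites more densely inside the locus (600 of 5000 sites in
  100 kb of 2.5 Mb), mimicking the elevated SNP density of a balanced
  supergene region; the control keeps the locus indistinguishable from
  background so that its windows are exchangeable with genome windows.

Each run samples 20 individuals per species (resequencing-panel scale)
and emits a phased genotype matrix over the segregating sites, a sample
table with expressed morphs, the per-haplotype truth, and allele-class
frequency trajectories.

# The statistics

**Windowed Weir–Cockerham F~ST~** (`fst_windows()`): per-site variance
components a, b, c for two diploid samples, aggregated per 10 kb window
as Σa / Σ(a+b+c) — the ratio-of-sums ("weighted") convention of
VCFtools' windowed output. Monomorphic sites contribute nothing; sites
with fewer than two called individuals in either population are
excluded; windows with no usable site are NA, never 0; negative
estimates are reported as computed since downstream comparisons are by
percentile.

**Windowed Tajima's D** (`tajima_windows()`): D = (π − S/a₁) /
√(e₁S + e₂S(S−1)) with the standard constants, π from allele
frequencies with the n/(n−1) correction (robust to unphased input),
individuals counted as two haplotypes. S = 0 windows are undefined.

**Percentile enrichment** (`percentile_rank()`): the fraction of
genome-wide windows strictly below the maximum focal-window value,
×100. The strictly-below tie rule is a declared convention. Windows in
the bottom decile of variant counts are removed first
(`drop_sparse_windows()`, a ≤-quantile cut with ties removed), since
sparse windows produce artificially extreme values.

**LD** (`ld_matrix()`): after a 75% genotyping-rate and MAF ≥ 0.001
filter and seeded thinning to ~1000 sites, haplotype frequencies come
from phase when available, otherwise from a two-locus EM over the
double-heterozygote ambiguity (iterated to |Δp| < 1e-12; the unit
tests verify it attains the genotype-likelihood maximum). D′ uses the
sign-dependent D_max; the LOD is the base-10 multinomial likelihood
ratio of the fitted haplotype frequencies against linkage equilibrium,
and pairs are classified white / blue / pink_red exactly as the
Haploview colour scheme (D′ compared to 1 at tolerance 1e-9).

**Association** (`gwas()`): per-site allelic 2×K contingency test
(chi-square, with Fisher's exact test whenever any expected *or
observed* cell is below 5 — a sparse observed cell, e.g. a fixed
difference, breaks the chi-square approximation even at large
expectations), BH q-values across all tested sites, flags at q < 0.01
and 0.001. The mixed-model machinery of GWAS pipelines is deliberately
not reproduced; population structure is instead exposed by the
genome-versus-locus PCA contrast below, and this divergence is logged
prominently here.

**PCA and heterozygote calling** (`snp_pca()`,
`call_locus_genotypes()`): eigendecomposition of the covariance of
mean-centred dosages (missing dosages mean-imputed per site — the only
place imputation occurs), run genome-wide and locus-restricted. A
supergene behaves like an inversion: the locus PCA separates carriers
along PC1 with heterozygotes intermediate, and a 1-D k-means (k = 3,
ordered centroids) labels the middle class heterozygous.

**Trans-species SNPs** (`shared_snps()`): per species, a SNP is
associated when q < 0.05 *and* the between-morph allele-frequency
difference reaches a threshold. The module default (0.8) formalizes a
manual scoring rule; the pipeline lowers it to 0.6 because with a
dominant balanced allele near frequency 1/2 the observable contrast
between morph classes tops out around 2/3, and 0.8 would discard fully
associated dominant markers. Pairwise intersections are taken by exact
reference position (allele-identity matching is available as an
option), and the Spearman correlation of shared counts against
phylogenetic proximity (negative tree distance) summarizes whether
sharing tracks relatedness.

**Gene conversion** (`detect_conversion_tracts()`): a Sawyer-style
inner-fragment scan. For each between-class haplotype pair, over the
columns variable among the two classes, score = matches − penalty ×
mismatches with default penalty q/(1−q) (q the pair's mismatch
fraction, making the expected per-column score zero under the null);
the best segment comes from a linear max-subarray scan and its p-value
from column-order permutations (default 10,000), Bonferroni-corrected
across pairs. The exact scoring constants of the original
permutation-test software are not reproduced; the formulation keeps
its global inner-fragment spirit with all constants configurable.
A silent-site mask is available as a column filter when exon
annotation exists.

**Genealogies** (`distance_tree()`): neighbour-joining on normalized
Hamming distances, with deterministic tie-breaking by tip-label order.
Distance trees replace likelihood tree search deliberately: the
signatures of the four hypotheses — clustering mode, branch-length
contrasts — are distance-visible, and NJ recovers additive metrics
exactly (verified against four-point-condition oracles).

## Reading the genealogy

`clustering_mode()` works on unrooted bipartitions, so it is invariant
to re-rooting. A label group is monophyletic when an edge separates
exactly that group; a tolerance (`mono_tol`, default 10% of the group)
absorbs occasional conversion mosaics or labelling errors. Morph labels
are assigned per *haplotype*, not per individual — both haplotypes of a
heterozygote would otherwise carry the dominant morph — by clustering
each species' locus haplotypes into allele classes
(`haplotype_class_clusters()`: average-linkage with the cluster count
chosen by mean silhouette, one class when the best silhouette is below
0.5) and mapping each class to the modal morph of its
sequence-homozygous carriers.

`by_phenotype` requires a morph class that spans two *non-sister*,
*polymorphic* species to form a clade: sister-pair-only sharing is
exactly what young lineages retain under turnover (the package records
it as a declared nesting/interleaving exception inside `by_species`
mode rather than evidence of allele sharing), and a background morph
covering monomorphic relatives is no evidence either. Sister pairs are
taken from the genome-wide tree (mutual nearest species).

`elongation_ratio()` is (mean terminal branch / total tree length) at
the locus divided by the same genome-wide. The pipeline computes it on
*allele-class representative* trees — one medoid haplotype per inferred
class per species, same tips for locus and genome trees — because the
theory of multiallelic balancing selection predicts elongation of the
*allelic* genealogy: summarizing by class representatives turns class
stems into terminal branches. On all-haplotype trees the deep class
stems sit on internal edges and the statistic loses its signal (we
verified this directly). Under the neutral preset the ratio sits near
1; under turnover it exceeds 1.3 in most replicates.

`phenotype_divergence_ratio()` divides the mean locus-tree path
distance between morph classes by the deepest mean genome-tree distance
between species — the introgression-versus-ILS axis.

## The discriminator

`discriminate()` is a two-stage decision tree with a per-criterion
evidence vector always attached:

* `by_phenotype` clustering → **introgression** if the phenotype
  divergence ratio is below `depth_ratio` (default 1.25, i.e. allele
  divergence shallower than the radiation), else **ILS**;
* `by_species` clustering → **turnover** if at least two of the three
  balancing signatures fire — elongation ratio > `r_star` (1.2), median
  locus Tajima percentile across polymorphic species ≥ `p_star` (90),
  sharing-versus-proximity correlation > 0 — else **independent**;
* anything else → `mixed/uncertain`, never silently coerced.

`r_star` and `p_star` default so that the neutral control rarely
triggers turnover (it essentially never does: it lacks two concurrent
signatures). At the packaged study conditions the discriminator
recovers the true preset in roughly 85–100% of replicates depending on
scenario; the residual confusions are the scientifically honest ones
(an independent co-option that drifted to loss in three of four
species resembles a single-species innovation; a turnover replicate
with an unusually weak percentile falls back to independent).

# What the simulations do and do not show

The generator emulates: diploid multi-species genotype matrices with a
recombination-suppressed mimicry window under NFDS, neutral background
variation at mutation–drift equilibrium, a species tree with staggered
splits, crossover, gene conversion, migration and allelic innovation.

It does not emulate: sequence-level realism (codon structure, indels),
inversion breakpoints, sex linkage or female-limited expression,
population growth or bottlenecks, missing genotype calls, or phasing
error (simulated output is perfectly phased; the statistics accept
unphased input but the tree stages require phase). Passing the
validation therefore shows the chain correctly extracts the four
scenarios' signatures from data *of this structure*; it does not show
robustness to assembly, calling or phasing artifacts of real
resequencing data.

Problem sizes were chosen at desk scale — 2.5 Mb genomes with 5000
candidate sites, 250 windows of 10 kb, 20 sampled individuals per
species, tens of replicates per validation statement — so a full
validation sweep runs in minutes on one core. The empirical study this
design mirrors used whole genomes and ~136 resequencing datasets;
percentile enrichments of comparable magnitude (locus F~ST~ near the
99th percentile, Tajima's D in the high 80s–90s under turnover) emerge
already at this scale.

# Numerical conventions and degenerate inputs

* Internal coordinates are kept 1-based inclusive at every file
  interface (VCF convention); BED export converts to 0-based
  half-open. Windows anchor at position 1 of each chromosome — the
  anchoring convention is declared here since window tilings are not
  unique.
* Missing genotypes are excluded site-wise from every statistic and
  never imputed, except mean-imputation inside PCA.
* F~ST~ windows with no usable site, Tajima windows with S = 0, LD
  pairs with a monomorphic member, and conversion-tract pairs with
  fewer than two variable columns are all *flagged undefined* and
  excluded, never zero-filled.
* All-identical tree input yields a star tree with a `degenerate`
  flag; k-means heterozygote calling on a constant PC1 is an error.
* Every stochastic stage of `run_scan()` draws its own sub-seed from
  the master seed via a fixed counter, so adding a stage never
  perturbs earlier stages and identical configs give byte-identical
  summary JSON.

# Session

```{r}
library(supergene)
report <- run_scan(scan_config(preset = "turnover", seed = 1))
report$call
```
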