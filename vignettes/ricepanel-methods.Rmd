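---
title: "Methods: panel design, simulation, and introgression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel design, simulation, and introgression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricepanel)
```

This vignette is the package's own account of the models and procedures it
implements: the marker-selection engine for fixed SNP arrays, the
generative model behind the synthetic data, and the conventions used by the
deployment analyses. It also records the design decisions that were
genuinely open and how each degenerate input is handled.

## Genotype and coordinate conventions

Genotypes are unphased biallelic dosages of the alternate allele: 0 =
homozygous reference, 1 = heterozygous, 2 = homozygous alternate, `NA` =
no-call. Array platforms report AA/AB/BB cluster calls; those map onto
0/1/2 once the strand is normalized to the manifest's reference allele, and
the manifest is treated as authoritative for alleles. All coordinates are
1-based inclusive base pairs (the convention in which rice physical
positions are printed); only BED exports convert to 0-based half-open.

Allele counting is the usual biallelic convention: a homozygote contributes
two copies, a heterozygote one of each, and no-calls are excluded from all
denominators. Stated MAC and call-rate cutoffs (the TASSEL-style "MAC = 5,
call rate = 0.8" filter implemented by `filter_loci()`) are read as
inclusive (`>=`), matching how genotype-QC tools apply printed thresholds.
A locus with zero calls has call rate 0 and undefined (NA) MAF, and is
always removed by any MAF-based filter.

## The design engine

`design_panel()` runs four stages. The thresholds live in
`design_policy()`; defaults are listed with units.

**Basic filtering** (`basic_filter()`) removes candidates whose assay
context predicts failure on a bead-type platform:

1. *flank_proximal* — any flanking variant within `flank_exclusion_bp`
   (10 bp) of the target, either side. A variant under the probe's 3' end
   destabilises hybridisation regardless of side. Boundary: an offset of
   exactly 10 bp removes; 11 bp retains.
2. *minor_hom_window* — a side of the target "violates" when a flanking
   variant within `hom_window_bp` (35 bp) has a minor-homozygote count above
   `minor_hom_max` (4) in the discovery panel (a common flanking
   polymorphism, which shifts cluster positions). With
   `hom_window_sides = "both"` (default) the candidate is removed only when
   both sides violate; `"either"` is provided because the one-sided reading
   of the rule is also defensible. The default follows the stricter literal
   "occurring on both sides" reading.
3. *indel* — indel candidates are removed; the panel is a SNP panel.
4. *repetitive_or_rare* — repetitive-sequence candidates and candidates
   with discovery-panel MAF below `global_maf_min`. The low-MAF cutoff has
   no canonical value; 0.05 was chosen once as the
   smallest frequency at which a minor allele is still seen several times
   in a ~128-genome discovery panel, and is configurable.

The four rules are independent predicates, so their order changes only the
per-rule attribution in the report, never the retained set; the test suite
asserts this on random catalogs.

**Qualification.** `subpop_qualify()` applies *strict* inequalities — MAF
> `subpop_maf_min` (0.20) and call rate > `subpop_obs_min` (0.80) within
each cultivated subpopulation — so a marker at exactly 20% MAF does not
qualify. Groups with fewer than two accessions cannot yield a frequency and
are skipped with a warning. `cross_qualify()` requires both parents to be
non-missing opposite homozygotes: heterozygous or missing parental calls
leave progeny segregation unscorable for a fixed-line design.
`union_candidates()` is an exact set union: a marker enters the candidate
pool if either criterion admits it.

**Selection** (`select_panel()`) is a three-phase deterministic greedy:

1. *Legacy phase.* Legacy markers are fixed content carried over from
   earlier assay sets; they bypass all filters and are always selected.
   They do, however, count toward coverage if they happen to be informative
   for a cross.
2. *Coverage phase.* Each chromosome is partitioned into 1 Mb bins
   (`[k·10^6 + 1, (k+1)·10^6]`). While any (cross, bin) cell holds fewer
   than `min_snps_per_mb_per_cross` (1) informative selected SNPs and a
   covering candidate exists, the candidate covering the most unmet cells
   is added; ties break to the lower chromosome, then the lower position.
   Cells for which no eligible candidate exists are reported in
   `unmet_constraints` rather than raised as errors — an exhausted bin is a
   property of the catalog, not a bug in the run.
3. *Quota phase.* For each subpopulation in the fixed order indica, aus,
   tropical japonica, temperate japonica, aromatic, `quota_per_subpop`
   (400) markers are taken from its qualified set, excluding markers
   already selected or used by another subpopulation's quota ("non-
   overlapping" is read as disjoint quota sets; a quota marker may still
   also be informative for a cross). Each pick maximizes the distance to
   the nearest already-selected marker on its chromosome — a marker on a
   chromosome with no selection yet has infinite distance and is picked
   first — with the same tie-break. Short quotas go to
   `unmet_constraints`.

Two points here were genuinely open. First, whether the subpopulation-quota
markers should be chosen before or jointly with the cross-polymorphic
markers is a free choice; coverage-then-quota was chosen
because the spacing guarantee is the binding constraint (quota markers are
plentiful) and a fixed order makes the procedure reproducible. Second,
"optimize genome spacing" names no algorithm; greedy maximum coverage with
deterministic tie-breaking is the simplest reproducible choice and
guarantees the per-Mb minimum whenever the catalog allows it.
Identical inputs always give identical `panel_design` objects.

*Partial bins.* A trailing bin shorter than `partial_bin_min_mb` (0.5 Mb)
is not treated as a constraint: a 100 kb sliver at a chromosome end would
otherwise be unsatisfiable whenever the catalog has no candidate there.

## The synthetic-data generator

The generator produces the study conditions the analyses are validated
under; its defaults were fixed once, before any test was run against them.

**Diversity panel** (`simulate_panel()`). The Balding–Nichols model is the
simplest structured-population model with a single divergence parameter per
group: per locus, an ancestral alternate-allele frequency
`p ~ Uniform(0.1, 0.5)`, and per group
`q_g ~ Beta(p(1−F_g)/F_g, (1−p)(1−F_g)/F_g)`. Accessions are drawn as
inbred lines (homozygous alternate with probability `q_g`), then overlaid
with a residual heterozygosity rate (0.005 — rice accessions are largely
inbred but not perfectly so) and a flat no-call rate (0.02, a typical
array-grade missingness). Default group sizes emulate a 128-genome
discovery panel: 21 indica, 16 aus, 18 tropical japonica, 19 temperate
japonica, 11 aromatic, 28 rufipogon, 9 nivara, 3 admixed, 3 outgroup.
Cultivated groups default to F = 0.4; the wild groups get lower F (0.15,
0.2) so they carry more internal diversity — the long-branch behaviour wild
accessions show in diversity trees — and the outgroup a much higher F
(0.8). Admixed accessions average the frequencies of two random groups.

What this emulates: group differentiation, within-group homogeneity
gradients, missingness, residual heterozygosity. What it does not: linkage
disequilibrium (loci are independent), coalescent genealogies, selection,
ascertainment bias in the candidate catalog, or genotyping-error structure
beyond a flat no-call rate. Passing tests therefore demonstrate the
correctness of the algorithms under a clean structured-panel model, not
robustness to every artefact of real array data.

**Candidate catalog** (`simulate_catalog()`). Positions follow a
homogeneous Poisson process per chromosome; default chromosome lengths are
rice-like (12 chromosomes: 43, 30, 36, 35, 30, 31, 30, 28, 23, 23, 29,
27 Mb). Indel and repetitive flags are Bernoulli at configured fractions;
discovery MAF is Uniform(0, 0.5); flanking variants fall in ±100 bp at
`flank_variant_rate_per_bp` with Poisson(2) minor-homozygote counts, so a
small tail exceeds the filter threshold of 4.

**Crosses** (`simulate_cross()`). Meioses use Haldane's no-interference
model: crossover counts are Poisson with mean
`length_Mb × cm_per_mb / 100` per chromosome, positions uniform. The
default 4.0 cM/Mb reflects the rice genetic map (~1500 cM over ~380 Mb).
The scheme string (`F2`, `BC2F1`, `BC3F2`, ...) is applied literally:
backcrosses to parent A, then self-pollination to the requested filial
generation. Truth segments carry zygosity (`hom`/`het`) so the donor genome
fraction — het counting one half — is computable;
`donor_genome_fraction()` implements that dosage and has expectation
`(1/2)^(n_bc + 1)` after `n_bc` backcrosses. CSSL mode rejection-samples
progeny until the donor covers the whole target interval (an error after
5000 attempts per progeny flags an unreachable target). Parents are
treated as fully inbred: heterozygous parental calls are resolved to a
random homozygote with a warning, and loci where the contributing parent
is missing yield missing progeny alleles.

All simulators take an explicit seed and are bit-reproducible; the pipeline
derives per-stage seeds from one top-level seed via `substream_seed()`.

## Deployment analyses

**Pairwise polymorphism.** There is no single convention for whether a
"polymorphic SNP between a pair" counts heterozygote differences, so both
policies are exposed: `differ_counts`
(default — any non-missing call difference; with a mostly inbred panel the
choice rarely matters) and `hom_only` (opposite homozygotes only, the
strict criterion for biparental design). Loci missing in either accession
are excluded from that pair; nothing is imputed.

**Spacing.** Adjacent gaps are within-chromosome only; the
nearest-neighbor distance of a marker is the smaller of its two flanking
gaps (one at chromosome ends); "within a threshold" is inclusive.
Chromosomes with a single marker contribute no gaps, and a manifest with no
multi-marker chromosome is an error ("no gaps defined").

**Distances and trees.** The default accession distance is the allele-
sharing p-distance (0 / 0.5 / 1 per locus, averaged over co-called loci); a
pair with zero co-called loci is an error naming the pair. The Tamura–Nei
(TN93) option renders accessions as pseudo-sequences over the panel's
ref/alt alleles, accumulating transition/transversion proportions and base
frequencies with fractional counts at heterozygous sites. Concatenated SNP
genotypes are not a homogeneous nucleotide sequence — applying a
substitution model to them is a known abuse, provided only for
comparability with sequence-based tree pipelines; p-distance is the
recommended default. Saturated pairs (a logarithm argument ≤ 0) return NA
with a warning rather than a fabricated distance.

`nj_tree()` is a from-scratch Saitou–Nei implementation: Q-criterion,
limb lengths `l_i = d_ij/2 + (R_i − R_j)/(2(r−2))`, reduction
`d_k = (d_ik + d_jk − d_ij)/2`, final trifurcating base node. Tie-breaking
is deterministic (lowest active-index pair among minima, within a relative
tolerance of 1e-12). Negative branch-length estimates — a standard
artefact of NJ on non-additive data — are clamped to zero and counted in
an attribute. Bootstrap support resamples loci with replacement, rebuilds
the tree, and scores each internal edge by the percentage of replicates
containing the same leaf-set bipartition; branch lengths are ignored in
the comparison and supports are mapped onto the point-estimate tree.
`write_newick()` writes branch lengths and integer supports as internal
node labels, single-quoting labels with spaces or metacharacters.

**PCA.** No-calls are mean-imputed per locus, loci are centred but not
variance-scaled (scaling would up-weight rare alleles), constant loci are
dropped, and an all-constant matrix is an error. The sign of each component
is fixed by making its largest-magnitude loading positive, so scores are
reproducible across platforms.

**Graphical genotypes and segments.** `classify_progeny()` codes progeny
A/B/H/NC against opposite-homozygote parental loci. `detect_segments()`
treats no-calls as transparent — missing cells inside an introgression
block neither break nor extend a run, matching how introgression plots are
read. The minimal interval spans the outermost donor-coded markers; the
maximal interval ends 1 bp inside the nearest flanking recurrent-coded
marker (the true breakpoint lies strictly between markers) or at the
chromosome end.

**Foreground, background, narrowing.** When no informative marker lies
inside a QTL interval, `foreground_status()` falls back to the two nearest
flanking markers — exactly the situation of a submergence-tolerance locus
bracketed by two array markers. Conflicting recurrent/donor evidence is
`unknown`, never a guess. Background recovery scores A = 1, H = 0.5, B = 0
(the standard MABC convention; half the genome of a heterozygous region is
recurrent). `narrow_region()` finds the maximal marker run where every
unaffected line is non-donor-homozygous while at least one affected line is
donor-homozygous, and reports the width as the coordinate difference of the
outermost satisfying markers, never a rounded figure.
`cssl_coverage()` delegates interval union/gap/overlap arithmetic to
IRanges.

## Problem sizes

The test suite validates on small fixtures (tens to hundreds of loci,
6–60 accessions) plus one array-scale design run: a ~18,000-candidate
catalog over 12 rice-like chromosomes with 100 accessions in 5
subpopulations, quota 400 per subpopulation and 3 crosses. That run takes
roughly 15 seconds on one CPU; the full suite runs in under two minutes.
`scripts/acceptance.R` repeats the array-scale run from a caller-supplied
seed. These sizes were chosen so every property is exercised at the scale
the design procedure targets while remaining desk-reproducible.

## Known limitations

* No linkage disequilibrium or ascertainment modelling in the simulator;
  qualification rates on real catalogs will differ from synthetic ones.
* The design engine optimizes spacing greedily; it is deterministic and
  meets the per-Mb guarantee whenever possible, but it is not a provably
  optimal spacing (the underlying problem is set-cover-like).
* TN93 on concatenated SNPs, as discussed, is a pragmatic approximation.
* Bead-chemistry scoring (probe designability) is out of scope; the
  manifest's `designable` flag is a stand-in supplied by the user or the
  simulator.
* The VCF reader handles biallelic SNP records with GT fields; phased
  separators are accepted but phase is discarded.
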